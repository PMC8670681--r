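test_that("error centering shifts draws by the distribution's tau-quantile", {
  x <- matrix(rnorm(20), 4)
  expect_identical(center_errors(x, 0.5), x)              # median of N(0,1) is 0
  expect_equal(center_errors(x, 0.75), x - qnorm(0.75))   # independent quantile oracle
  expect_equal(center_errors(x, 0.25), x + abs(qnorm(0.75)))  # symmetry
  expect_error(center_errors(x, 0), "tau")
  expect_error(center_errors(x, 1.2), "tau")
})

test_that("centered draws have near-zero empirical tau-quantile", {
  set.seed(11)
  e <- rnorm(1e6)
  for (tau in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(quantile(center_errors(e, tau), tau)), 0.005)
  }
})

test_that("panel generation is seed-deterministic", {
  a <- generate_panel(20, 15, tau = 0.25, seed = 99, design = "heteroscedastic")
  b <- generate_panel(20, 15, tau = 0.25, seed = 99, design = "heteroscedastic")
  expect_identical(a, b)
  c <- generate_panel(20, 15, tau = 0.25, seed = 100, design = "heteroscedastic")
  expect_false(identical(a$y, c$y))
})

test_that("rho = 0 decouples units and zero-error panels solve the linear system", {
  zero_dist <- error_dist(function(n) rep(0, n), function(p) 0, "degenerate")
  w <- build_block_weights(10)
  p0 <- generate_panel(10, 6, w = w, rho = 0, seed = 5, dist = zero_dist,
                       burn_in = 0)
  expect_equal(p0$y, p0$X[, , 1] + p0$truth$eta, tolerance = 1e-12)

  p5 <- generate_panel(10, 6, w = w, rho = 0.5, seed = 5, dist = zero_dist,
                       burn_in = 0)
  rhs <- p5$X[, , 1] + p5$truth$eta
  expect_equal(p5$y, solve(diag(10) - 0.5 * w$values, rhs), tolerance = 1e-10)
})

test_that("structural residual recovers the injected error at machine precision", {
  w <- build_block_weights(20)
  pan <- generate_panel(20, 30, w = w, rho = 0.5, seed = 42, burn_in = 0)
  D <- compute_spatial_lag(pan, w)
  u <- pan$y - 0.5 * D - pan$X[, , 1] - pan$truth$eta
  expect_equal(u, pan$truth$u, tolerance = 1e-10)
})

test_that("heteroscedastic errors keep a zero conditional median", {
  w <- build_block_weights(50)
  pan <- generate_panel(50, 200, w = w, design = "heteroscedastic", seed = 3,
                        burn_in = 0)
  D <- compute_spatial_lag(pan, w)
  u <- pan$y - 0.5 * D - pan$X[, , 1] - pan$truth$eta
  expect_lt(abs(median(u)), 0.02)  # 1 + 0.1 X > 0 preserves the median
})

test_that("spatial lag matches its definition on simple cases", {
  y <- matrix(c(3, 5, 1, 2), 2)
  expect_equal(compute_spatial_lag(y, matrix(0, 2, 2)), matrix(0, 2, 2))
  perm <- matrix(c(0, 1, 1, 0), 2)          # swap the two units
  expect_equal(compute_spatial_lag(y, perm), y[2:1, ])
  w <- build_block_weights(10)
  const <- matrix(7, 10, 3)
  expect_equal(compute_spatial_lag(const, w), const)  # row sums are 1
})

test_that("instrument construction aligns and loses the right periods", {
  w <- build_block_weights(10)
  pan <- generate_panel(10, 30, w = w, seed = 8, burn_in = 0)
  lag0 <- make_instruments(pan, w, "lagged_response")
  expect_equal(dim(lag0$omega), c(10, 29, 1))
  expect_equal(lag0$t_offset, 1L)
  expect_equal(lag0$omega[, , 1], pan$y[, 1:29])

  pan1 <- generate_panel(10, 30, w = w, seed = 8, burn_in = 1)
  lag1 <- make_instruments(pan1, w, "lagged_response")
  expect_equal(dim(lag1$omega), c(10, 30, 1))
  expect_equal(lag1$t_offset, 0L)
  expect_equal(lag1$omega[, 1, 1], pan1$y_pre[, 1])
  expect_equal(lag1$omega[, 2:30, 1], pan1$y[, 1:29])

  wx <- make_instruments(pan1, w, "spatial_lag_x")
  expect_equal(wx$t_offset, 0L)
  expect_equal(wx$omega[, , 1], w$values %*% pan1$X[, , 1])
  # constant covariate cross-section: row-normalized W passes it through
  pan_c <- pan1
  pan_c$X[, , 1] <- matrix(4.2, 10, 30)
  wx_c <- make_instruments(pan_c, w, "spatial_lag_x")
  expect_equal(wx_c$omega[, , 1], matrix(4.2, 10, 30))
})

test_that("the spatial lag of X is correlated with the endogenous regressor", {
  w <- build_block_weights(100)
  pan <- generate_panel(100, 100, w = w, rho = 0, seed = 77, burn_in = 0)
  D <- compute_spatial_lag(pan, w)
  wx <- make_instruments(pan, w, "spatial_lag_x")
  # D = W(X beta + eta + e) loads on WX even at rho = 0
  expect_gt(cor(as.vector(wx$omega[, , 1]), as.vector(D)), 0.3)
})
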