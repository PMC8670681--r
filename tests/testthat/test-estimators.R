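test_that("model spec validates its fields", {
  s <- qr_model_spec()
  expect_equal(length(s$rho_grid), 41)
  expect_equal(s$rho_grid[21], 0)
  expect_error(qr_model_spec(tau = 1.1), "tau")
  expect_error(qr_model_spec(rho_grid = numeric(0)), "nonempty")
  expect_error(qr_model_spec(rho_grid = c(0.5, 0.1)), "ascending")
  expect_error(qr_model_spec(rho_grid = c(-1.5, 0)), "within")
  expect_error(qr_model_spec(bandwidth = "fixed"), "fixed_bandwidth")
})

test_that("noiseless per-unit fits recover the structural coefficients", {
  set.seed(31)
  T_ <- 30
  D <- rnorm(T_); X <- rnorm(T_)
  y <- 0.5 * D + X + 2
  fu <- fit_unit_qr(y, D, X, 0.5)
  expect_equal(fu$theta, c(0.5, 1), tolerance = 1e-6)
  expect_equal(fu$eta, 2, tolerance = 1e-6)
  expect_false(fu$rank_deficient)
})

test_that("a degenerate spatial lag is flagged as rank deficient", {
  set.seed(32)
  suppressWarnings(fu <- fit_unit_qr(rnorm(20), rep(0, 20), rnorm(20), 0.5))
  expect_true(fu$rank_deficient)
})

test_that("grid profiling selects the structural rho", {
  spec1 <- qr_model_spec(rho_grid = 0.5)
  set.seed(33)
  T_ <- 40
  om <- runif(T_, -2, 2)
  D <- om + 0.1 * rnorm(T_)       # instrument drives the endogenous regressor
  X <- rnorm(T_)
  y <- 0.5 * D + X + 1 + 1e-3 * rnorm(T_)
  # singleton grid: rho_hat is that point no matter the data
  e1 <- fit_unit_ivqr(y, D, X, om, spec1)
  expect_equal(e1$rho_hat, 0.5)
  # near-noiseless data: exhaustive grid scan puts the norm minimum at 0.5
  spec <- qr_model_spec()
  e <- fit_unit_ivqr(y, D, X, om, spec)
  expect_equal(e$rho_hat, 0.5)
  at_half <- which(abs(spec$rho_grid - 0.5) < 1e-12)
  expect_true(all(e$norm_profile[at_half] <= e$norm_profile[-at_half]))
  expect_equal(e$beta_hat, 1, tolerance = 0.02)
  expect_equal(e$eta_hat, 1, tolerance = 0.02)
  # rho_hat always lies on the grid
  expect_true(any(abs(spec$rho_grid - e$rho_hat) < 1e-12))
})

test_that("an instrument duplicating a covariate raises a collinearity error", {
  set.seed(34)
  X <- rnorm(40); D <- rnorm(40); y <- rnorm(40)
  expect_error(fit_unit_ivqr(y, D, X, X, qr_model_spec()), "collinear")
})

test_that("S_i matches its closed form and a brute-force loop", {
  # orthonormal-in-sample columns: S = tau(1-tau) I
  T_ <- 8
  q1 <- qr.Q(qr(matrix(rnorm(T_ * 2), T_))) * sqrt(T_)
  S <- estimate_Si(q1[, 1], q1[, 2], 0.5)
  expect_equal(S, 0.25 * diag(2), tolerance = 1e-10)
  expect_equal(estimate_Si(q1[, 1], q1[, 2], 0.25), 0.75 * S,
               tolerance = 1e-10)
  # random instance against an explicit double loop
  set.seed(35)
  om <- matrix(rnorm(30), 15); X <- matrix(rnorm(30), 15)
  S2 <- estimate_Si(om, X, 0.3)
  xs <- cbind(om, X)
  acc <- matrix(0, 4, 4)
  for (t in 1:15) acc <- acc + xs[t, ] %*% t(xs[t, ])
  expect_equal(unname(S2), 0.3 * 0.7 * acc / 15, tolerance = 1e-12)
})

test_that("J_i averages density-weighted cross moments", {
  # standard normal residuals: mean density at zero approaches dnorm(0)
  set.seed(36)
  r <- rnorm(20000)
  J <- estimate_Ji(r, rep(1, 20000), rep(1, 20000), rep(1, 20000), 0.5)
  expect_equal(mean(J$density), dnorm(0), tolerance = 0.01)
  # random instance against an explicit loop with the same density values
  set.seed(37)
  T_ <- 25
  r <- rnorm(T_); om <- rnorm(T_); D <- rnorm(T_); X <- matrix(rnorm(T_))
  Jo <- estimate_Ji(r, om, D, X, 0.4)
  xs <- cbind(om, X); xt <- cbind(D, X)
  acc <- matrix(0, 2, 2)
  for (t in 1:T_) acc <- acc + Jo$density[t] * xs[t, ] %*% t(xt[t, ])
  expect_equal(unname(Jo$J), unname(acc) / T_, tolerance = 1e-12)
})

test_that("doubling residuals halves the scale-adaptive density at zero", {
  set.seed(38)
  r <- rnorm(200)
  f1 <- mdqr:::powell_density(r, 0.5)
  f2 <- mdqr:::powell_density(2 * r, 0.5)
  keep <- f1 > 1e-3          # away from the density floor
  expect_equal(f2[keep], f1[keep] / 2, tolerance = 1e-12)
  expect_equal(attr(f2, "bandwidth"), 2 * attr(f1, "bandwidth"),
               tolerance = 1e-12)
})

test_that("V_i sandwich matches closed forms and an explicit oracle", {
  expect_equal(estimate_Vi_iv(diag(2), 0.25 * diag(2)), 0.25 * diag(2),
               tolerance = 1e-10)
  expect_equal(estimate_Vi_iv(diag(c(2, 1)), diag(2)), diag(c(0.25, 1)),
               tolerance = 1e-10)
  set.seed(39)
  J <- matrix(rnorm(4), 2) + 2 * diag(2)
  S <- crossprod(matrix(rnorm(6), 3, 2)) / 3
  V <- estimate_Vi_iv(J, S)
  expect_equal(V, solve(J) %*% S %*% t(solve(J)), tolerance = 1e-10)
  expect_equal(V, t(V))
})

test_that("minimum-distance combination weights by inverse covariance", {
  mk <- function(theta, V) list(rho_hat = theta[1], beta_hat = theta[2],
                                V_hat = V, tau = 0.5, T_eff = 50)
  t1 <- c(0.4, 1.2); t2 <- c(0.6, 0.8); t3 <- c(0.2, 1.0)
  # equal covariances: exactly the arithmetic mean
  eq <- combine_md(list(mk(t1, diag(2)), mk(t2, diag(2)), mk(t3, diag(2))))
  expect_equal(unname(eq$theta_hat), (t1 + t2 + t3) / 3, tolerance = 1e-12)
  # single unit passes through
  expect_equal(unname(combine_md(list(mk(t1, diag(2))))$theta_hat), t1)
  # V1 = I, V2 = 3I: hand-computed (3 theta1 + theta2) / 4
  two <- combine_md(list(mk(t1, diag(2)), mk(t2, 3 * diag(2))))
  expect_equal(unname(two$theta_hat), (3 * t1 + t2) / 4, tolerance = 1e-12)
  # flagged units are dropped and counted
  fl <- mk(c(9, 9), diag(2)); fl$flagged <- TRUE
  dr <- combine_md(list(mk(t1, diag(2)), mk(t2, diag(2)), fl))
  expect_equal(unname(dr$theta_hat), (t1 + t2) / 2, tolerance = 1e-12)
  expect_equal(dr$n_excluded, 1L)
  expect_error(combine_md(list()), "no estimates")
})

test_that("confidence intervals use the sqrt(NT) normal scaling", {
  fit <- structure(list(theta_hat = c(rho = 0.5, beta1 = 1),
                        V_combined = diag(2), n_units = 100, n_periods = 100,
                        tau = 0.5, method = "iv_mdqr"), class = "md_fit")
  ci <- confidence_intervals(fit, 0.95)
  expect_equal(ci$upper - ci$estimate, rep(qnorm(0.975) / 100, 2),
               tolerance = 1e-12)
  expect_equal(ci$upper - ci$estimate, rep(0.0196, 2), tolerance = 1e-4)
  ci50 <- confidence_intervals(fit, 0.5)
  expect_true(all(ci50$upper - ci50$lower < ci$upper - ci$lower))
  expect_error(confidence_intervals(fit, 1.2), "level")
})

test_that("pooled fixed-effects solver agrees with the dense design", {
  set.seed(40)
  n <- 80; N <- 8
  un <- rep(0:(N - 1), each = n / N)
  Xd <- matrix(rnorm(n * 2), n)
  y <- rnorm(n)
  a <- mdqr:::qrfn_fe_cpp(Xd, un, N, y, 0.3)
  Z <- stats::model.matrix(~ factor(un) - 1)
  b <- mdqr:::qrfn_cpp(cbind(Xd, Z), y, 0.3)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-6)
})

test_that("IV-FEQR with a singleton grid matches the pooled fit at known rho", {
  w <- build_block_weights(20)
  pan <- generate_panel(20, 25, w = w, seed = 41)
  iv <- make_instruments(pan, w, "spatial_lag_x")
  fe <- fit_iv_feqr(pan, w, iv, qr_model_spec(rho_grid = 0.5))
  expect_equal(unname(fe$theta_hat[["rho"]]), 0.5)
  # independent path: dense interior-point fit with explicit dummies
  D <- compute_spatial_lag(pan, w)
  yv <- as.vector(t(pan$y)) - 0.5 * as.vector(t(D))
  Xd <- cbind(as.vector(t(pan$X[, , 1])), as.vector(t(iv$omega[, , 1])))
  Z <- stats::model.matrix(~ factor(rep(1:20, each = 25)) - 1)
  dense <- fit_qr(yv, cbind(Xd, Z), 0.5)
  expect_equal(unname(fe$theta_hat[["beta1"]]),
               unname(dense$coefficients[1]), tolerance = 1e-5)
})

test_that("flagged units are excluded from the combination, capped at 20%", {
  w <- build_block_weights(10)
  pan <- generate_panel(10, 40, w = w, seed = 43)
  iv <- make_instruments(pan, w, "spatial_lag_x")
  # sabotage one unit's instrument into the constant column
  iv$omega[3, , 1] <- 1
  fit <- fit_iv_mdqr(pan, w, iv, qr_model_spec())
  expect_equal(fit$n_excluded, 1L)
  expect_equal(fit$n_units, 9L)
  # sabotage three units: over the 20% cap
  iv$omega[4, , 1] <- 1
  iv$omega[5, , 1] <- 1
  expect_error(fit_iv_mdqr(pan, w, iv, qr_model_spec()), "20%")
})

test_that("quantile process reduces to a single fit and is sorted by tau", {
  w <- build_block_weights(10)
  pan <- generate_panel(10, 30, w = w, seed = 44)
  iv <- make_instruments(pan, w, "spatial_lag_x")
  spec <- qr_model_spec()
  one <- quantile_process(pan, w, 0.5, spec, iv)
  ref <- confidence_intervals(fit_iv_mdqr(pan, w, iv, spec))
  expect_equal(one$estimate, ref$estimate)
  expect_equal(one$lower, ref$lower)
  sweep <- quantile_process(pan, w, c(0.75, 0.25, 0.5), spec, iv)
  expect_true(!is.unsorted(sweep$tau))
  expect_equal(unique(sweep$tau), c(0.25, 0.5, 0.75))
})
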