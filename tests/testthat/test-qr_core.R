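test_that("check loss matches its closed form", {
  expect_equal(check_loss(2, 0.3), 0.6)
  expect_equal(check_loss(-2, 0.3), 1.4)
  expect_equal(check_loss(0, 0.7), 0)
  expect_true(all(check_loss(rnorm(100), 0.4) >= 0))
  expect_error(check_loss(1, 0), "tau")
  expect_error(check_loss(1, 1), "tau")
})

test_that("intercept-only fits recover sample quantiles", {
  f <- fit_qr(c(1, 2, 3), matrix(1, 3, 1), 0.5)
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$objective, 1)
  # even n: any point of [2, 3] is optimal, the objective is pinned at 2
  f4 <- fit_qr(c(1, 2, 3, 4), matrix(1, 4, 1), 0.5)
  expect_equal(f4$objective, 2, tolerance = 1e-8)
  # exact linear signal: zero loss, coefficients reproduced
  set.seed(2)
  X <- cbind(1, rnorm(20))
  y <- drop(X %*% c(0.7, -1.3))
  fl <- fit_qr(y, X, 0.3)
  expect_equal(unname(fl$coefficients), c(0.7, -1.3), tolerance = 1e-7)
  expect_lt(fl$objective, 1e-7)
})

test_that("solver objective matches the vertex-enumeration oracle", {
  set.seed(314)
  for (k in 1:40) {
    inst <- random_qr_instance()
    f <- fit_qr(inst$y, inst$X, inst$tau)
    expect_true(f$converged)
    expect_equal(f$objective, qr_brute_objective(inst$y, inst$X, inst$tau),
                 tolerance = 1e-6)
  }
})

test_that("fits are scale and regression equivariant", {
  set.seed(6)
  X <- cbind(1, rnorm(40), runif(40))
  y <- rnorm(40)
  b <- fit_qr(y, X, 0.3)$coefficients
  expect_equal(fit_qr(3.7 * y, X, 0.3)$coefficients, 3.7 * b, tolerance = 1e-7)
  shifted <- fit_qr(y + 2 * X[, 3], X, 0.3)$coefficients
  expect_equal(shifted, b + c(0, 0, 2), tolerance = 1e-7)
})

test_that("the share of negative residuals brackets tau", {
  set.seed(9)
  X <- cbind(1, rnorm(200))
  y <- rnorm(200) + X[, 2]
  for (tau in c(0.25, 0.5, 0.75)) {
    f <- fit_qr(y, X, tau)
    share <- mean(f$residuals < -1e-7)
    expect_gte(share, tau - ncol(X) / 200 - 1e-8)
    expect_lte(share, tau + ncol(X) / 200 + 1e-8)
    expect_equal(f$objective, sum(check_loss(f$residuals, tau)))
  }
})

test_that("fitted intercept-only quantiles are nondecreasing in tau", {
  set.seed(13)
  y <- rt(60, df = 3)
  qs <- vapply(seq(0.1, 0.9, by = 0.1),
               function(tau) fit_qr(y, matrix(1, 60, 1), tau)$coefficients,
               numeric(1))
  expect_true(all(diff(qs) >= -1e-10))
})

test_that("rank-deficient designs are flagged and still solved", {
  set.seed(21)
  X <- cbind(1, rnorm(30))
  X <- cbind(X, X[, 2])    # duplicated column
  y <- rnorm(30)
  expect_warning(f <- fit_qr(y, X, 0.5), "rank-deficient")
  expect_true(f$rank_deficient)
  expect_equal(f$objective,
               qr_brute_objective(y, X[, 1:2], 0.5), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_qr(1:2, matrix(1, 2, 2), 0.5), "more observations")
  expect_error(fit_qr(1:3, matrix(1, 3, 1), 1.5), "tau")
  expect_error(fit_qr(c(1, NA, 3), matrix(1, 3, 1), 0.5), "non-finite")
})
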