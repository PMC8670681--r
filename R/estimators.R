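#' Model specification for quantile estimation
#'
#' Bundles the tuning choices shared by the quantile estimators: the quantile
#' level, the search grid for the spatial coefficient, the instrument kind,
#' the bandwidth rule for the residual density at zero, the norm applied to
#' the instrument coefficient in the grid profiling step, and the covariance
#' regularization constant.
#'
#' @param tau Quantile level in (0, 1).
#' @param rho_grid Ascending grid in `[-1, 1]` searched for the spatial
#'   coefficient; default `{0.05 k : -20 <= k <= 20}`.
#' @param instrument Default instrument kind used when none is supplied.
#' @param bandwidth Bandwidth rule for the kernel density of the residuals at
#'   zero: Hall-Sheather (default), Bofinger, or a fixed value.
#' @param fixed_bandwidth Bandwidth on the residual scale when
#'   `bandwidth = "fixed"`.
#' @param gamma_norm Norm of the instrument coefficient minimized over the
#'   grid: `"euclidean"` (default; equals `|gamma|` for a single instrument),
#'   `"abs"` (L1), or `"wald"` (`gamma' Omega^{-1} gamma` with `Omega` the
#'   gamma block of the per-fit sandwich covariance).
#' @param ridge_eps Ridge added to a covariance whose minimum eigenvalue
#'   falls below it.
#' @param density_floor Lower bound on pointwise density estimates.
#' @return An object of class `qr_model_spec`.
#' @export
qr_model_spec <- function(tau = 0.5,
                          rho_grid = seq(-1, 1, by = 0.05),
                          instrument = c("spatial_lag_x", "lagged_response"),
                          bandwidth = c("hall_sheather", "bofinger", "fixed"),
                          fixed_bandwidth = NULL,
                          gamma_norm = c("euclidean", "abs", "wald"),
                          ridge_eps = 1e-8,
                          density_floor = 1e-4) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  rho_grid <- as.numeric(rho_grid)
  if (length(rho_grid) == 0L || any(!is.finite(rho_grid)))
    stop("rho_grid must be a nonempty finite vector")
  if (is.unsorted(rho_grid, strictly = TRUE)) stop("rho_grid must be strictly ascending")
  if (any(abs(rho_grid) > 1 + 1e-12)) stop("rho_grid must lie within [-1, 1]")
  bandwidth <- match.arg(bandwidth)
  if (bandwidth == "fixed" &&
      (!is.numeric(fixed_bandwidth) || fixed_bandwidth <= 0))
    stop("fixed bandwidth rule needs a positive fixed_bandwidth")
  if (ridge_eps <= 0) stop("ridge_eps must be positive")
  structure(list(tau = tau, rho_grid = rho_grid,
                 instrument = match.arg(instrument),
                 bandwidth = bandwidth, fixed_bandwidth = fixed_bandwidth,
                 gamma_norm = match.arg(gamma_norm),
                 ridge_eps = ridge_eps, density_floor = density_floor),
            class = "qr_model_spec")
}

# Powell kernel estimate of the residual density at zero, one value per
# observation: f_hat_t = K(e_t / h) / h with a Gaussian kernel.  The
# bandwidth comes from the Hall-Sheather or Bofinger rule on the quantile
# scale, mapped to the residual scale by the normal quantile spread times a
# robust estimate of the residual dispersion (min of sd and IQR/1.349).
powell_density <- function(residuals, tau, rule = "hall_sheather",
                           fixed_bandwidth = NULL, floor = 1e-4) {
  n <- length(residuals)
  if (rule == "fixed") {
    h <- fixed_bandwidth
  } else {
    qt <- qnorm(tau)
    h_tau <- switch(rule,
      hall_sheather = n^(-1 / 3) * qnorm(0.975)^(2 / 3) *
        ((1.5 * dnorm(qt)^2) / (2 * qt^2 + 1))^(1 / 3),
      bofinger = n^(-1 / 5) *
        ((4.5 * dnorm(qt)^4) / (2 * qt^2 + 1)^2)^(1 / 5),
      stop("unknown bandwidth rule: ", rule))
    while (tau - h_tau <= 0 || tau + h_tau >= 1) h_tau <- h_tau / 2
    sc <- min(sd(residuals), IQR(residuals) / 1.349)
    if (!is.finite(sc) || sc <= 0)
      stop("degenerate residuals: zero spread, cannot estimate density")
    # the rule's h_tau is the half-window of a tau-space difference
    # quotient; the matching kernel bandwidth on the residual scale is the
    # half-spread of the corresponding quantile window
    h <- (qnorm(tau + h_tau) - qnorm(tau - h_tau)) / 2 * sc
  }
  if (!is.finite(h) || h <= 0) stop("nonpositive bandwidth")
  f <- pmax(dnorm(residuals / h) / h, floor)
  attr(f, "bandwidth") <- h
  f
}

#' Outer-product matrix S_i of the score
#'
#' `S_i(tau) = tau (1 - tau) * mean_t( x*_t x*_t' )` with
#' `x*_t = [omega_t', X_t']'`: the middle of the sandwich covariance of the
#' per-unit instrumented quantile fit.
#'
#' @param omega_i T x q instrument matrix for one unit.
#' @param X_i T x p covariate matrix for the same periods.
#' @param tau Quantile level.
#' @return Symmetric PSD `(q + p) x (q + p)` matrix.
#' @export
estimate_Si <- function(omega_i, X_i, tau) {
  omega_i <- as.matrix(omega_i); X_i <- as.matrix(X_i)
  if (nrow(omega_i) != nrow(X_i)) stop("omega and X are not aligned")
  xs <- cbind(omega_i, X_i)
  tau * (1 - tau) * crossprod(xs) / nrow(xs)
}

#' Jacobian matrix J_i of the score
#'
#' `J_i(tau) = mean_t( f_hat_t x*_t xtilde_t' )` with
#' `x*_t = [omega_t', X_t']'`, `xtilde_t = [D_t, X_t']'` and `f_hat_t` a
#' Powell kernel estimate of the residual density at zero.
#'
#' @param residuals_i Residuals from the selected per-unit fit.
#' @param omega_i T x q instrument matrix.
#' @param D_i Spatial-lag vector, length T.
#' @param X_i T x p covariate matrix.
#' @param tau Quantile level.
#' @param bandwidth_rule `"hall_sheather"`, `"bofinger"` or `"fixed"`.
#' @param fixed_bandwidth Bandwidth when the rule is `"fixed"`.
#' @param density_floor Lower bound on pointwise density estimates.
#' @return List with `J` (`(q+p) x (1+p)` matrix), `density` (the pointwise
#'   estimates) and `bandwidth`.
#' @export
estimate_Ji <- function(residuals_i, omega_i, D_i, X_i, tau,
                        bandwidth_rule = "hall_sheather",
                        fixed_bandwidth = NULL, density_floor = 1e-4) {
  omega_i <- as.matrix(omega_i); X_i <- as.matrix(X_i)
  f <- powell_density(as.numeric(residuals_i), tau, bandwidth_rule,
                      fixed_bandwidth, density_floor)
  xs <- cbind(omega_i, X_i)
  xt <- cbind(D_i, X_i)
  list(J = crossprod(xs * f, xt) / nrow(xs),
       density = as.numeric(f), bandwidth = attr(f, "bandwidth"))
}

#' Per-unit sandwich covariance of the instrumented fit
#'
#' `V_i = J_i^{-1} S_i (J_i^{-1})'`.  Overidentified fits (more instrument
#' rows than parameters) use the least-squares pseudo-inverse
#' `(J'J)^{-1} J'`.  The result is symmetrized and, if its minimum
#' eigenvalue falls below `ridge_eps`, regularized by adding
#' `ridge_eps * I`.
#'
#' @param Ji Jacobian matrix from [estimate_Ji()] (the `J` element).
#' @param Si Score matrix from [estimate_Si()].
#' @param ridge_eps Regularization constant.
#' @return Symmetric positive-definite `(1+p) x (1+p)` matrix.
#' @export
estimate_Vi_iv <- function(Ji, Si, ridge_eps = 1e-8) {
  Ji <- as.matrix(Ji); Si <- as.matrix(Si)
  Jinv <- if (nrow(Ji) == ncol(Ji)) solve(Ji) else solve(crossprod(Ji), t(Ji))
  v <- Jinv %*% Si %*% t(Jinv)
  v <- (v + t(v)) / 2
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge_eps) v <- v + diag(ridge_eps, nrow(v))
  if (!all(is.finite(v))) stop("non-finite covariance")
  v
}

# Sandwich covariance of the plain (uninstrumented) per-unit quantile fit:
# V_i = tau(1-tau) H^{-1} G H^{-1} with G = mean(xt xt'), H = mean(f xt xt'),
# xt = [D, X', 1]' (the fitted intercept rides along; the (rho, beta) block
# is returned unless keep_all).
estimate_Vi_qr <- function(residuals_i, D_i, X_i, tau,
                           bandwidth_rule = "hall_sheather",
                           fixed_bandwidth = NULL, density_floor = 1e-4,
                           ridge_eps = 1e-8, keep_all = FALSE) {
  X_i <- as.matrix(X_i)
  xt <- cbind(D_i, X_i, 1)
  f <- powell_density(as.numeric(residuals_i), tau, bandwidth_rule,
                      fixed_bandwidth, density_floor)
  G <- crossprod(xt) / nrow(xt)
  H <- crossprod(xt * f, xt) / nrow(xt)
  Hinv <- solve(H)
  v <- tau * (1 - tau) * Hinv %*% G %*% t(Hinv)
  v <- (v + t(v)) / 2
  if (!keep_all) {
    d <- ncol(X_i) + 1L
    v <- v[seq_len(d), seq_len(d), drop = FALSE]
  }
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge_eps) v <- v + diag(ridge_eps, nrow(v))
  v
}

# Internal constructor for a per-unit estimate.
individual_estimate <- function(unit_id, tau, rho_hat, beta_hat, eta_hat,
                                V_hat, T_eff, gamma_hat = NULL,
                                gamma_profile = NULL, norm_profile = NULL,
                                residuals = NULL, flagged = FALSE) {
  structure(list(unit_id = unit_id, tau = tau, rho_hat = rho_hat,
                 beta_hat = beta_hat, eta_hat = eta_hat,
                 gamma_hat = gamma_hat, gamma_profile = gamma_profile,
                 norm_profile = norm_profile, V_hat = V_hat,
                 T_eff = T_eff, residuals = residuals, flagged = flagged),
            class = "individual_estimate")
}

#' Per-unit quantile regression on the spatial lag
#'
#' Step 1 of the two-step minimum-distance procedure: the `tau`-th quantile
#' regression of one unit's time series `y_i` on `[D_i, X_i, 1]`.  The
#' coefficient on the spatial lag `D` is endogeneity-biased; the
#' instrumented variant [fit_unit_ivqr()] removes that bias.
#'
#' @param y_i Response vector, length T.
#' @param D_i Spatial-lag vector, length T.
#' @param X_i T x p covariate matrix.
#' @param tau Quantile level.
#' @return List with `theta` (`c(rho, beta)`), `eta` (the unit intercept),
#'   `residuals`, `rank_deficient`, and the underlying `fit`.
#' @export
fit_unit_qr <- function(y_i, D_i, X_i, tau) {
  X_i <- as.matrix(X_i)
  p <- ncol(X_i); T_ <- length(y_i)
  if (T_ <= p + 2L) stop("time series too short: need T > p + 2")
  Z <- cbind(D = D_i, X_i, intercept = 1)
  fit <- fit_qr(y_i, Z, tau)
  list(theta = unname(fit$coefficients[seq_len(p + 1L)]),
       eta = unname(fit$coefficients[p + 2L]),
       residuals = fit$residuals,
       rank_deficient = fit$rank_deficient,
       fit = fit)
}

#' Per-unit instrumental-variable quantile regression (grid profiling)
#'
#' For each candidate value `rho_j` of the spatial coefficient, fits the
#' `tau`-th quantile regression of `y_i - rho_j D_i` on `[X_i, 1, omega_i]`
#' and records the instrument coefficient `gamma_hat(rho_j)`.  The estimate
#' of `rho` is the grid point making the configured norm of `gamma_hat`
#' closest to zero (at the true coefficient the instrument, being
#' independent of the error, has no explanatory power).  Ties within 1e-12
#' are broken toward the candidate closest to zero, then the smaller one.
#'
#' @param y_i,D_i,X_i One unit's response, spatial lag and covariates,
#'   already aligned with the instrument rows.
#' @param omega_i T_eff x q instrument matrix.
#' @param spec A [qr_model_spec].
#' @param unit_id Optional label.
#' @return An `individual_estimate`: `rho_hat`, `beta_hat`, `eta_hat`,
#'   `gamma_hat`, the full `gamma_profile` over the grid, the per-unit
#'   sandwich covariance `V_hat`, residuals at the selected fit, and a
#'   `flagged` indicator when the covariance could not be formed.
#' @export
fit_unit_ivqr <- function(y_i, D_i, X_i, omega_i, spec, unit_id = NA) {
  X_i <- as.matrix(X_i); omega_i <- as.matrix(omega_i)
  p <- ncol(X_i); q <- ncol(omega_i)
  T_ <- length(y_i)
  if (nrow(omega_i) != T_ || length(D_i) != T_ || nrow(X_i) != T_)
    stop("y, D, X and omega are not aligned")
  if (T_ <= p + q + 2L) stop("time series too short: need T > p + q + 2")
  Z <- cbind(X_i, intercept = 1, omega_i)
  if (qr(Z)$rank < ncol(Z))
    stop("collinear design: instrument collinear with covariates or constant")

  grid <- spec$rho_grid
  J <- length(grid)
  gam <- matrix(NA_real_, J, q)
  coefs <- matrix(NA_real_, J, ncol(Z))
  ok <- logical(J)
  fits <- vector("list", J)
  for (j in seq_len(J)) {
    f <- fit_qr(y_i - grid[j] * D_i, Z, spec$tau)
    coefs[j, ] <- f$coefficients
    gam[j, ] <- f$coefficients[(p + 2L):(p + 1L + q)]
    ok[j] <- f$converged && !f$rank_deficient
    fits[[j]] <- f
  }
  if (!any(ok)) stop("all grid fits failed")

  norms <- switch(spec$gamma_norm,
    euclidean = sqrt(rowSums(gam^2)),
    abs = rowSums(abs(gam)),
    wald = vapply(seq_len(J), function(j) {
      if (!ok[j]) return(Inf)
      # gamma block of the sandwich covariance of the grid-j fit
      v <- tryCatch({
        f <- powell_density(fits[[j]]$residuals, spec$tau, spec$bandwidth,
                            spec$fixed_bandwidth, spec$density_floor)
        G <- crossprod(Z) / T_
        H <- crossprod(Z * as.numeric(f), Z) / T_
        Hi <- solve(H)
        spec$tau * (1 - spec$tau) * Hi %*% G %*% t(Hi)
      }, error = function(e) NULL)
      if (is.null(v)) return(Inf)
      gi <- (p + 2L):(p + 1L + q)
      drop(t(gam[j, ]) %*% solve(v[gi, gi, drop = FALSE], gam[j, ]))
    }, numeric(1)))
  norms[!ok] <- Inf

  cand <- which(norms <= min(norms) + 1e-12)
  sel <- cand[order(abs(grid[cand]), grid[cand])][1L]
  rho_hat <- grid[sel]
  b <- coefs[sel, ]
  resid <- as.numeric(y_i - rho_hat * D_i - Z %*% b)

  # sandwich over the full per-unit parameter vector (the fit estimates an
  # intercept, so the moment vectors carry the constant); the covariance of
  # (rho, beta) is the leading block
  Xa <- cbind(X_i, 1)
  Si <- estimate_Si(omega_i, Xa, spec$tau)
  Jout <- tryCatch(
    estimate_Ji(resid, omega_i, D_i, Xa, spec$tau, spec$bandwidth,
                spec$fixed_bandwidth, spec$density_floor),
    error = function(e) NULL)
  V <- if (is.null(Jout)) NULL else tryCatch(
    estimate_Vi_iv(Jout$J, Si, spec$ridge_eps)[seq_len(p + 1L),
                                               seq_len(p + 1L)],
    error = function(e) NULL)

  rownames(gam) <- format(grid)
  individual_estimate(
    unit_id = unit_id, tau = spec$tau, rho_hat = rho_hat,
    beta_hat = unname(b[seq_len(p)]), eta_hat = unname(b[p + 1L]),
    gamma_hat = unname(b[(p + 2L):(p + 1L + q)]),
    gamma_profile = gam, norm_profile = norms,
    V_hat = V, T_eff = T_, residuals = resid,
    flagged = is.null(V))
}

#' Minimum-distance combination of per-unit estimates
#'
#' Pools per-unit estimates `theta_i = (rho_i, beta_i')'` by inverse-variance
#' weighting:
#' \deqn{\hat\theta = \Big(\sum_i \hat V_i^{-1}\Big)^{-1} \sum_i \hat V_i^{-1}
#'   \hat\theta_i,}
#' the efficient fixed-effects-free combination.  With all covariances equal
#' this is exactly the unweighted mean.  Flagged units (failed fits or
#' covariances) are dropped and counted.
#'
#' @param estimates List of per-unit estimates; each element needs fields
#'   `rho_hat`, `beta_hat`, `V_hat`, `tau`, `T_eff` and optionally `flagged`.
#' @param method Label stored on the result.
#' @return An object of class `md_fit`: `theta_hat` (named vector),
#'   `V_combined` (`N * (sum V_i^{-1})^{-1}`, the estimate of the asymptotic
#'   covariance of `sqrt(NT)(theta_hat - theta)`), `n_units`, `n_excluded`,
#'   `n_periods`, `tau`, `method`.
#' @export
combine_md <- function(estimates, method = "iv_mdqr") {
  if (length(estimates) == 0L) stop("no estimates to combine")
  flagged <- vapply(estimates, function(e) isTRUE(e$flagged) || is.null(e$V_hat),
                    logical(1))
  est <- estimates[!flagged]
  if (length(est) == 0L) stop("all per-unit estimates are flagged")
  taus <- vapply(est, function(e) e$tau, numeric(1))
  if (length(unique(taus)) != 1L) stop("estimates have inconsistent tau")
  d <- length(est[[1L]]$beta_hat) + 1L
  if (any(vapply(est, function(e) length(e$beta_hat) + 1L, integer(1)) != d))
    stop("estimates have inconsistent dimension")

  acc <- matrix(0, d, d)
  accv <- numeric(d)
  n_used <- 0L
  n_dropped <- sum(flagged)
  for (e in est) {
    wi <- tryCatch(chol2inv(chol((e$V_hat + t(e$V_hat)) / 2)),
                   error = function(err) NULL)
    if (is.null(wi) || !all(is.finite(wi))) { n_dropped <- n_dropped + 1L; next }
    acc <- acc + wi
    accv <- accv + wi %*% c(e$rho_hat, e$beta_hat)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable per-unit covariances")
  theta <- drop(solve(acc, accv))
  vcomb <- n_used * solve(acc)
  vcomb <- (vcomb + t(vcomb)) / 2
  names(theta) <- c("rho", paste0("beta", seq_len(d - 1L)))
  dimnames(vcomb) <- list(names(theta), names(theta))
  structure(list(theta_hat = theta, V_combined = vcomb,
                 n_units = n_used, n_excluded = n_dropped,
                 n_periods = max(vapply(est, function(e) e$T_eff, numeric(1))),
                 tau = taus[1L], method = method,
                 individual = estimates),
            class = "md_fit")
}

#' @export
print.md_fit <- function(x, ...) {
  cat(sprintf("%s fit at tau = %g (N = %d units%s, T = %d)\n",
              toupper(gsub("_", "-", x$method)), x$tau, x$n_units,
              if (x$n_excluded > 0) sprintf(" + %d excluded", x$n_excluded) else "",
              x$n_periods))
  ci <- confidence_intervals(x)
  print(ci, row.names = FALSE)
  invisible(x)
}

# Shared per-unit loop guard: abort when too many units dropped.
check_exclusions <- function(flagged, n_units) {
  if (sum(flagged) > 0.2 * n_units)
    stop(sprintf("more than 20%% of units excluded (%d of %d)",
                 sum(flagged), n_units))
}

#' Two-step minimum-distance quantile regression (no instrument)
#'
#' Step 1: per-unit quantile regression of `y_i` on `[D_i, X_i, 1]` with the
#' per-unit sandwich covariance `V_i = tau(1-tau) H_i^{-1} G_i H_i^{-1}`.
#' Step 2: inverse-variance combination across units.  Because the spatial
#' lag `D` is endogenous, the estimate of `rho` is biased; this estimator is
#' the uncorrected baseline that [fit_iv_mdqr()] improves on.
#'
#' @param panel A `sar_panel`.
#' @param w A [spatial_weights] object.
#' @param spec A [qr_model_spec].
#' @return An `md_fit` with `method = "mdqr"`.
#' @export
fit_mdqr <- function(panel, w, spec = qr_model_spec()) {
  D <- compute_spatial_lag(panel, w)
  N <- panel$n_units
  ests <- vector("list", N)
  for (i in seq_len(N)) {
    ests[[i]] <- tryCatch({
      fu <- fit_unit_qr(panel$y[i, ], D[i, ],
                        panel$X[i, , , drop = TRUE], spec$tau)
      if (fu$rank_deficient) stop("rank-deficient unit design")
      V <- estimate_Vi_qr(fu$residuals, D[i, ],
                          matrix(panel$X[i, , ], panel$n_periods),
                          spec$tau, spec$bandwidth, spec$fixed_bandwidth,
                          spec$density_floor, spec$ridge_eps)
      individual_estimate(i, spec$tau, fu$theta[1L], fu$theta[-1L], fu$eta,
                          V, panel$n_periods, residuals = fu$residuals)
    }, error = function(e) individual_estimate(
         i, spec$tau, NA_real_, NA_real_, NA_real_, NULL,
         panel$n_periods, flagged = TRUE))
  }
  flagged <- vapply(ests, function(e) e$flagged, logical(1))
  check_exclusions(flagged, N)
  out <- combine_md(ests, method = "mdqr")
  out$spec <- spec
  out
}

# Align panel, spatial lag and instruments on the estimation sample.
align_sample <- function(panel, w, instruments) {
  D <- compute_spatial_lag(panel, w)
  off <- instruments$t_offset
  idx <- (1L + off):panel$n_periods
  if (dim(instruments$omega)[2] != length(idx))
    stop("instrument array does not align with the estimation sample")
  list(y = panel$y[, idx, drop = FALSE],
       D = D[, idx, drop = FALSE],
       X = panel$X[, idx, , drop = FALSE],
       omega = instruments$omega,
       idx = idx, T_eff = length(idx))
}

#' Instrumental-variable minimum-distance quantile regression
#'
#' The main estimator: per-unit grid-profiled IV quantile regression
#' ([fit_unit_ivqr()]) followed by inverse-variance minimum-distance
#' combination ([combine_md()]), using the per-unit sandwich covariance
#' `V_i = J_i^{-1} S_i (J_i^{-1})'`.
#'
#' @param panel A `sar_panel`.
#' @param w A [spatial_weights] object.
#' @param instruments An [instrument_set]; built with [make_instruments()]
#'   from `spec$instrument` when `NULL`.
#' @param spec A [qr_model_spec].
#' @return An `md_fit` with `method = "iv_mdqr"`.
#' @export
fit_iv_mdqr <- function(panel, w, instruments = NULL, spec = qr_model_spec()) {
  if (is.null(instruments))
    instruments <- panel$instruments %||% make_instruments(panel, w, spec$instrument)
  al <- align_sample(panel, w, instruments)
  N <- panel$n_units
  ests <- vector("list", N)
  for (i in seq_len(N)) {
    ests[[i]] <- tryCatch(
      fit_unit_ivqr(al$y[i, ], al$D[i, ],
                    matrix(al$X[i, , ], al$T_eff),
                    matrix(al$omega[i, , ], al$T_eff),
                    spec, unit_id = i),
      error = function(e) individual_estimate(
        i, spec$tau, NA_real_, NA_real_, NA_real_, NULL,
        al$T_eff, flagged = TRUE))
  }
  flagged <- vapply(ests, function(e) e$flagged, logical(1))
  check_exclusions(flagged, N)
  out <- combine_md(ests, method = "iv_mdqr")
  out$n_periods <- al$T_eff
  out$spec <- spec
  out
}

#' Pooled instrumental-variable fixed-effects quantile regression
#'
#' The one-shot comparison estimator: for each candidate `rho_j`, a pooled
#' quantile regression of `y - rho_j D` on the covariates, a full block of
#' unit indicators, and the instruments; `rho_hat` minimizes the configured
#' norm of the pooled instrument coefficient.  All `N` fixed effects are
#' estimated jointly, which is what the minimum-distance estimators avoid.
#' The unit-indicator block is handled by a structured interior-point solve,
#' so the cost per grid point stays linear in `N T`.
#'
#' @inheritParams fit_iv_mdqr
#' @return An `md_fit` with `method = "iv_feqr"` (covariance from the pooled
#'   sandwich with per-unit density estimates).
#' @export
fit_iv_feqr <- function(panel, w, instruments = NULL, spec = qr_model_spec()) {
  if (is.null(instruments))
    instruments <- panel$instruments %||% make_instruments(panel, w, spec$instrument)
  al <- align_sample(panel, w, instruments)
  N <- panel$n_units
  p <- panel$n_covariates
  q <- dim(al$omega)[3]
  Te <- al$T_eff
  if (N * Te <= p + q + N) stop("not enough observations for the pooled fit")

  # stack unit-major: observation (i, t) at row (i - 1) * Te + t
  yv <- as.vector(t(al$y))
  Dv <- as.vector(t(al$D))
  Xd <- matrix(NA_real_, N * Te, p + q)
  for (k in seq_len(p)) Xd[, k] <- as.vector(t(al$X[, , k]))
  for (k in seq_len(q)) Xd[, p + k] <- as.vector(t(al$omega[, , k]))
  unit0 <- rep(seq_len(N) - 1L, each = Te)

  grid <- spec$rho_grid
  J <- length(grid)
  gam <- matrix(NA_real_, J, q)
  coefs <- matrix(NA_real_, J, p + q + N)
  ok <- logical(J)
  for (j in seq_len(J)) {
    sol <- qrfn_fe_cpp(Xd, unit0, N, yv - grid[j] * Dv, spec$tau)
    coefs[j, ] <- sol$coefficients
    gam[j, ] <- sol$coefficients[(p + 1L):(p + q)]
    ok[j] <- isTRUE(sol$converged)
  }
  if (!any(ok)) stop("all grid fits failed")
  norms <- switch(spec$gamma_norm,
    euclidean = sqrt(rowSums(gam^2)),
    abs = rowSums(abs(gam)),
    wald = sqrt(rowSums(gam^2)))   # pooled Wald weighting reduces to |gamma| for q = 1
  norms[!ok] <- Inf
  cand <- which(norms <= min(norms) + 1e-12)
  sel <- cand[order(abs(grid[cand]), grid[cand])][1L]
  rho_hat <- grid[sel]
  b <- coefs[sel, ]
  beta_hat <- b[seq_len(p)]
  gamma_hat <- b[(p + 1L):(p + q)]
  eta_hat <- b[(p + q + 1L):(p + q + N)]
  resid <- yv - rho_hat * Dv - Xd %*% b[seq_len(p + q)] - eta_hat[unit0 + 1L]

  # pooled sandwich: per-unit density estimates, pooled moment matrices
  f <- numeric(N * Te)
  for (i in seq_len(N)) {
    rows <- ((i - 1L) * Te + 1L):(i * Te)
    f[rows] <- tryCatch(
      as.numeric(powell_density(resid[rows], spec$tau, spec$bandwidth,
                                spec$fixed_bandwidth, spec$density_floor)),
      error = function(e) rep(spec$density_floor, Te))
  }
  # within-unit demeaning marginalizes the unit-indicator block, the pooled
  # analogue of carrying the per-unit intercept through the sandwich
  xs <- cbind(Xd[, (p + 1L):(p + q), drop = FALSE], Xd[, seq_len(p), drop = FALSE])
  xt <- cbind(Dv, Xd[, seq_len(p), drop = FALSE])
  xs <- apply(xs, 2, function(v) v - ave(v, unit0))
  xt <- apply(xt, 2, function(v) v - ave(v, unit0))
  Si <- spec$tau * (1 - spec$tau) * crossprod(xs) / (N * Te)
  Ji <- crossprod(xs * f, xt) / (N * Te)
  V <- tryCatch(estimate_Vi_iv(Ji, Si, spec$ridge_eps), error = function(e) {
    d <- p + 1L
    diag(NA_real_, d)
  })

  theta <- c(rho_hat, beta_hat)
  names(theta) <- c("rho", paste0("beta", seq_len(p)))
  dimnames(V) <- list(names(theta), names(theta))
  rownames(gam) <- format(grid)
  structure(list(theta_hat = theta, V_combined = V,
                 n_units = N, n_excluded = 0L, n_periods = Te,
                 tau = spec$tau, method = "iv_feqr",
                 eta_hat = eta_hat, gamma_hat = gamma_hat,
                 gamma_profile = gam, norm_profile = norms,
                 spec = spec),
            class = "md_fit")
}

#' Confidence intervals for a combined estimate
#'
#' Normal-theory pointwise intervals based on the limiting distribution
#' `sqrt(NT) (theta_hat - theta) -> N(0, V)`:
#' `theta_k +/- z_{(1+level)/2} sqrt(V_kk / (N T))`.
#'
#' @param est An `md_fit`.
#' @param level Coverage in (0, 1); default 0.95.
#' @return Data frame with columns `parameter`, `estimate`, `lower`, `upper`.
#' @export
confidence_intervals <- function(est, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  z <- qnorm((1 + level) / 2)
  hw <- z * sqrt(pmax(diag(est$V_combined), 0) / (est$n_units * est$n_periods))
  data.frame(parameter = names(est$theta_hat),
             estimate = unname(est$theta_hat),
             lower = unname(est$theta_hat - hw),
             upper = unname(est$theta_hat + hw))
}

#' Quantile-process sweep
#'
#' Fits the IV minimum-distance estimator at each quantile of `tau_grid` and
#' collects estimates with pointwise confidence intervals, the ingredients
#' of a quantile-effect plot.
#'
#' @param panel A `sar_panel`.
#' @param w A [spatial_weights] object.
#' @param tau_grid Quantile levels in (0, 1).
#' @param spec_base A [qr_model_spec] supplying everything except `tau`.
#' @param instruments Optional [instrument_set] reused across quantiles.
#' @param level CI coverage.
#' @return Data frame sorted by `tau` with columns `tau`, `parameter`,
#'   `estimate`, `lower`, `upper`.  Quantiles whose fit failed are reported
#'   in the `"failed_taus"` attribute (with a warning), not fatal.
#' @export
quantile_process <- function(panel, w, tau_grid, spec_base = qr_model_spec(),
                             instruments = NULL, level = 0.95) {
  if (any(tau_grid <= 0 | tau_grid >= 1)) stop("all tau must be in (0, 1)")
  tau_grid <- sort(tau_grid)
  if (is.null(instruments))
    instruments <- panel$instruments %||%
      make_instruments(panel, w, spec_base$instrument)
  rows <- list()
  failed <- numeric(0)
  for (tau in tau_grid) {
    spec <- spec_base
    spec$tau <- tau
    fit <- tryCatch(fit_iv_mdqr(panel, w, instruments, spec),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("tau = %g failed: %s", tau, conditionMessage(fit)))
      failed <- c(failed, tau)
      next
    }
    ci <- confidence_intervals(fit, level)
    rows[[length(rows) + 1L]] <- cbind(tau = tau, ci)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tau = numeric(0), parameter = character(0),
               estimate = numeric(0), lower = numeric(0), upper = numeric(0))
  attr(out, "failed_taus") <- failed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
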