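#' Error distribution specification
#'
#' A pluggable error law for the panel simulator: a sampler plus an inverse
#' CDF, the latter used to center draws so that their `tau`-quantile is zero.
#'
#' @param sample Function of `n` returning `n` draws.
#' @param quantile Inverse CDF, a function of a probability.
#' @param name Label.
#' @return An object of class `error_dist`.
#' @export
error_dist <- function(sample, quantile, name = "custom") {
  stopifnot(is.function(sample), is.function(quantile))
  structure(list(sample = sample, quantile = quantile, name = name),
            class = "error_dist")
}

#' Standard normal error distribution
#' @return An [error_dist] object for N(0, 1) disturbances.
#' @export
dist_normal <- function() {
  error_dist(sample = function(n) rnorm(n), quantile = qnorm, name = "normal")
}

#' Center error draws at a quantile
#'
#' Shifts raw draws by the distribution's `tau`-quantile, `e - F^{-1}(tau)`,
#' so the centered errors have zero `tau`-th quantile.  This is what makes
#' the `tau`-th conditional quantile of the simulated response equal the
#' structural equation.
#'
#' @param raw_draws Numeric vector or matrix of draws from `dist`.
#' @param tau Quantile level in (0, 1).
#' @param dist An [error_dist]; defaults to standard normal.
#' @return Centered draws, same shape as `raw_draws`.
#' @export
center_errors <- function(raw_draws, tau, dist = dist_normal()) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  raw_draws - dist$quantile(tau)
}

#' Simulate a spatial autoregressive panel
#'
#' Generates a balanced panel from
#' \deqn{y_t = (I - \rho W)^{-1} (X_t \beta + \eta + u_t),}
#' with covariates drawn i.i.d. U(-2, 2), fixed effects `eta ~ N(0, 1)` (one
#' draw per call), and disturbances `u_t = e_t - F^{-1}(tau)` (homoscedastic)
#' or `u_t = (1 + 0.1 X_t) * (e_t - F^{-1}(tau))` (heteroscedastic, single
#' covariate only; the scale stays positive because |X| < 2).  `burn_in`
#' extra leading periods are generated and kept separately so a
#' lagged-response instrument can be formed without losing estimation
#' periods.
#'
#' @param n_units Cross-section size N.
#' @param n_periods Time series length T.
#' @param tau Quantile at which the errors are centered.
#' @param w [spatial_weights]; defaults to [build_block_weights()] on
#'   `n_units`.
#' @param rho Spatial autoregressive coefficient, `|rho| < 1`.
#' @param beta Covariate coefficient vector (its length sets p).
#' @param eta Optional fixed-effect vector (length N); drawn N(0,1) if `NULL`.
#' @param design `"homoscedastic"` or `"heteroscedastic"`.
#' @param dist Error law, an [error_dist].
#' @param seed Optional integer seed; identical seeds give identical panels.
#' @param burn_in Number of extra leading periods (default 1).
#' @return An object of class `sar_panel` with fields `y` (N x T), `X`
#'   (N x T x p), `y_pre`/`X_pre` (burn-in periods, or `NULL`), ids, and the
#'   generating `truth`.
#' @export
generate_panel <- function(n_units, n_periods, tau = 0.5, w = NULL,
                           rho = 0.5, beta = 1, eta = NULL,
                           design = c("homoscedastic", "heteroscedastic"),
                           dist = dist_normal(), seed = NULL, burn_in = 1L) {
  design <- match.arg(design)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (is.null(w)) w <- build_block_weights(n_units)
  if (!inherits(w, "spatial_weights")) w <- spatial_weights(w)
  if (w$n_units != n_units) stop("weight matrix dimension does not match n_units")
  p <- length(beta)
  if (design == "heteroscedastic" && p != 1L)
    stop("the heteroscedastic design uses a single covariate")
  burn_in <- as.integer(burn_in)
  if (burn_in < 0L) stop("burn_in must be nonnegative")
  if (!is.null(seed)) set.seed(seed)

  n_tot <- n_periods + burn_in
  X <- array(runif(n_units * n_tot * p, -2, 2), dim = c(n_units, n_tot, p))
  if (is.null(eta)) eta <- rnorm(n_units)
  if (length(eta) != n_units) stop("eta must have length n_units")
  e <- center_errors(matrix(dist$sample(n_units * n_tot), n_units, n_tot),
                     tau, dist)
  if (design == "heteroscedastic") {
    scale <- 1 + 0.1 * X[, , 1L]
    if (any(scale <= 0)) stop("heteroscedastic scale must stay positive")
    u <- scale * e
  } else {
    u <- e
  }
  xb <- matrix(0, n_units, n_tot)
  for (k in seq_len(p)) xb <- xb + X[, , k] * beta[k]
  rhs <- xb + u + eta            # eta recycles down columns
  m <- diag(n_units) - rho * w$values
  y_all <- solve(m, rhs)

  est <- burn_in + seq_len(n_periods)
  structure(list(
    y = y_all[, est, drop = FALSE],
    X = X[, est, , drop = FALSE],
    y_pre = if (burn_in > 0L) y_all[, seq_len(burn_in), drop = FALSE] else NULL,
    X_pre = if (burn_in > 0L) X[, seq_len(burn_in), , drop = FALSE] else NULL,
    n_units = n_units, n_periods = n_periods, n_covariates = p,
    unit_ids = seq_len(n_units), time_ids = seq_len(n_periods),
    tau = tau, design = design, burn_in = burn_in,
    truth = list(rho = rho, beta = beta, eta = eta,
                 u = u[, est, drop = FALSE]),
    instruments = NULL
  ), class = "sar_panel")
}

#' @export
print.sar_panel <- function(x, ...) {
  cat(sprintf("sar_panel: N = %d units, T = %d periods, p = %d covariate(s)%s\n",
              x$n_units, x$n_periods, x$n_covariates,
              if (x$burn_in > 0) sprintf(", %d burn-in period(s)", x$burn_in) else ""))
  if (!is.null(x$truth))
    cat(sprintf("generated: design = %s, rho = %g, tau = %g\n",
                x$design, x$truth$rho, x$tau))
  invisible(x)
}

#' Spatial lag of the response
#'
#' Computes `D_it = sum_j w_ij y_jt`, the endogenous spatial lag entering the
#' SAR structural equation.
#'
#' @param panel A `sar_panel`, or an N x T response matrix.
#' @param w A [spatial_weights] object.
#' @return N x T matrix of spatial lags.
#' @export
compute_spatial_lag <- function(panel, w) {
  y <- if (inherits(panel, "sar_panel")) panel$y else as.matrix(panel)
  if (!inherits(w, "spatial_weights")) w <- spatial_weights(w)
  if (ncol(w$values) != nrow(y)) stop("weight matrix does not match panel dimension")
  w$values %*% y
}

#' Instrument set
#'
#' Container for instruments aligned with the estimation sample.  `t_offset`
#' records how many leading periods of the panel must be dropped so that the
#' instrument array lines up with `(y, D, X)`.
#'
#' @param omega N x T_eff x q array (a matrix is treated as q = 1).
#' @param kind One of `"lagged_response"`, `"spatial_lag_x"`,
#'   `"user_supplied"`.
#' @param t_offset Number of leading estimation periods dropped (0 or 1).
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(omega, kind = "user_supplied", t_offset = 0L) {
  if (is.matrix(omega)) omega <- array(omega, dim = c(dim(omega), 1L))
  stopifnot(length(dim(omega)) == 3L, dim(omega)[3] >= 1L)
  t_offset <- as.integer(t_offset)
  if (!t_offset %in% c(0L, 1L)) stop("t_offset must be 0 or 1")
  structure(list(omega = omega, kind = kind, t_offset = t_offset,
                 q = dim(omega)[3]),
            class = "instrument_set")
}

#' Build instruments for the spatial lag
#'
#' Two standard choices for instrumenting the endogenous spatial lag `D_it`:
#' the lagged response `y_{i,t-1}` (uses the simulator's burn-in period when
#' available, otherwise drops the first estimation period), and the spatial
#' lag of the covariates `w_i' X_t`, which inherits the exogeneity of X and
#' is correlated with `D_it` through the reduced form.
#'
#' Under a design that is serially independent within units, only the
#' spatial lag of X carries within-unit identifying variation; see the
#' methods vignette for why the lagged response is then uninformative.
#'
#' @param panel A `sar_panel`.
#' @param w A [spatial_weights] object.
#' @param kind `"spatial_lag_x"` or `"lagged_response"`.
#' @return An [instrument_set].
#' @export
make_instruments <- function(panel, w,
                             kind = c("spatial_lag_x", "lagged_response")) {
  kind <- match.arg(kind)
  if (!inherits(panel, "sar_panel")) stop("panel must be a sar_panel")
  if (!inherits(w, "spatial_weights")) w <- spatial_weights(w)
  if (w$n_units != panel$n_units) stop("weight matrix does not match panel")
  if (kind == "spatial_lag_x") {
    p <- panel$n_covariates
    omega <- array(NA_real_, dim = c(panel$n_units, panel$n_periods, p))
    for (k in seq_len(p)) omega[, , k] <- w$values %*% panel$X[, , k]
    return(instrument_set(omega, kind, t_offset = 0L))
  }
  # lagged response
  T_ <- panel$n_periods
  if (panel$burn_in >= 1L) {
    omega <- cbind(panel$y_pre[, panel$burn_in],
                   panel$y[, -T_, drop = FALSE])
    return(instrument_set(omega, kind, t_offset = 0L))
  }
  if (T_ < 2L) stop("lagged-response instrument needs T >= 2 or a burn-in period")
  instrument_set(panel$y[, -T_, drop = FALSE], kind, t_offset = 1L)
}
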