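#' Check (pinball) loss
#'
#' `rho_tau(u) = u * (tau - 1{u <= 0})`: the piecewise-linear loss whose
#' minimizer over a location model is the `tau`-th sample quantile.
#'
#' @param u Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Nonnegative losses, same length as `u`.
#' @export
check_loss <- function(u, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  u * (tau - (u <= 0))
}

#' Quantile regression by Frisch-Newton interior point
#'
#' Minimizes `sum_k rho_tau(y_k - x_k' b)` over `b`, solving the equivalent
#' linear program with a Mehrotra predictor-corrector interior-point method
#' (see `src/qrfn.cpp`).  Rank-deficient designs are handled by dropping
#' dependent columns (pivoted QR factorization); the fit is then flagged and
#' dropped coefficients are returned as zero.
#'
#' @param y Response vector, length n.
#' @param X Design matrix, n x p with n > p.
#' @param tau Quantile level in (0, 1).
#' @param eps Relative duality-gap tolerance.
#' @param maxit Iteration cap.
#' @return An object of class `qr_fit`: `coefficients`, `residuals`,
#'   `objective` (total check loss), `tau`, `converged`, `iterations`,
#'   `rank_deficient`.
#' @examples
#' f <- fit_qr(c(1, 2, 3), matrix(1, 3, 1), 0.5)
#' f$coefficients  # the sample median, 2
#' @export
fit_qr <- function(y, X, tau, eps = 1e-10, maxit = 100L) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(y)) || !all(is.finite(X))) stop("non-finite values in y or X")
  if (n <= p) stop("need more observations than regressors")

  qd <- qr(X)
  rank_deficient <- qd$rank < p
  keep <- seq_len(p)
  if (rank_deficient) {
    warning("rank-deficient design: dropping ", p - qd$rank,
            " dependent column(s)")
    keep <- sort(qd$pivot[seq_len(qd$rank)])
  }
  sol <- qrfn_cpp(X[, keep, drop = FALSE], y, tau, eps, as.integer(maxit))
  coef <- numeric(p)
  coef[keep] <- sol$coefficients
  names(coef) <- colnames(X)
  res <- as.numeric(y - X %*% coef)
  structure(list(coefficients = coef, residuals = res,
                 objective = sum(check_loss(res, tau)), tau = tau,
                 converged = isTRUE(sol$converged),
                 iterations = sol$iterations,
                 rank_deficient = rank_deficient),
            class = "qr_fit")
}

#' @export
print.qr_fit <- function(x, ...) {
  cat(sprintf("qr_fit (tau = %g): objective %.6g, %sconverged in %d iterations%s\n",
              x$tau, x$objective, if (x$converged) "" else "NOT ",
              x$iterations,
              if (x$rank_deficient) " [rank deficient]" else ""))
  print(x$coefficients)
  invisible(x)
}
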