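#' Write a panel to long-format CSV
#'
#' Columns `unit`, `time`, `y`, `X1..Xp`, optionally `omega1..omegaq` (only
#' for instruments aligned with the full estimation sample), and a `pre`
#' flag marking burn-in rows when those are included.  Rows are ordered by
#' unit, then time.
#'
#' @param panel A `sar_panel`.
#' @param path Destination CSV path.
#' @param instruments Optional [instrument_set] with `t_offset = 0` whose
#'   columns are written alongside.
#' @param include_pre Write burn-in periods (flagged `pre = 1`)? Default
#'   `TRUE`; required for a lossless round trip of a simulated panel.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, instruments = NULL, include_pre = TRUE) {
  stopifnot(inherits(panel, "sar_panel"))
  N <- panel$n_units; T_ <- panel$n_periods; p <- panel$n_covariates
  mk <- function(y, X, times, pre) {
    df <- data.frame(unit = rep(panel$unit_ids, each = length(times)),
                     time = rep(times, N),
                     y = as.vector(t(y)))
    for (k in seq_len(p)) df[[paste0("X", k)]] <- as.vector(t(X[, , k]))
    df$pre <- pre
    df
  }
  df <- mk(panel$y, panel$X, panel$time_ids, 0L)
  if (!is.null(instruments)) {
    if (instruments$t_offset != 0L)
      stop("only instruments aligned with the full sample (t_offset = 0) can be written")
    for (k in seq_len(instruments$q))
      df[[paste0("omega", k)]] <- as.vector(t(instruments$omega[, , k]))
  }
  if (include_pre && panel$burn_in > 0L) {
    pre_times <- seq_len(panel$burn_in) - panel$burn_in  # ..., -1, 0
    dfp <- mk(panel$y_pre, panel$X_pre, pre_times, 1L)
    for (nm in setdiff(names(df), names(dfp))) dfp[[nm]] <- NA_real_
    df <- rbind(dfp[names(df)], df)
    df <- df[order(df$unit, df$time), ]
  }
  if (all(df$pre == 0L)) df$pre <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format panel CSV
#'
#' Expects columns `unit`, `time`, `y`, covariates `X1..Xp`, optionally
#' instruments `omega1..omegaq` and a `pre` flag for burn-in rows.  The
#' panel must be balanced; with `allow_unbalanced = TRUE`, units with
#' incomplete time series are dropped instead.  Time labels are ordinal
#' only: they are sorted, never parsed as dates.
#'
#' @param path CSV path.
#' @param allow_unbalanced Drop incomplete units instead of erroring.
#' @return A `sar_panel`; any `omega` columns are attached as
#'   `$instruments`.
#' @export
read_panel <- function(path, allow_unbalanced = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.csv(path)
  req <- c("unit", "time", "y")
  if (!all(req %in% names(df)))
    stop("panel file must have columns: ", paste(req, collapse = ", "))
  if (!is.numeric(df$y)) stop("column y must be numeric")
  if (is.null(df$pre)) df$pre <- 0L

  key <- paste(df$unit, df$time, df$pre)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("unit", "time")][1L, ]
    stop(sprintf("duplicated (unit, time) pair: (%s, %s)", d$unit, d$time))
  }

  est <- df[df$pre == 0L, , drop = FALSE]
  times <- sort(unique(est$time))
  units <- sort(unique(est$unit))
  counts <- table(est$unit)
  complete <- names(counts)[counts == length(times)]
  if (length(complete) < length(units)) {
    if (!allow_unbalanced)
      stop("panel is unbalanced: not every (unit, time) cell is present")
    units <- sort(unique(est$unit[est$unit %in% complete]))
    est <- est[est$unit %in% units, , drop = FALSE]
    df <- df[df$unit %in% units, , drop = FALSE]
  }
  est <- est[order(match(est$unit, units), match(est$time, times)), ]
  if (anyNA(est$y)) stop("missing response values")
  N <- length(units); T_ <- length(times)

  xcols <- grep("^X[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("X", "", xcols)))]
  p <- length(xcols)
  if (p == 0L) stop("no covariate columns (X1, X2, ...) found")
  ocols <- grep("^omega[0-9]+$", names(df), value = TRUE)
  ocols <- ocols[order(as.integer(sub("omega", "", ocols)))]

  to_mat <- function(v) matrix(v, nrow = N, ncol = T_, byrow = TRUE)
  y <- to_mat(est$y)
  X <- array(NA_real_, c(N, T_, p))
  for (k in seq_len(p)) X[, , k] <- to_mat(est[[xcols[k]]])
  if (anyNA(X)) stop("missing covariate values")

  pre <- df[df$pre == 1L, , drop = FALSE]
  burn <- 0L; y_pre <- NULL; X_pre <- NULL
  if (nrow(pre) > 0L) {
    pre_times <- sort(unique(pre$time))
    burn <- length(pre_times)
    pre <- pre[order(match(pre$unit, units), match(pre$time, pre_times)), ]
    y_pre <- matrix(pre$y, N, burn, byrow = TRUE)
    X_pre <- array(NA_real_, c(N, burn, p))
    for (k in seq_len(p)) X_pre[, , k] <- matrix(pre[[xcols[k]]], N, burn, byrow = TRUE)
  }

  panel <- structure(list(
    y = y, X = X, y_pre = y_pre, X_pre = X_pre,
    n_units = N, n_periods = T_, n_covariates = p,
    unit_ids = units, time_ids = times,
    tau = NA_real_, design = NA_character_, burn_in = burn,
    truth = NULL, instruments = NULL), class = "sar_panel")

  if (length(ocols) > 0L) {
    omega <- array(NA_real_, c(N, T_, length(ocols)))
    for (k in seq_along(ocols)) omega[, , k] <- to_mat(est[[ocols[k]]])
    panel$instruments <- instrument_set(omega, "user_supplied", 0L)
  }
  panel
}

#' Serialize a fit to JSON
#'
#' Writes the coefficients, covariance, confidence intervals, sample sizes
#' and the resolved model specification of an `md_fit` as a JSON object.
#'
#' @param fit An `md_fit`.
#' @param path Destination path.
#' @param seed Optional seed to echo for reproducibility.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "md_fit"))
  ci <- confidence_intervals(fit)
  spec <- fit$spec
  out <- list(
    method = fit$method, tau = fit$tau,
    coefficients = as.list(fit$theta_hat),
    covariance = unname(fit$V_combined),
    n_units = fit$n_units, n_excluded = fit$n_excluded,
    n_periods = fit$n_periods,
    confidence_intervals = ci,
    spec = if (is.null(spec)) NULL else list(
      rho_grid_min = min(spec$rho_grid), rho_grid_max = max(spec$rho_grid),
      rho_grid_points = length(spec$rho_grid),
      instrument = spec$instrument, bandwidth = spec$bandwidth,
      gamma_norm = spec$gamma_norm),
    seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
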