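#' Monte Carlo scenario
#'
#' One cell of a replication study: a simulation design, sample sizes, a
#' quantile level, the estimators to run, and a replication count.  The
#' replication `r` uses seed `base_seed + r`, so any report is reproducible
#' from the scenario alone and independent of how replications are
#' scheduled.
#'
#' @param design `"homoscedastic"` or `"heteroscedastic"`.
#' @param n_units,n_periods Panel dimensions N and T.
#' @param tau Quantile level.
#' @param estimators Subset of `c("iv_mdqr", "mdqr", "iv_feqr")`.
#' @param n_reps Number of replications.
#' @param base_seed Integer; replication `r` uses `base_seed + r`.
#' @param spec A [qr_model_spec]; its `tau` is overridden by `tau`.
#' @param rho,beta True parameter values of the data-generating process.
#' @param burn_in Leading periods generated for instrument construction.
#' @return An object of class `mc_scenario`.
#' @export
mc_scenario <- function(design = c("homoscedastic", "heteroscedastic"),
                        n_units = 50L, n_periods = 50L, tau = 0.5,
                        estimators = c("iv_mdqr", "mdqr", "iv_feqr"),
                        n_reps = 1000L, base_seed = 1L,
                        spec = qr_model_spec(tau = tau),
                        rho = 0.5, beta = 1, burn_in = 1L) {
  design <- match.arg(design)
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (n_reps < 1L) stop("n_reps must be at least 1")
  spec$tau <- tau
  structure(list(design = design, n_units = as.integer(n_units),
                 n_periods = as.integer(n_periods), tau = tau,
                 estimators = estimators, n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed), spec = spec,
                 rho = rho, beta = beta, burn_in = as.integer(burn_in)),
            class = "mc_scenario")
}

run_mc_rep <- function(scenario, w, r, level = 0.95) {
  seed_r <- scenario$base_seed + r
  panel <- generate_panel(scenario$n_units, scenario$n_periods,
                          tau = scenario$tau, w = w, rho = scenario$rho,
                          beta = scenario$beta, design = scenario$design,
                          seed = seed_r, burn_in = scenario$burn_in)
  need_iv <- any(scenario$estimators %in% c("iv_mdqr", "iv_feqr"))
  iv <- if (need_iv) make_instruments(panel, w, scenario$spec$instrument) else NULL
  rows <- list()
  for (est in scenario$estimators) {
    fit <- tryCatch(switch(est,
      mdqr = fit_mdqr(panel, w, scenario$spec),
      iv_mdqr = fit_iv_mdqr(panel, w, iv, scenario$spec),
      iv_feqr = fit_iv_feqr(panel, w, iv, scenario$spec)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[est]] <- data.frame(rep = r, estimator = est,
                                parameter = NA_character_,
                                estimate = NA_real_, lower = NA_real_,
                                upper = NA_real_)
      next
    }
    ci <- confidence_intervals(fit, level)
    rows[[est]] <- data.frame(rep = r, estimator = est,
                              parameter = ci$parameter,
                              estimate = ci$estimate,
                              lower = ci$lower, upper = ci$upper)
  }
  do.call(rbind, rows)
}

#' Run a Monte Carlo scenario
#'
#' Simulates `n_reps` fresh panels, fits every requested estimator on each,
#' and aggregates bias (mean estimate minus truth) and RMSE per
#' (estimator, parameter) cell.  Replications are seeded individually
#' (`base_seed + r`), so the report is deterministic and identical whether
#' run serially or on several workers.  Replications in which an estimator
#' fails are dropped and counted; an estimator failing more than 5% of
#' replications aborts the run.
#'
#' @param scenario An [mc_scenario].
#' @param cores Number of worker processes (forked via the parallel
#'   package); results do not depend on this.
#' @param verbose Print progress to stderr.
#' @return An object of class `mc_report`: the `scenario`, the long per-rep
#'   `results` (estimate and 95% CI per parameter), and a `summary` data
#'   frame with columns `estimator`, `parameter`, `truth`, `bias`, `rmse`,
#'   `mc_se_bias`, `n_effective`.
#' @export
run_scenario <- function(scenario, cores = 1L, verbose = FALSE) {
  stopifnot(inherits(scenario, "mc_scenario"))
  w <- build_block_weights(scenario$n_units)
  reps <- seq_len(scenario$n_reps)
  runner <- function(r) {
    if (verbose && r %% 25L == 0L)
      message(sprintf("  replication %d / %d", r, scenario$n_reps))
    run_mc_rep(scenario, w, r)
  }
  res <- if (cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(reps, runner, mc.cores = cores)
  } else {
    lapply(reps, runner)
  }
  results <- do.call(rbind, res)

  truth <- c(rho = scenario$rho,
             stats::setNames(scenario$beta,
                             paste0("beta", seq_along(scenario$beta))))
  cells <- list()
  for (est in scenario$estimators) {
    sub <- results[results$estimator == est, , drop = FALSE]
    failed <- unique(sub$rep[is.na(sub$parameter)])
    if (length(failed) > 0.05 * scenario$n_reps)
      stop(sprintf("estimator %s failed in %d of %d replications",
                   est, length(failed), scenario$n_reps))
    sub <- sub[!is.na(sub$parameter), , drop = FALSE]
    for (par in names(truth)) {
      vals <- sub$estimate[sub$parameter == par]
      dev <- vals - truth[[par]]
      cells[[length(cells) + 1L]] <- data.frame(
        estimator = est, parameter = par, truth = truth[[par]],
        bias = mean(dev), rmse = sqrt(mean(dev^2)),
        mc_se_bias = sd(vals) / sqrt(length(vals)),
        n_effective = length(vals))
    }
  }
  structure(list(scenario = scenario, results = results,
                 summary = do.call(rbind, cells)),
            class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("mc_report: %s, N = %d, T = %d, tau = %g, %d replications\n",
              s$design, s$n_units, s$n_periods, s$tau, s$n_reps))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate Monte Carlo reports
#'
#' Lays several reports out in the conventional simulation-table shape:
#' rows are (T, N, parameter), columns are tau-by-estimator cells rendered
#' as `bias (rmse)`.
#'
#' @param reports List of `mc_report` objects sharing a parameter set.
#' @param digits Decimal places in the rendering (default 3).
#' @return Data frame of formatted cells (first columns `T`, `N`,
#'   `parameter`); a plain-text rendering is attached as attribute `"text"`.
#' @export
tabulate_mc <- function(reports, digits = 3L) {
  if (length(reports) == 0L) stop("no reports to tabulate")
  if (inherits(reports, "mc_report")) reports <- list(reports)
  pars <- lapply(reports, function(r) sort(unique(r$summary$parameter)))
  if (length(unique(vapply(pars, paste, character(1), collapse = ","))) != 1L)
    stop("reports have inconsistent parameter sets")

  fmt <- function(b, r) sprintf("%.*f (%.*f)", digits, b, digits, r)
  long <- do.call(rbind, lapply(reports, function(r) {
    s <- r$scenario
    cbind(data.frame(T = s$n_periods, N = s$n_units, tau = s$tau),
          r$summary)
  }))
  long$cell <- fmt(long$bias, long$rmse)
  long$col <- sprintf("tau=%g %s", long$tau, long$estimator)

  keys <- unique(long[, c("T", "N", "parameter")])
  cols <- unique(long$col)
  out <- keys
  for (cn in cols) {
    out[[cn]] <- vapply(seq_len(nrow(keys)), function(i) {
      m <- long$T == keys$T[i] & long$N == keys$N[i] &
        long$parameter == keys$parameter[i] & long$col == cn
      if (any(m)) long$cell[which(m)[1L]] else ""
    }, character(1))
  }
  txt <- utils::capture.output(print(out, row.names = FALSE))
  attr(out, "text") <- txt
  out
}

#' Read a flat key=value scenario configuration
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognized keys: `design`, `N`, `T`, `tau`, `estimators`
#' (comma-separated), `reps`, `seed`, `rho`, `beta`, `instrument`,
#' `burn_in`.
#'
#' @param path Config file path.
#' @return An [mc_scenario].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  conf <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  get <- function(key, default) if (key %in% names(conf)) conf[[key]] else default
  spec <- qr_model_spec(
    tau = as.numeric(get("tau", 0.5)),
    instrument = get("instrument", "spatial_lag_x"))
  mc_scenario(
    design = get("design", "homoscedastic"),
    n_units = as.integer(get("N", 50)),
    n_periods = as.integer(get("T", 50)),
    tau = as.numeric(get("tau", 0.5)),
    estimators = strsplit(get("estimators", "iv_mdqr,mdqr,iv_feqr"), ",")[[1L]],
    n_reps = as.integer(get("reps", 1000)),
    base_seed = as.integer(get("seed", 1)),
    spec = spec,
    rho = as.numeric(get("rho", 0.5)),
    beta = as.numeric(get("beta", 1)),
    burn_in = as.integer(get("burn_in", 1)))
}
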