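# The top-level fit: a full single-laboratory validation analysis on a table
# of quantified well results.

#' Fit a single-laboratory ddPCR validation analysis
#'
#' The central fitting function of the package. Given one row per valid well
#' (a measured concentration with its level, run and optionally assay labels)
#' and a table of certified reference values, it estimates, per concentration
#' level, the relative repeatability and run-to-run variation by nested
#' one-way ANOVA; pools the per-level components by root mean square; assesses
#' the trueness (relative bias and its expanded uncertainty) against the
#' certified values; optionally estimates the between-assay component; and
#' combines everything with the droplet-volume uncertainty into the expanded
#' measurement uncertainty (k = 2) of a routine result reported as the mean of
#' `n_meas` replicates in `n_run` runs.
#'
#' @param data data frame of QC-passed results with columns `level_id`,
#'   `run_id`, the concentration in `value`, and optionally `assay_id`.
#' @param certified certified levels (`level_id`, `c_cert`, `U_cert`); see
#'   [erm_ad623()]. Only levels present in `data` are used.
#' @param value name of the concentration column (default `"c_sample"`).
#' @param u_vd_rel relative standard uncertainty of the droplet volume.
#' @param s_thres_rel threshold-setting component to carry into the budget
#'   (default 0: negligible inside the working range).
#' @param n_meas,n_run design of the routine result whose uncertainty is
#'   reported (defaults: mean of 4 replicates in 1 run).
#' @param n_method group-size convention for unbalanced runs, see
#'   [precision_from_runs()].
#' @param run_term reading of the run term in the budget, see
#'   [combined_uncertainty()].
#' @return An object of class `"ddpcr_validation"` with components
#'   `per_level` (data frame of level means and precision components),
#'   `pooled` (named fractions `s_repeat_rel`, `s_run_rel`,
#'   `u_precision_rel`), `bias` (a `"bias_estimate"`), `assay` (component list
#'   or `NULL`), `budget` (an `"uncertainty_budget"`), and `call`. Methods:
#'   [print.ddpcr_validation()], [summary.ddpcr_validation()],
#'   [coef.ddpcr_validation()], [plot.ddpcr_validation()].
#' @examples
#' st <- simulate_validation_study(c(AD623d = 255), n_runs = 3,
#'                                 replicates = c(6, 8, 6),
#'                                 config = sim_config(255, run_effect_rel_sd = 0.02),
#'                                 keep_amplitudes = FALSE, seed = 42)
#' res <- quantify_study(st)
#' res$c_sample <- res$c_sample * 4  # pretend a 4x dilution
#' fit <- ddpcr_validation(res, certified = data.frame(level_id = "AD623d",
#'                                                     c_cert = 1020, U_cert = 90))
#' fit
#' @export
ddpcr_validation <- function(data, certified, value = "c_sample",
                             u_vd_rel = 0.018, s_thres_rel = 0,
                             n_meas = 4, n_run = 1,
                             n_method = "mean", run_term = "variance") {
  stopifnot(is.data.frame(data),
            all(c("level_id", "run_id", value) %in% names(data)))
  if (anyNA(data[[value]])) stop_ddpcr("missing concentrations in data")
  levels_present <- unique(data$level_id)

  per <- lapply(levels_present, function(lv) {
    d <- data[data$level_id == lv, ]
    runs <- split(d[[value]], d$run_id)
    if (length(runs) < 2L) {
      warning("level ", lv, " measured in < 2 runs: precision skipped",
              call. = FALSE)
      return(data.frame(level_id = lv, c_meas = mean(d[[value]]),
                        n = nrow(d), n_runs = length(runs),
                        s_repeat_rel = NA_real_, s_run_rel = NA_real_,
                        u_precision_rel = NA_real_, run_clamped = NA))
    }
    p <- precision_from_runs(runs, n_method = n_method)
    data.frame(level_id = lv, c_meas = p$mean_concentration, n = p$n_total,
               n_runs = p$n_runs, s_repeat_rel = p$s_repeat_rel,
               s_run_rel = p$s_run_rel, u_precision_rel = p$u_precision_rel,
               run_clamped = p$run_clamped)
  })
  per <- do.call(rbind, per)

  ok <- !is.na(per$s_repeat_rel)
  if (!any(ok)) stop_ddpcr("no level has >= 2 runs; cannot estimate precision")
  pooled <- c(s_repeat_rel = pool_rms(per$s_repeat_rel[ok]),
              s_run_rel = pool_rms(per$s_run_rel[ok]),
              u_precision_rel = pool_rms(per$u_precision_rel[ok]))

  bias <- bias_assessment(per[, c("level_id", "c_meas")], certified,
                          u_precision_rel = pooled[["u_precision_rel"]])

  assay <- NULL
  if ("assay_id" %in% names(data) && length(unique(data$assay_id)) > 1L) {
    s_by_level <- vapply(levels_present, function(lv) {
      d <- data[data$level_id == lv, ]
      assay_variability(split(d[[value]], d$assay_id))$s_assay_rel
    }, numeric(1))
    assay <- list(per_level = stats::setNames(s_by_level, levels_present),
                  s_assay_pooled_rel = pool_rms(s_by_level))
  }

  budget <- combined_uncertainty(pooled[["s_repeat_rel"]],
                                 pooled[["s_run_rel"]],
                                 u_vd_rel = u_vd_rel,
                                 u_bias_rel = bias$u_bias_rel,
                                 s_thres_rel = s_thres_rel,
                                 n_meas = n_meas, n_run = n_run,
                                 run_term = run_term)

  structure(list(per_level = per, pooled = pooled, bias = bias,
                 assay = assay, budget = budget, u_vd_rel = u_vd_rel,
                 s_thres_rel = s_thres_rel, n_wells = nrow(data),
                 call = match.call()),
            class = "ddpcr_validation")
}

#' @export
print.ddpcr_validation <- function(x, ...) {
  cat("Single-laboratory ddPCR validation\n")
  cat(sprintf("  %d wells, %d level(s)\n", x$n_wells, nrow(x$per_level)))
  cat(sprintf("  pooled: s_repeat,rel %s, s_run,rel %s, u_precision,rel %s\n",
              pct(x$pooled[["s_repeat_rel"]]), pct(x$pooled[["s_run_rel"]]),
              pct(x$pooled[["u_precision_rel"]])))
  cat(sprintf("  mean bias %s (u_bias,rel %s) -> %ssignificant\n",
              pct(x$bias$mean_bias_rel), pct(x$bias$u_bias_rel),
              if (x$bias$significant) "" else "not "))
  if (!is.null(x$assay))
    cat(sprintf("  s_assay,pooled,rel %s\n", pct(x$assay$s_assay_pooled_rel)))
  cat(sprintf("  U_meas,rel %s (k = 2, mean of %d measurement(s) in %d run(s))\n",
              pct(x$budget$U_meas_rel), x$budget$n_meas, x$budget$n_run))
  invisible(x)
}

#' Summarise a ddPCR validation fit
#'
#' @param object a [ddpcr_validation()] fit.
#' @param ... unused.
#' @return An object of class `"summary.ddpcr_validation"` holding a per-level
#'   accuracy table (percent scale) plus the pooled components, bias and
#'   budget of the fit.
#' @export
summary.ddpcr_validation <- function(object, ...) {
  tab <- merge(object$per_level, object$bias$per_level[, c("level_id", "c_cert",
                                                           "U_cert", "bias_rel")],
               by = "level_id", sort = FALSE)
  tab <- data.frame(level_id = tab$level_id, c_cert = tab$c_cert,
                    U_cert = tab$U_cert, c_meas = tab$c_meas,
                    bias_rel_pct = 100 * tab$bias_rel,
                    s_repeat_rel_pct = 100 * tab$s_repeat_rel,
                    s_run_rel_pct = 100 * tab$s_run_rel,
                    u_precision_rel_pct = 100 * tab$u_precision_rel,
                    run_clamped = tab$run_clamped)
  structure(list(table = tab, pooled = object$pooled, bias = object$bias,
                 assay = object$assay, budget = object$budget),
            class = "summary.ddpcr_validation")
}

#' @export
print.summary.ddpcr_validation <- function(x, ...) {
  cat("Accuracy assessment per certified level (percent scale):\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  cat("\n")
  cat(sprintf("pooled (RMS): s_repeat,rel %s  s_run,rel %s  u_precision,rel %s\n",
              pct(x$pooled[["s_repeat_rel"]]), pct(x$pooled[["s_run_rel"]]),
              pct(x$pooled[["u_precision_rel"]])))
  print(x$bias)
  if (!is.null(x$assay))
    cat(sprintf("s_assay,pooled,rel %s\n", pct(x$assay$s_assay_pooled_rel)))
  print(x$budget)
  invisible(x)
}

#' Extract the uncertainty-budget components of a validation fit
#'
#' @param object a [ddpcr_validation()] fit.
#' @param ... unused.
#' @return Named numeric vector of relative components (fractions):
#'   pooled repeatability, run and precision terms, droplet-volume and bias
#'   uncertainties, the threshold component, and the combined `U_meas_rel`.
#' @export
coef.ddpcr_validation <- function(object, ...) {
  c(s_repeat_rel = unname(object$pooled[["s_repeat_rel"]]),
    s_run_rel = unname(object$pooled[["s_run_rel"]]),
    u_precision_rel = unname(object$pooled[["u_precision_rel"]]),
    u_vd_rel = object$u_vd_rel,
    u_bias_rel = object$bias$u_bias_rel,
    s_thres_rel = object$s_thres_rel,
    s_assay_rel = if (is.null(object$assay)) NA_real_
                  else unname(object$assay$s_assay_pooled_rel),
    U_meas_rel = object$budget$U_meas_rel)
}

#' Plot the uncertainty budget of a validation fit
#'
#' Bar plot of the standard-uncertainty contributions entering the combined
#' expanded uncertainty (percent scale).
#'
#' @param x a [ddpcr_validation()] fit.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted component vector.
#' @export
plot.ddpcr_validation <- function(x, ...) {
  comp <- 100 * x$budget$components
  graphics::barplot(comp, ylab = "standard uncertainty contribution (%)",
                    main = sprintf("U_meas,rel = %s (k = 2)",
                                   pct(x$budget$U_meas_rel)), ...)
  invisible(comp)
}
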