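# Method-validation statistics: nested precision, trueness, assay and
# threshold variance components, combined expanded uncertainty, linearity,
# LOD/LOQ and robustness. Relative quantities are fractions internally and
# become percentages only when printed.

#' Repeatability and run-to-run variation from a nested design
#'
#' Results of one concentration level, grouped per run, are decomposed by
#' one-way ANOVA into the relative repeatability
#' `s_repeat_rel = sqrt(MS_within) / c_mean` and the relative run-to-run
#' variation `s_run_rel = sqrt((MS_between - MS_within) / n_bar) / c_mean`.
#' When `MS_between < MS_within` the run component cannot be estimated and is
#' set to zero (negligible against the repeatability), with `run_clamped`
#' flagged. The relative standard uncertainty of the mean of the whole design
#' is `u_precision_rel = sqrt(s_repeat² / (n_bar * n_run) + s_run² / n_run)`.
#'
#' For unbalanced designs `n_bar` is the arithmetic mean of the run sizes;
#' `n_method = "iso"` switches to the ISO 5725-3 effective group size
#' `n0 = (N - sum(n_g²)/N) / (k - 1)`.
#'
#' @param runs list of numeric vectors of measured concentrations, one per
#'   run.
#' @param n_method `"mean"` (default) or `"iso"`; see Details.
#' @return An object of class `"precision_estimate"`: `s_repeat_rel`,
#'   `s_run_rel`, `u_precision_rel` (fractions), `run_clamped`, `ms_within`,
#'   `ms_between`, `n_runs`, `n_bar_repli`, `n_total`, `mean_concentration`.
#' @examples
#' precision_from_runs(list(c(1, 2, 3), c(2, 3, 4)))
#' @export
precision_from_runs <- function(runs, n_method = c("mean", "iso")) {
  n_method <- match.arg(n_method)
  a <- one_way_anova(runs)
  n_bar <- if (n_method == "iso") {
    sizes <- lengths(runs)
    (a$n_total - sum(sizes^2) / a$n_total) / (a$n_groups - 1L)
  } else a$n_bar
  cbar <- a$grand_mean
  if (cbar <= 0) stop_ddpcr("mean concentration must be positive")
  s_repeat <- sqrt(a$ms_within) / cbar
  clamped <- a$ms_between < a$ms_within
  s_run <- if (clamped) 0 else sqrt((a$ms_between - a$ms_within) / n_bar) / cbar
  u_prec <- sqrt(s_repeat^2 / (n_bar * a$n_groups) + s_run^2 / a$n_groups)
  structure(list(s_repeat_rel = s_repeat, s_run_rel = s_run,
                 u_precision_rel = u_prec, run_clamped = clamped,
                 ms_within = a$ms_within, ms_between = a$ms_between,
                 n_runs = a$n_groups, n_bar_repli = n_bar,
                 n_total = a$n_total, mean_concentration = cbar),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("precision over %d run(s) (n = %d, mean %.4g copies/uL)\n",
              x$n_runs, x$n_total, x$mean_concentration))
  cat(sprintf("  s_repeat,rel %s  s_run,rel %s%s  u_precision,rel %s\n",
              pct(x$s_repeat_rel), pct(x$s_run_rel),
              if (x$run_clamped) " (clamped: MS_between < MS_within)" else "",
              pct(x$u_precision_rel)))
  invisible(x)
}

#' Precision uncertainty of a mean result from known components
#'
#' Direct evaluation of
#' `u = sqrt(s_repeat² / (n_bar * n_run) + s_run² / n_run)` for components
#' obtained elsewhere (e.g. from a published validation summary).
#'
#' @param s_repeat_rel,s_run_rel relative SDs (any consistent scale).
#' @param n_bar_repli average replicates per run; `n_run` number of runs.
#' @return The relative standard uncertainty, on the input scale.
#' @examples
#' precision_uncertainty(0.077, 0, n_bar_repli = 40 / 3, n_run = 3)  # ~1.2 %
#' @export
precision_uncertainty <- function(s_repeat_rel, s_run_rel, n_bar_repli, n_run) {
  stopifnot(s_repeat_rel >= 0, s_run_rel >= 0, n_bar_repli >= 1, n_run >= 1)
  sqrt(s_repeat_rel^2 / (n_bar_repli * n_run) + s_run_rel^2 / n_run)
}

#' Trueness assessment against certified reference levels
#'
#' Relative bias per level, `(c_meas - c_cert) / c_cert`; the mean bias over
#' levels; and the uncertainty of that bias estimate,
#' `u_bias_rel = sqrt(u_precision² + sum(u_cert_rel²) / n_cert)`, combining
#' the pooled precision of the measured means with the certified relative
#' standard uncertainties (`u_cert_rel = (U_cert / 2) / c_cert`, coverage
#' factor k = 2 as on CRM certificates). The bias is significant when its
#' absolute mean exceeds the expanded `U_bias_rel = 2 * u_bias_rel`.
#'
#' @param measured_means data frame with `level_id` and `c_meas` columns, or a
#'   named numeric vector of measured mean concentrations.
#' @param certified data frame with `level_id`, `c_cert`, `U_cert` (see
#'   [erm_ad623()]); levels must match `measured_means`.
#' @param u_precision_rel pooled relative precision uncertainty (fraction).
#' @return An object of class `"bias_estimate"`: `per_level` (data frame with
#'   `bias_rel`), `mean_bias_rel`, `u_bias_rel`, `U_bias_rel`, `significant`,
#'   `n_cert`.
#' @examples
#' cert <- erm_ad623()[1:5, ]
#' meas <- data.frame(level_id = cert$level_id,
#'                    c_meas = c(0.97e6, 0.93e5, 0.94e4, 0.93e3, 97))
#' bias_assessment(meas, cert, u_precision_rel = 0.019)
#' @export
bias_assessment <- function(measured_means, certified, u_precision_rel) {
  stopifnot(u_precision_rel >= 0)
  if (!is.data.frame(measured_means))
    measured_means <- data.frame(level_id = names(measured_means),
                                 c_meas = as.numeric(measured_means))
  stopifnot(all(c("level_id", "c_meas") %in% names(measured_means)),
            all(c("level_id", "c_cert", "U_cert") %in% names(certified)))
  idx <- match(measured_means$level_id, certified$level_id)
  if (anyNA(idx))
    stop_ddpcr("levels not found in certified table: ",
               paste(measured_means$level_id[is.na(idx)], collapse = ", "))
  cert <- certified[idx, ]
  per <- data.frame(level_id = measured_means$level_id,
                    c_meas = measured_means$c_meas,
                    c_cert = cert$c_cert, U_cert = cert$U_cert,
                    u_cert_rel = (cert$U_cert / 2) / cert$c_cert)
  per$bias_rel <- (per$c_meas - per$c_cert) / per$c_cert
  n_cert <- nrow(per)
  u_bias <- sqrt(u_precision_rel^2 + sum(per$u_cert_rel^2) / n_cert)
  mean_bias <- mean(per$bias_rel)
  structure(list(per_level = per, mean_bias_rel = mean_bias,
                 u_bias_rel = u_bias, U_bias_rel = 2 * u_bias,
                 significant = abs(mean_bias) > 2 * u_bias, n_cert = n_cert),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("relative bias over %d certified level(s): mean %s\n",
              x$n_cert, pct(x$mean_bias_rel)))
  cat(sprintf("  u_bias,rel %s, U_bias,rel %s (k = 2) -> bias %ssignificant\n",
              pct(x$u_bias_rel), pct(x$U_bias_rel),
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Assay variance component
#'
#' Between-assay relative SD from results of the same material measured with
#' two (or more) independent primer/probe assays:
#' `s_assay_rel = sqrt((MS_between_assay - MS_within_assay) / n_bar) / c_mean`,
#' clamped to zero when the between-assay mean square does not exceed the
#' within-assay one.
#'
#' @param results_by_assay list of numeric vectors of measured concentrations,
#'   one per assay (`>= 2`).
#' @return A list: `s_assay_rel` (fraction), `clamped`, `ms_within`,
#'   `ms_between`, `n_bar`, `mean_concentration`.
#' @examples
#' assay_variability(list(c(10, 11, 12), c(13, 14, 15)))$s_assay_rel  # 0.1633
#' @export
assay_variability <- function(results_by_assay) {
  if (!is.list(results_by_assay) || length(results_by_assay) < 2L)
    stop_ddpcr("need results from at least two assays")
  a <- one_way_anova(results_by_assay)
  clamped <- a$ms_between < a$ms_within
  s <- if (clamped) 0 else sqrt((a$ms_between - a$ms_within) / a$n_bar) / a$grand_mean
  list(s_assay_rel = s, clamped = clamped, ms_within = a$ms_within,
       ms_between = a$ms_between, n_bar = a$n_bar,
       mean_concentration = a$grand_mean)
}

#' Threshold-setting variance component
#'
#' Each replicate measurement is re-analysed under several threshold variants
#' (midpoint, low, high, rain removal); grouping the variant results per
#' replicate, the within-replicate mean square captures the disagreement
#' introduced by the threshold choice:
#' `s_thres_rel = sqrt(MS_within_replicate) / c_mean`.
#'
#' @param per_replicate_variants list with one numeric vector per replicate,
#'   holding that replicate's concentrations under the different variants
#'   (each of length `>= 2`).
#' @return A list: `s_thres_rel` (fraction), `ms_within`,
#'   `mean_concentration`, `n_replicates`.
#' @examples
#' threshold_variability(list(c(100, 102, 98, 100)))$s_thres_rel  # 0.0163
#' @export
threshold_variability <- function(per_replicate_variants) {
  stopifnot(is.list(per_replicate_variants),
            length(per_replicate_variants) >= 1L)
  sizes <- lengths(per_replicate_variants)
  if (any(sizes < 2L))
    stop_ddpcr("every replicate needs results from >= 2 threshold variants")
  x <- unlist(per_replicate_variants, use.names = FALSE)
  stopifnot(all(is.finite(x)))
  ss_within <- sum(vapply(per_replicate_variants,
                          function(v) sum((v - mean(v))^2), numeric(1)))
  ms_within <- ss_within / (length(x) - length(per_replicate_variants))
  cbar <- mean(x)
  if (cbar <= 0) stop_ddpcr("mean concentration must be positive")
  list(s_thres_rel = sqrt(ms_within) / cbar, ms_within = ms_within,
       mean_concentration = cbar,
       n_replicates = length(per_replicate_variants))
}

#' Combined expanded measurement uncertainty (k = 2)
#'
#' Quadrature combination of the validated uncertainty components for a
#' result that is the mean of `n_meas` replicate measurements spread over
#' `n_run` runs:
#' `U = 2 * sqrt(s_repeat² / n_meas + s_run² / n_run + u_vd² + u_bias² (+ s_thres²))`.
#' The threshold component is included whenever `s_thres_rel > 0` (needed near
#' the limits of the working range). `run_term = "linear"` switches the run
#' contribution to `(s_run / n_run)²`; the two readings coincide for
#' `n_run = 1`.
#'
#' @param s_repeat_rel,s_run_rel pooled relative repeatability and run-to-run
#'   variation (fractions).
#' @param u_vd_rel relative standard uncertainty of the droplet volume
#'   (default 0.018).
#' @param u_bias_rel relative standard uncertainty of the bias estimate.
#' @param s_thres_rel threshold-setting component (default 0 = omitted).
#' @param n_meas number of replicate measurements averaged; `n_run` number of
#'   runs they span.
#' @param run_term `"variance"` (default, `s_run² / n_run`) or `"linear"`.
#' @return An object of class `"uncertainty_budget"`: `U_meas_rel` and the
#'   `components` (named vector of the variance contributions' square roots).
#' @examples
#' combined_uncertainty(0.061, 0.029, u_vd_rel = 0.018, u_bias_rel = 0.054,
#'                      n_meas = 4, n_run = 1)  # ~14.2 %
#' @export
combined_uncertainty <- function(s_repeat_rel, s_run_rel = 0,
                                 u_vd_rel = 0.018, u_bias_rel = 0,
                                 s_thres_rel = 0, n_meas, n_run = 1,
                                 run_term = c("variance", "linear")) {
  run_term <- match.arg(run_term)
  stopifnot(s_repeat_rel >= 0, s_run_rel >= 0, u_vd_rel >= 0,
            u_bias_rel >= 0, s_thres_rel >= 0, n_meas >= 1, n_run >= 1)
  run_var <- if (run_term == "variance") s_run_rel^2 / n_run
             else (s_run_rel / n_run)^2
  comp <- c(repeatability = s_repeat_rel^2 / n_meas,
            run = run_var,
            droplet_volume = u_vd_rel^2,
            bias = u_bias_rel^2,
            threshold = s_thres_rel^2)
  structure(list(U_meas_rel = 2 * sqrt(sum(comp)),
                 components = sqrt(comp),
                 n_meas = n_meas, n_run = n_run, run_term = run_term),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("expanded measurement uncertainty U_meas,rel = %s (k = 2, mean of %d measurement(s) in %d run(s))\n",
              pct(x$U_meas_rel), x$n_meas, x$n_run))
  comp <- x$components[x$components > 0]
  cat("  standard-uncertainty contributions:",
      paste(sprintf("%s %s", names(comp), pct(comp)), collapse = ", "), "\n")
  invisible(x)
}

#' Linearity of measured against expected concentration
#'
#' Least-squares regression through the origin, `measured = slope * expected`
#' (a dPCR response is proportional by construction, so no intercept is
#' fitted). The coefficient of determination is the through-origin convention,
#' `1 - SS_res / sum(y²)` (uncentred total sum of squares).
#'
#' @param expected,measured numeric vectors of matched concentrations
#'   (`expected > 0`, `>= 1` point).
#' @return A list: `slope`, `r_squared`, `fit` (the underlying `lm`).
#' @examples
#' linearity_fit(c(1, 10, 100), c(2, 20, 200))$slope  # 2
#' @export
linearity_fit <- function(expected, measured) {
  stopifnot(length(expected) == length(measured), length(expected) >= 1L,
            all(is.finite(expected)), all(is.finite(measured)))
  if (all(expected == 0)) stop_ddpcr("expected concentrations are all zero")
  fit <- lm(measured ~ 0 + expected)
  list(slope = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Experimental limit-of-detection summary at one low level
#'
#' Summarises replicate wells measured at one concentration near the expected
#' LOD: when every valid replicate contains at least one positive droplet, the
#' level lies above the LOD (at 60 replicates, a concentration exactly at the
#' 95 %-confidence LOD would on average leave 3 replicates negative).
#'
#' @param replicate_results data frame with columns `P` and `c_pcr` (e.g. from
#'   [analyze_wells()]), one row per valid replicate.
#' @return A list: `n_valid`, `n_positive` (wells with `P >= 1`),
#'   `all_positive`, `mean_c_pcr`, `rel_sd`.
#' @export
lod_experimental <- function(replicate_results) {
  stopifnot(is.data.frame(replicate_results),
            all(c("P", "c_pcr") %in% names(replicate_results)),
            nrow(replicate_results) >= 1L)
  n <- nrow(replicate_results)
  npos <- sum(replicate_results$P >= 1)
  mc <- mean(replicate_results$c_pcr)
  list(n_valid = n, n_positive = npos, all_positive = npos == n,
       mean_c_pcr = mc,
       rel_sd = if (n > 1 && mc > 0) sd(replicate_results$c_pcr) / mc else NA_real_)
}

#' Limit-of-quantification assessment at one level
#'
#' Runs the full uncertainty chain on replicate results of a single low
#' concentration level measured over several runs: precision from the nested
#' design, bias against the certified value of that level (`n_cert = 1`), and
#' the combined expanded uncertainty including the threshold component (which
#' is not negligible at the limits of the working range). The level qualifies
#' as at or above the LOQ when `U_meas_rel` does not exceed the acceptance
#' limit (default 30 % for a mean of four replicates).
#'
#' @param level_results data frame with `run_id` and a concentration column
#'   `c_sample` (or `c_pcr` if `value = "c_pcr"`).
#' @param certified_level one-row data frame (`level_id`, `c_cert`, `U_cert`).
#' @param u_vd_rel,s_thres_rel budget components (fractions).
#' @param n_meas replicates averaged in the reported result (default 4).
#' @param acceptance_limit_rel maximum acceptable expanded uncertainty
#'   (default 0.30).
#' @param value name of the concentration column.
#' @param run_term see [combined_uncertainty()].
#' @return A list: `precision` (`"precision_estimate"`), `bias`
#'   (`"bias_estimate"`), `budget` (`"uncertainty_budget"`), `U_meas_rel`,
#'   `meets_loq`.
#' @export
loq_assess <- function(level_results, certified_level, u_vd_rel = 0.018,
                       s_thres_rel = 0, n_meas = 4,
                       acceptance_limit_rel = 0.30, value = "c_sample",
                       run_term = "variance") {
  stopifnot(is.data.frame(level_results),
            all(c("run_id", value) %in% names(level_results)),
            nrow(certified_level) == 1L)
  runs <- split(level_results[[value]], level_results$run_id)
  if (length(runs) < 2L) stop_ddpcr("LOQ level must be measured over >= 2 runs")
  prec <- precision_from_runs(runs)
  meas <- data.frame(level_id = certified_level$level_id,
                     c_meas = mean(level_results[[value]]))
  bias <- bias_assessment(meas, certified_level,
                          u_precision_rel = prec$u_precision_rel)
  budget <- combined_uncertainty(prec$s_repeat_rel, prec$s_run_rel,
                                 u_vd_rel = u_vd_rel,
                                 u_bias_rel = bias$u_bias_rel,
                                 s_thres_rel = s_thres_rel,
                                 n_meas = n_meas, n_run = 1,
                                 run_term = run_term)
  list(precision = prec, bias = bias, budget = budget,
       U_meas_rel = budget$U_meas_rel,
       meets_loq = budget$U_meas_rel <= acceptance_limit_rel)
}

#' Robustness comparison across perturbed method conditions
#'
#' Compares group means obtained under deliberately perturbed method
#' parameters (annealing temperature, primer/probe concentration, ...) with a
#' reference condition: a deviation is significant when it exceeds the
#' method's expanded measurement uncertainty.
#'
#' @param groups named list of numeric vectors of measured concentrations,
#'   one per condition.
#' @param U_meas_rel relative expanded measurement uncertainty (fraction).
#' @param reference name of the reference condition (default the first).
#' @return A data frame: `condition`, `n`, `mean`, `sd`, `delta_rel` (relative
#'   deviation from the reference mean), `significant`.
#' @examples
#' robustness_compare(list(opt = c(279, 280), minus = c(272, 274)),
#'                    U_meas_rel = 0.142)
#' @export
robustness_compare <- function(groups, U_meas_rel,
                               reference = names(groups)[1L]) {
  stopifnot(is.list(groups), length(groups) >= 2L, U_meas_rel >= 0)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_ddpcr("groups must be named by condition")
  if (any(lengths(groups) == 0L)) stop_ddpcr("empty condition group")
  if (!reference %in% names(groups))
    stop_ddpcr("reference condition not found: ", reference)
  m_ref <- mean(groups[[reference]])
  out <- data.frame(
    condition = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(g) if (length(g) > 1) sd(g) else NA_real_,
                numeric(1)),
    row.names = NULL)
  out$delta_rel <- (out$mean - m_ref) / m_ref
  out$significant <- abs(out$delta_rel) > U_meas_rel
  out
}
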