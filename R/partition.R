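# Partition analysis: cluster estimation, threshold variants, rain
# classification and the three well-exclusion (QC) rules.

#' Estimate negative/positive droplet clusters from amplitudes
#'
#' One-dimensional two-means clustering: droplets are split at an initial
#' threshold (given, or the midpoint of the amplitude range), cluster means
#' are computed, the threshold is moved to the midpoint of the means, and the
#' procedure iterates until the assignment is stable. This automates the
#' analyst's by-eye cluster identification; a manually chosen threshold can
#' still be supplied downstream. A tie at the threshold is assigned to the
#' positive side, consistently with [classify_well()].
#'
#' @param amplitudes numeric vector of droplet fluorescence amplitudes
#'   (length `>= 2`).
#' @param init_threshold optional initial split amplitude.
#' @param max_iter iteration cap (assignment stabilises long before).
#' @return An object of class `"cluster_stats"`: `neg_mean`, `neg_sd`,
#'   `pos_mean`, `pos_sd`, `n_neg`, `n_pos`, `one_cluster` (flag set when all
#'   droplets fall on one side, e.g. identical amplitudes). Single-droplet
#'   clusters get `sd = 0`.
#' @examples
#' estimate_clusters(c(1000, 1000, 6000, 6000))
#' @export
estimate_clusters <- function(amplitudes, init_threshold = NULL,
                              max_iter = 100L) {
  if (length(amplitudes) == 0L) stop_ddpcr("empty amplitude vector")
  if (length(amplitudes) < 2L) stop_ddpcr("need at least 2 droplets")
  stopifnot(is.numeric(amplitudes), all(is.finite(amplitudes)))
  thr <- if (is.null(init_threshold)) mean(range(amplitudes)) else init_threshold
  assign_old <- NULL
  for (i in seq_len(max_iter)) {
    is_pos <- amplitudes >= thr
    if (all(is_pos) || !any(is_pos)) {
      return(structure(list(neg_mean = mean(amplitudes),
                            neg_sd = if (length(amplitudes) > 1) sd(amplitudes) else 0,
                            pos_mean = NA_real_, pos_sd = NA_real_,
                            n_neg = length(amplitudes), n_pos = 0L,
                            one_cluster = TRUE),
                       class = "cluster_stats"))
    }
    if (!is.null(assign_old) && identical(is_pos, assign_old)) break
    assign_old <- is_pos
    thr <- (mean(amplitudes[is_pos]) + mean(amplitudes[!is_pos])) / 2
  }
  neg <- amplitudes[!is_pos]; pos <- amplitudes[is_pos]
  structure(list(neg_mean = mean(neg),
                 neg_sd = if (length(neg) > 1) sd(neg) else 0,
                 pos_mean = mean(pos),
                 pos_sd = if (length(pos) > 1) sd(pos) else 0,
                 n_neg = length(neg), n_pos = length(pos),
                 one_cluster = FALSE),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  if (x$one_cluster) {
    cat(sprintf("single droplet cluster: mean %.4g (SD %.3g), n = %d\n",
                x$neg_mean, x$neg_sd, x$n_neg))
  } else {
    cat(sprintf("droplet clusters: neg %.4g (SD %.3g, n = %d); pos %.4g (SD %.3g, n = %d)\n",
                x$neg_mean, x$neg_sd, x$n_neg, x$pos_mean, x$pos_sd, x$n_pos))
  }
  invisible(x)
}

#' Threshold set from cluster statistics
#'
#' The midpoint threshold sits halfway between the cluster means (the routine
#' analysis threshold). The low threshold is the upper boundary of the
#' negative cluster (`neg_mean + 4 * neg_sd`: all rain counted positive); the
#' high threshold is the lower boundary of the positive cluster
#' (`pos_mean - 4 * pos_sd`: all rain counted negative). Re-analysing wells
#' under these variants bounds the uncertainty of the threshold setting.
#'
#' @param clusters a two-cluster [estimate_clusters()] result, or any list
#'   with `neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`.
#' @return An object of class `"threshold_set"`: `midpoint`, `low`, `high`.
#' @examples
#' make_thresholds(list(neg_mean = 1764, neg_sd = 135,
#'                      pos_mean = 5418, pos_sd = 212))
#' @export
make_thresholds <- function(clusters) {
  if (isTRUE(clusters$one_cluster))
    stop_ddpcr("one-cluster input: no threshold derivable")
  stopifnot(clusters$pos_mean > clusters$neg_mean,
            clusters$neg_sd >= 0, clusters$pos_sd >= 0)
  structure(list(midpoint = (clusters$neg_mean + clusters$pos_mean) / 2,
                 low = clusters$neg_mean + 4 * clusters$neg_sd,
                 high = clusters$pos_mean - 4 * clusters$pos_sd),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: midpoint %.4g, low %.4g, high %.4g\n",
              x$midpoint, x$low, x$high))
  invisible(x)
}

#' Classify the droplets of a well at a threshold
#'
#' Counts positives (`amplitude >= threshold`; ties positive) and rain
#' droplets (amplitude strictly between the low and high cluster boundaries;
#' droplets exactly on a boundary belong to their cluster). With
#' `rain_removal = TRUE`, rain droplets are removed from both the positive and
#' the accepted count before quantification.
#'
#' @param well a `"droplet_well"` with amplitudes present.
#' @param threshold classification amplitude.
#' @param rain_removal drop rain droplets from `P` and `A` (requires `bounds`).
#' @param bounds a [make_thresholds()] result (or list with `low`, `high`)
#'   defining the rain band; optional unless `rain_removal = TRUE`.
#' @return An object of class `"well_result"`: labels plus `P`, `A`, `rain`,
#'   `threshold`, `rain_removal`, `df_sample`, `df_pcr`.
#' @examples
#' w <- simulate_well(sim_config(250), seed = 1)
#' classify_well(w, threshold = 3591)
#' @export
classify_well <- function(well, threshold, rain_removal = FALSE, bounds = NULL) {
  stopifnot(inherits(well, "droplet_well"))
  amp <- well$amplitudes
  if (is.null(amp)) stop_ddpcr("well has no amplitudes; cannot classify")
  if (rain_removal && is.null(bounds))
    stop_ddpcr("rain_removal requires cluster bounds")
  rain <- NA_integer_
  if (!is.null(bounds)) {
    if (bounds$low > bounds$high)
      stop_ddpcr("invalid bounds: low > high")
    is_rain <- amp > bounds$low & amp < bounds$high
    rain <- sum(is_rain)
    if (rain_removal) amp <- amp[!is_rain]
  }
  structure(list(well_id = well$well_id, run_id = well$run_id,
                 level_id = well$level_id, assay_id = well$assay_id,
                 P = sum(amp >= threshold), A = length(amp), rain = rain,
                 threshold = threshold, rain_removal = rain_removal,
                 df_sample = well$df_sample, df_pcr = well$df_pcr),
            class = "well_result")
}

#' @export
print.well_result <- function(x, ...) {
  cat(sprintf("well %s: P = %d, A = %d, rain = %s (threshold %.4g%s)\n",
              x$well_id, x$P, x$A,
              ifelse(is.na(x$rain), "?", x$rain), x$threshold,
              if (x$rain_removal) ", rain removed" else ""))
  invisible(x)
}

#' Well quality control (exclusion rules)
#'
#' Applies the three technical exclusion rules of the validated analysis:
#' \describe{
#'   \item{`min_droplets`}{the well has fewer than `min_droplets` (default
#'     10,000) accepted droplets; exact on the count, needs no amplitudes.}
#'   \item{`amplitude_outlier`}{the well's negative or positive cluster mean
#'     deviates from the plate-median cluster mean by more than `mad_cutoff`
#'     (default 5) plate median absolute deviations — a robust-z
#'     operationalisation of "clearly different from the other wells".}
#'   \item{`low_amplitude_tail`}{at least `tail_fraction` (default 5 %) of the
#'     accepted droplets lie below the negative cluster's lower boundary
#'     (plate negative mean − 4 SD).}
#' }
#' Rules needing amplitudes are reported under `not_evaluated` when the well
#' carries counts only.
#'
#' @param well a `"droplet_well"`.
#' @param plate_clusters plate-level [estimate_clusters()] result (pooled
#'   amplitudes); needed for `low_amplitude_tail`.
#' @param plate_well_stats optional data frame of per-well cluster means for
#'   the plate (columns `neg_mean`, `pos_mean`), needed for
#'   `amplitude_outlier`.
#' @param min_droplets,tail_fraction,mad_cutoff rule parameters.
#' @return An object of class `"qc_report"`: `passed`, `failed_rules`,
#'   `not_evaluated`, `details`.
#' @seealso [qc_plate()] which evaluates all three rules for every well of a
#'   plate.
#' @export
qc_well <- function(well, plate_clusters = NULL, plate_well_stats = NULL,
                    min_droplets = 10000, tail_fraction = 0.05,
                    mad_cutoff = 5) {
  stopifnot(inherits(well, "droplet_well"))
  failed <- character(0); not_eval <- character(0); details <- list()

  details$accepted <- well$accepted
  if (well$accepted < min_droplets) failed <- c(failed, "min_droplets")

  amp <- well$amplitudes
  if (is.null(amp)) {
    not_eval <- c(not_eval, "amplitude_outlier", "low_amplitude_tail")
  } else {
    if (is.null(plate_well_stats) || nrow(plate_well_stats) < 2L) {
      not_eval <- c(not_eval, "amplitude_outlier")
    } else {
      own <- estimate_clusters(amp)
      z <- function(x, ref) {
        m <- median(ref); s <- mad(ref)
        if (!is.finite(s) || s == 0) return(0)
        abs(x - m) / s
      }
      zn <- z(own$neg_mean, plate_well_stats$neg_mean)
      zp <- if (own$one_cluster) 0 else z(own$pos_mean, plate_well_stats$pos_mean)
      details$outlier_z <- c(neg = zn, pos = zp)
      if (max(zn, zp, na.rm = TRUE) > mad_cutoff)
        failed <- c(failed, "amplitude_outlier")
    }
    if (is.null(plate_clusters)) {
      not_eval <- c(not_eval, "low_amplitude_tail")
    } else {
      floor_amp <- plate_clusters$neg_mean - 4 * plate_clusters$neg_sd
      frac <- mean(amp < floor_amp)
      details$low_tail_fraction <- frac
      if (frac >= tail_fraction) failed <- c(failed, "low_amplitude_tail")
    }
  }
  structure(list(passed = length(failed) == 0L, failed_rules = failed,
                 not_evaluated = not_eval, details = details),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC %s%s\n", if (x$passed) "passed" else "FAILED",
              if (length(x$failed_rules))
                paste0(" (", paste(x$failed_rules, collapse = ", "), ")") else ""))
  if (length(x$not_evaluated))
    cat("  not evaluated:", paste(x$not_evaluated, collapse = ", "), "\n")
  invisible(x)
}

#' QC every well of a plate
#'
#' Computes per-well and pooled cluster statistics for the plate, then applies
#' [qc_well()] to each well with the plate context in place.
#'
#' @param wells list of `"droplet_well"` objects from one plate.
#' @param ... rule parameters forwarded to [qc_well()].
#' @return A list of `"qc_report"` objects, one per well.
#' @export
qc_plate <- function(wells, ...) {
  stopifnot(length(wells) >= 1)
  has_amp <- vapply(wells, function(w) !is.null(w$amplitudes), logical(1))
  plate_clusters <- NULL; well_stats <- NULL
  if (any(has_amp)) {
    pooled <- unlist(lapply(wells[has_amp], `[[`, "amplitudes"))
    plate_clusters <- estimate_clusters(pooled)
    per <- lapply(wells[has_amp], function(w) estimate_clusters(w$amplitudes))
    well_stats <- data.frame(
      neg_mean = vapply(per, `[[`, numeric(1), "neg_mean"),
      pos_mean = vapply(per, function(p)
        if (p$one_cluster) NA_real_ else p$pos_mean, numeric(1)))
  }
  lapply(wells, qc_well, plate_clusters = plate_clusters,
         plate_well_stats = well_stats, ...)
}

#' Selectivity: pooled false-positive and false-negative droplet fractions
#'
#' Pools classified counts over matrix-blank wells (no target: any positive
#' droplet is a false positive) and high-concentration positive-control wells
#' (any negative droplet is counted as a false negative), both classified at
#' the same threshold.
#'
#' @param blank_results,positive_results lists of `"well_result"` objects (or
#'   data frames with `P` and `A` columns).
#' @return A list with `false_positive_fraction` (blank positives over blank
#'   accepted) and `false_negative_fraction` (control negatives over control
#'   accepted), as fractions.
#' @examples
#' blanks <- data.frame(P = 0, A = 61275)
#' ctrls  <- data.frame(P = 57895 - 33, A = 57895)
#' selectivity_metrics(blanks, ctrls)
#' @export
selectivity_metrics <- function(blank_results, positive_results) {
  pa <- function(x) {
    if (is.data.frame(x)) return(list(P = sum(x$P), A = sum(x$A)))
    list(P = sum(vapply(x, `[[`, numeric(1), "P")),
         A = sum(vapply(x, `[[`, numeric(1), "A")))
  }
  b <- pa(blank_results); p <- pa(positive_results)
  if (b$A == 0 || p$A == 0) stop_ddpcr("zero accepted droplets in a group")
  list(false_positive_fraction = b$P / b$A,
       false_negative_fraction = (p$A - p$P) / p$A)
}

#' Classify, QC and quantify a plate of wells into a results table
#'
#' The per-plate analysis pipeline: estimate clusters from the pooled plate
#' amplitudes (or accept a manual threshold), derive the threshold set, apply
#' QC, classify every well under the requested threshold variant and convert
#' counts to concentrations.
#'
#' @param wells list of `"droplet_well"` objects (with amplitudes, or counts
#'   only in which case classification is skipped and recorded counts are
#'   used).
#' @param variant one of `"midpoint"`, `"low"`, `"high"`, `"rain_removal"`.
#' @param manual_threshold optional plate-wide threshold overriding the
#'   estimated midpoint (the low/high rain band still comes from the clusters).
#' @param droplet_volume_nl droplet volume (nL) for quantification.
#' @param qc run the exclusion rules and flag failing wells.
#' @param ... QC rule parameters passed on to [qc_plate()].
#' @return A data frame with one row per well: labels, `variant`, `P`, `A`,
#'   `rain`, `threshold`, `qc_passed`, `failed_rules`, `c_pcr`, `c_sample`.
#' @export
analyze_wells <- function(wells, variant = c("midpoint", "low", "high",
                                             "rain_removal"),
                          manual_threshold = NULL, droplet_volume_nl = 0.834,
                          qc = TRUE, ...) {
  variant <- match.arg(variant)
  stopifnot(length(wells) >= 1)
  has_amp <- vapply(wells, function(w) !is.null(w$amplitudes), logical(1))

  thr_set <- NULL
  if (any(has_amp)) {
    pooled <- unlist(lapply(wells[has_amp], `[[`, "amplitudes"))
    thr_set <- make_thresholds(estimate_clusters(pooled))
    if (!is.null(manual_threshold)) thr_set$midpoint <- manual_threshold
  } else if (variant != "midpoint") {
    stop_ddpcr("threshold variants need amplitudes; counts-only wells carry ",
               "a fixed classification")
  }

  reports <- if (qc) qc_plate(wells, ...) else NULL

  rows <- lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    if (has_amp[i]) {
      thr <- switch(variant, midpoint = thr_set$midpoint, low = thr_set$low,
                    high = thr_set$high, rain_removal = thr_set$midpoint)
      res <- classify_well(w, thr, rain_removal = variant == "rain_removal",
                           bounds = thr_set)
    } else {
      res <- list(well_id = w$well_id, run_id = w$run_id,
                  level_id = w$level_id, assay_id = w$assay_id,
                  P = w$positives, A = w$accepted, rain = NA_integer_,
                  threshold = NA_real_, df_sample = w$df_sample,
                  df_pcr = w$df_pcr)
    }
    q <- concentration_from_counts(res$P, res$A, droplet_volume_nl,
                                   df_sample = res$df_sample,
                                   df_pcr = res$df_pcr, allow_saturated = TRUE)
    data.frame(well_id = res$well_id, run_id = res$run_id,
               level_id = res$level_id, assay_id = res$assay_id,
               variant = variant, P = res$P, A = res$A, rain = res$rain,
               threshold = res$threshold,
               qc_passed = if (qc) reports[[i]]$passed else NA,
               failed_rules = if (qc)
                 paste(reports[[i]]$failed_rules, collapse = ";") else "",
               c_pcr = q$c_pcr, c_sample = q$c_sample,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
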