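# Plate files, study configuration and the end-to-end validation runner.
# Plates are plain CSV (header row, UTF-8, '.' decimal separator): one row per
# well, with an optional companion amplitude CSV (one row per droplet) so that
# count-only workflows stay light. Numeric output is written at 6 significant
# digits; row order is deterministic.

plate_columns <- c("well_id", "run_id", "level_id", "assay_id", "accepted",
                   "positives", "df_sample", "df_pcr")

fmt6 <- function(x) {
  if (is.numeric(x)) format(signif(x, 6), trim = TRUE, scientific = FALSE)
  else x
}

#' Read a droplet plate export
#'
#' Reads a per-well CSV (columns `well_id` and `accepted` required;
#' `run_id`, `level_id`, `assay_id`, `positives`, `df_sample`, `df_pcr`
#' optional) and, if given, a companion amplitude CSV with columns `well_id`
#' and `amplitude` (one row per accepted droplet). Unknown extra columns load
#' with a warning; malformed rows are reported with their row numbers.
#'
#' @param path path to the plate CSV.
#' @param amplitude_path optional path to the companion amplitude CSV.
#' @return A list of `"droplet_well"` objects.
#' @export
read_plate <- function(path, amplitude_path = NULL) {
  if (!file.exists(path)) stop_ddpcr("plate file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "accepted")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_ddpcr("plate file lacks required column(s): ",
               paste(miss, collapse = ", "))
  extra <- setdiff(names(x), plate_columns)
  if (length(extra))
    warning("ignoring unknown plate column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$well_id))
    stop_ddpcr("duplicated well_id(s) in plate: ",
               paste(unique(x$well_id[duplicated(x$well_id)]), collapse = ", "))
  bad <- which(!is.finite(x$accepted) | x$accepted < 0)
  if (length(bad))
    stop_ddpcr("invalid accepted count at row(s): ", paste(bad, collapse = ", "))
  if ("positives" %in% names(x)) {
    bad <- which(!is.na(x$positives) & (x$positives < 0 | x$positives > x$accepted))
    if (length(bad))
      stop_ddpcr("positives > accepted (or negative) for well(s): ",
                 paste(x$well_id[bad], collapse = ", "))
  }

  amps <- NULL
  if (!is.null(amplitude_path)) {
    if (!file.exists(amplitude_path))
      stop_ddpcr("amplitude file not found: ", amplitude_path)
    a <- read.csv(amplitude_path, stringsAsFactors = FALSE)
    if (!all(c("well_id", "amplitude") %in% names(a)))
      stop_ddpcr("amplitude file needs columns well_id, amplitude")
    unknown <- setdiff(unique(a$well_id), x$well_id)
    if (length(unknown))
      stop_ddpcr("amplitude file references unknown well(s): ",
                 paste(unknown, collapse = ", "))
    amps <- split(a$amplitude, a$well_id)
  }

  lapply(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    amp <- if (!is.null(amps)) amps[[r$well_id]] else NULL
    if (!is.null(amp) && length(amp) != r$accepted)
      stop_ddpcr("well ", r$well_id, ": ", length(amp),
                 " amplitudes but accepted = ", r$accepted)
    structure(list(
      well_id = r$well_id,
      run_id = if ("run_id" %in% names(r)) as.character(r$run_id) else "run1",
      level_id = if ("level_id" %in% names(r)) as.character(r$level_id) else "L1",
      assay_id = if ("assay_id" %in% names(r)) as.character(r$assay_id) else "assay1",
      accepted = as.integer(r$accepted),
      positives = if ("positives" %in% names(r)) as.integer(r$positives)
                  else NA_integer_,
      amplitudes = amp,
      df_sample = if ("df_sample" %in% names(r)) as.numeric(r$df_sample) else 1,
      df_pcr = if ("df_pcr" %in% names(r)) as.numeric(r$df_pcr) else 1,
      meta = list()), class = "droplet_well")
  })
}

#' Write a droplet plate (and ground truth) to CSV/JSON
#'
#' Writes the per-well counts CSV, optionally the companion amplitude CSV, and
#' optionally a ground-truth JSON sidecar (true concentration, true positives
#' and rain count per well, the seed) for simulated plates. Output is
#' deterministic: stable row order, numbers at 6 significant digits.
#'
#' @param wells list of `"droplet_well"` objects.
#' @param path output path for the plate CSV.
#' @param amplitude_path optional output path for the amplitude CSV.
#' @param truth_path optional output path for the ground-truth JSON.
#' @param seed seed to record in the ground truth, if any.
#' @return Invisibly, `path`.
#' @export
write_plate <- function(wells, path, amplitude_path = NULL, truth_path = NULL,
                        seed = NULL) {
  stopifnot(length(wells) >= 1)
  tab <- do.call(rbind, lapply(wells, function(w)
    data.frame(well_id = w$well_id, run_id = w$run_id, level_id = w$level_id,
               assay_id = w$assay_id, accepted = w$accepted,
               positives = w$positives, df_sample = w$df_sample,
               df_pcr = w$df_pcr, stringsAsFactors = FALSE)))
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], fmt6)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)

  if (!is.null(amplitude_path)) {
    a <- do.call(rbind, lapply(wells, function(w) {
      if (is.null(w$amplitudes)) return(NULL)
      data.frame(well_id = w$well_id, amplitude = fmt6(w$amplitudes),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(a)) stop_ddpcr("no amplitudes to write")
    write.csv(a, amplitude_path, row.names = FALSE, quote = FALSE)
  }

  if (!is.null(truth_path)) {
    truth <- list(
      seed = seed,
      wells = lapply(wells, function(w)
        list(well_id = w$well_id,
             true_concentration = w$meta$true_concentration,
             true_positives = w$meta$true_positives,
             n_rain = w$meta$n_rain)))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Study configuration for a validation run
#'
#' Bundles the analysis parameters of a validation study: the certified
#' levels, the droplet volume and its relative standard uncertainty, the QC
#' rule parameters, the threshold mode and the LOQ acceptance limit. Defaults
#' reproduce the bundled BCR-ABL/ERM-AD623 validation analysis.
#'
#' @param certified certified levels data frame (default [erm_ad623()]).
#' @param droplet_volume_nl droplet volume (nL, default 0.834).
#' @param u_vd_rel relative droplet-volume uncertainty (default 0.018).
#' @param min_droplets,tail_fraction,mad_cutoff QC rule parameters, see
#'   [qc_well()].
#' @param threshold `"auto"` or a numeric manual plate threshold.
#' @param loq_acceptance_limit_rel maximum acceptable expanded uncertainty at
#'   the LOQ (default 0.30).
#' @param n_meas,n_run design of the routine reported result.
#' @return An object of class `"study_config"` (validated list).
#' @export
study_config <- function(certified = erm_ad623(), droplet_volume_nl = 0.834,
                         u_vd_rel = 0.018, min_droplets = 10000,
                         tail_fraction = 0.05, mad_cutoff = 5,
                         threshold = "auto",
                         loq_acceptance_limit_rel = 0.30,
                         n_meas = 4, n_run = 1) {
  stopifnot(is.data.frame(certified),
            all(c("level_id", "c_cert", "U_cert") %in% names(certified)),
            all(certified$c_cert > 0), all(certified$U_cert >= 0),
            droplet_volume_nl > 0, u_vd_rel >= 0, min_droplets >= 0,
            tail_fraction >= 0, tail_fraction <= 1, mad_cutoff > 0,
            loq_acceptance_limit_rel > 0, n_meas >= 1, n_run >= 1)
  if (!(identical(threshold, "auto") ||
        (is.numeric(threshold) && length(threshold) == 1L)))
    stop_ddpcr("threshold must be \"auto\" or a single amplitude")
  structure(list(certified = certified,
                 droplet_volume_nl = droplet_volume_nl, u_vd_rel = u_vd_rel,
                 min_droplets = min_droplets, tail_fraction = tail_fraction,
                 mad_cutoff = mad_cutoff, threshold = threshold,
                 loq_acceptance_limit_rel = loq_acceptance_limit_rel,
                 n_meas = n_meas, n_run = n_run),
            class = "study_config")
}

#' Read or write a study configuration as YAML
#'
#' The YAML file may set any [study_config()] parameter; `certified` is given
#' as a list of `{level_id, c_cert, U_cert}` records and defaults to the
#' bundled ERM-AD623 values when absent.
#'
#' @param path YAML file path.
#' @return `read_study_config()` returns a `"study_config"`;
#'   `write_study_config()` invisibly returns `path`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_ddpcr("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_ddpcr("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$certified))
    y$certified <- do.call(rbind, lapply(y$certified, as.data.frame))
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @param config a `"study_config"` to serialise.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- unclass(config)
  y$certified <- lapply(seq_len(nrow(config$certified)), function(i)
    as.list(config$certified[i, c("level_id", "c_cert", "U_cert")]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run a full validation analysis from plate files
#'
#' Chains the whole pipeline: read plates (counts, plus amplitudes when
#' available), apply QC and thresholding per plate, quantify, estimate
#' per-level precision (levels with fewer than two runs are skipped with a
#' warning), pool, assess bias against the configured certified levels, build
#' the combined uncertainty budget, and write a JSON report plus an accuracy
#' table CSV. Every excluded well is reported with the rule it failed; wells
#' in equal QC-passed plus QC-excluded.
#'
#' @param plate_paths character vector of plate CSV paths (`>= 1`).
#' @param config a `"study_config"` (or a path to a YAML config).
#' @param out_dir output directory (created if needed); set `NULL` to skip
#'   writing files.
#' @param amplitude_paths optional character vector parallel to `plate_paths`
#'   (`NA` entries for count-only plates).
#' @return Invisibly, a list: `fit` (the [ddpcr_validation()] object),
#'   `results` (per-well table), `excluded` (table of excluded wells), and the
#'   output file paths.
#' @export
run_validation <- function(plate_paths, config = study_config(),
                           out_dir = NULL, amplitude_paths = NULL) {
  if (length(plate_paths) == 0L) stop_ddpcr("no plate files given")
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  if (is.null(amplitude_paths)) amplitude_paths <- rep(NA_character_,
                                                       length(plate_paths))
  stopifnot(length(amplitude_paths) == length(plate_paths))

  results <- do.call(rbind, lapply(seq_along(plate_paths), function(i) {
    ap <- amplitude_paths[i]
    wells <- read_plate(plate_paths[i],
                        amplitude_path = if (is.na(ap)) NULL else ap)
    analyze_wells(wells,
                  manual_threshold = if (identical(config$threshold, "auto"))
                    NULL else config$threshold,
                  droplet_volume_nl = config$droplet_volume_nl,
                  min_droplets = config$min_droplets,
                  tail_fraction = config$tail_fraction,
                  mad_cutoff = config$mad_cutoff)
  }))

  excluded <- results[!results$qc_passed, , drop = FALSE]
  for (i in seq_len(nrow(excluded)))
    message("excluded well ", excluded$well_id[i], " (",
            excluded$failed_rules[i], ")")
  valid <- results[results$qc_passed & !is.na(results$c_sample), , drop = FALSE]
  if (nrow(valid) == 0L) stop_ddpcr("no valid wells after QC")

  fit <- ddpcr_validation(valid, certified = config$certified,
                          u_vd_rel = config$u_vd_rel,
                          n_meas = config$n_meas, n_run = config$n_run)

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    s <- summary(fit)
    paths$accuracy_csv <- file.path(out_dir, "accuracy_table.csv")
    tab <- s$table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], fmt6)
    write.csv(tab, paths$accuracy_csv, row.names = FALSE, quote = FALSE)

    paths$report_json <- file.path(out_dir, "report.json")
    report <- list(
      n_wells = nrow(results), n_valid = nrow(valid),
      n_excluded = nrow(excluded),
      excluded = if (nrow(excluded))
        excluded[, c("well_id", "failed_rules")] else list(),
      pooled = as.list(fit$pooled),
      mean_bias_rel = fit$bias$mean_bias_rel,
      u_bias_rel = fit$bias$u_bias_rel,
      U_bias_rel = fit$bias$U_bias_rel,
      bias_significant = fit$bias$significant,
      s_assay_pooled_rel = if (is.null(fit$assay)) NULL
                           else fit$assay$s_assay_pooled_rel,
      U_meas_rel = fit$budget$U_meas_rel,
      components = as.list(fit$budget$components))
    jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(list(fit = fit, results = results, excluded = excluded,
                 paths = paths))
}
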