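# Absolute quantification: Poisson partition estimator and gravimetric
# dilution factors.

#' Copy number concentration from droplet counts
#'
#' Converts positive/accepted droplet counts to absolute copy number
#' concentrations. The estimated number of template copies in the analysed
#' droplets is `ln(1 - P/A) / ln(1 - 1/A)`; dividing by the analysed volume
#' `A * Vd` gives the PCR-mix concentration, and the sample concentration
#' follows by multiplying with the dilution factors:
#' `c_sample = df_sample * df_pcr * c_pcr`. Natural logarithms are used
#' throughout (any base cancels in the ratio, but the large-`A` identity
#' `copies ≈ -A * ln(1 - P/A)` holds only for the natural log). The droplet
#' volume is given in nanolitres and converted internally to microlitres, so
#' concentrations are in copies/µL.
#'
#' A saturated well (`P == A`) has unbounded estimated concentration and is an
#' error unless `allow_saturated = TRUE`, in which case `NA` is returned with
#' `saturated = TRUE`.
#'
#' @param P,A positive and accepted droplet counts (vectorised, `0 <= P <= A`,
#'   `A >= 2`).
#' @param droplet_volume_nl droplet volume in nanolitres (default 0.834).
#' @param df_sample,df_pcr dilution factors (`>= 1`).
#' @param allow_saturated return `NA` instead of failing for `P == A` wells.
#' @return A data frame with columns `c_pcr`, `c_sample` (copies/µL) and
#'   `saturated` (logical).
#' @examples
#' concentration_from_counts(3000, 17000)            # ~232.8 copies/uL
#' concentration_from_counts(10000, 20000)           # ~831.1 copies/uL
#' concentration_from_counts(0, 17000)$c_pcr         # 0
#' @export
concentration_from_counts <- function(P, A, droplet_volume_nl = 0.834,
                                      df_sample = 1, df_pcr = 1,
                                      allow_saturated = FALSE) {
  stopifnot(is.numeric(P), is.numeric(A), droplet_volume_nl > 0,
            all(df_sample >= 1), all(df_pcr >= 1))
  n <- max(length(P), length(A))
  P <- rep_len(P, n); A <- rep_len(A, n)
  if (any(A < 2)) stop_ddpcr("A must be >= 2")
  if (any(P < 0) || any(P > A)) stop_ddpcr("P must satisfy 0 <= P <= A")
  saturated <- P == A
  if (any(saturated) && !allow_saturated)
    stop_ddpcr("saturated well(s) with P == A: concentration is unbounded")
  vd_ul <- droplet_volume_nl * 1e-3
  copies <- rep(NA_real_, n)
  ok <- !saturated
  copies[ok] <- log1p(-P[ok] / A[ok]) / log1p(-1 / A[ok])
  c_pcr <- copies / (A * vd_ul)
  data.frame(c_pcr = c_pcr, c_sample = df_sample * df_pcr * c_pcr,
             saturated = saturated)
}

#' Gravimetric dilution factor
#'
#' Dilution factor of a gravimetrically prepared mixture: masses are converted
#' to volumes via their densities, and the factor is total volume over sample
#' volume. For the PCR step (sample combined with the pre-sample mix) use the
#' pre-sample mix mass and density (default density 1.0353 g/mL, determined by
#' replicate weighing of a calibrated 100 µL pipette volume; the aqueous
#' sample buffer defaults to 1.0 g/mL).
#'
#' @param mass_sample_g mass of the DNA sample (g), `> 0`.
#' @param mass_added_g mass of the diluent or pre-sample mix (g), `>= 0`.
#' @param density_sample_g_per_ml,density_added_g_per_ml densities (g/mL).
#' @return The dimensionless dilution factor (`>= 1`).
#' @examples
#' gravimetric_dilution_factor(1, 9)                        # 10
#' gravimetric_dilution_factor(2, 18.636,
#'   density_added_g_per_ml = 1.0353)                       # ~10 (PCR step)
#' @export
gravimetric_dilution_factor <- function(mass_sample_g, mass_added_g,
                                        density_sample_g_per_ml = 1.0,
                                        density_added_g_per_ml = 1.0) {
  stopifnot(is.numeric(mass_sample_g), is.numeric(mass_added_g),
            density_sample_g_per_ml > 0, density_added_g_per_ml > 0)
  if (mass_sample_g <= 0) stop_ddpcr("sample mass must be > 0")
  if (mass_added_g < 0) stop_ddpcr("added mass must be >= 0")
  v_sample <- mass_sample_g / density_sample_g_per_ml
  v_added <- mass_added_g / density_added_g_per_ml
  (v_sample + v_added) / v_sample
}

#' Quantify a simulated study or a list of wells from their counts
#'
#' Convenience wrapper applying [concentration_from_counts()] to every well of
#' a [simulate_validation_study()] result (counts-only wells) or to a list of
#' classified well results.
#'
#' @param study a `"ddpcr_study"` object with counts-only wells.
#' @param droplet_volume_nl droplet volume (nL); defaults to the study config.
#' @return The study design data frame with `P`, `A`, `c_pcr` and `c_sample`
#'   columns appended.
#' @examples
#' st <- simulate_validation_study(c(L = 250), n_runs = 2, replicates = 3,
#'                                 config = sim_config(250),
#'                                 keep_amplitudes = FALSE, seed = 1)
#' head(quantify_study(st))
#' @export
quantify_study <- function(study, droplet_volume_nl = study$config$droplet_volume_nl) {
  stopifnot(inherits(study, "ddpcr_study"))
  P <- vapply(study$wells, function(w) {
    if (is.na(w$positives))
      stop_ddpcr("wells carry amplitudes; classify them first (see analyze_wells)")
    as.numeric(w$positives)
  }, numeric(1))
  A <- vapply(study$wells, function(w) as.numeric(w$accepted), numeric(1))
  dfs <- vapply(study$wells, function(w) w$df_sample * w$df_pcr, numeric(1))
  q <- concentration_from_counts(P, A, droplet_volume_nl, allow_saturated = TRUE)
  out <- study$design
  out$P <- P; out$A <- A
  out$c_pcr <- q$c_pcr
  out$c_sample <- dfs * q$c_pcr
  out
}
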