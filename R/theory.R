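# Closed-form stochastic-effect predictions for digital PCR: the Poisson
# sampling component, the binomial partition (distribution) component, their
# combination over a concentration grid, and the theoretical minimum LOD.

#' Relative SD from Poisson sampling of the template into the PCR mix
#'
#' When on average `T_sampled` template copies are pipetted into the PCR mix,
#' the realised number is Poisson distributed, so the relative SD of the
#' sampled amount is `1 / sqrt(T_sampled)`.
#'
#' @param T_sampled expected number of copies sampled (`> 0`), vectorised.
#' @return Relative SD (fraction).
#' @examples
#' sampling_rel_std(100)  # 0.10
#' @export
sampling_rel_std <- function(T_sampled) {
  stopifnot(is.numeric(T_sampled))
  if (any(T_sampled <= 0)) stop_ddpcr("T_sampled must be > 0")
  1 / sqrt(T_sampled)
}

#' Relative SD from the distribution of copies over the droplets
#'
#' Delta-method relative SD of the Poisson-corrected concentration estimator.
#' With mean occupancy `lambda` copies per droplet, a droplet is positive with
#' probability `p = 1 - exp(-lambda)`; the estimator `-ln(1 - P/A)` applied to
#' `P ~ Binomial(A, p)` has, to first order, variance
#' `p (1 - p) / (A (1 - p)^2)`, giving
#' `s = sqrt((exp(lambda) - 1) / A) / lambda` as relative SD. In the
#' low-occupancy limit this tends to `1 / sqrt(A * lambda)`, the Poisson CV of
#' the expected copy count in the analysed droplets.
#'
#' @param lambda_per_droplet mean copies per droplet (`> 0`), vectorised.
#' @param A number of analysed droplets (`>= 2`).
#' @return Relative SD (fraction).
#' @examples
#' distribution_rel_std(1, 20000)  # ~0.00927
#' @export
distribution_rel_std <- function(lambda_per_droplet, A) {
  stopifnot(is.numeric(lambda_per_droplet), A >= 2)
  if (any(lambda_per_droplet <= 0)) stop_ddpcr("lambda must be > 0")
  sqrt(expm1(lambda_per_droplet) / A) / lambda_per_droplet
}

#' Stochastic-effect curve over a concentration grid
#'
#' Combines the sampling and distribution components in quadrature for each
#' concentration: `T_sampled = c * sampled_volume`,
#' `lambda = c * Vd` (with `Vd` converted from nL to µL), `T_A = lambda * A`.
#' The combined relative SD is U-shaped over the working range: the sampling
#' and distribution terms blow up at low concentrations, and the distribution
#' term rises again as droplets saturate at high concentration.
#'
#' @param c_grid PCR-mix concentrations (copies/µL, `> 0`).
#' @param A analysed droplets per well (default 17,000).
#' @param droplet_volume_nl droplet volume (nL, default 0.834).
#' @param sampled_volume_ul volume of PCR mix prepared per well (µL, default
#'   20, the droplet-generator load).
#' @return A data frame with columns `c_pcr`, `T_sampled`, `lambda`, `T_A`,
#'   `s_sampling_rel`, `s_distribution_rel`, `s_stochastic_rel` (fractions).
#' @examples
#' stochastic_curve(c(2.5, 26, 255, 2575))
#' @export
stochastic_curve <- function(c_grid, A = 17000, droplet_volume_nl = 0.834,
                             sampled_volume_ul = 20) {
  stopifnot(all(c_grid > 0), A >= 2, droplet_volume_nl > 0,
            sampled_volume_ul > 0)
  lambda <- c_grid * droplet_volume_nl * 1e-3
  T_sampled <- c_grid * sampled_volume_ul
  s_samp <- sampling_rel_std(T_sampled)
  s_dist <- distribution_rel_std(lambda, A)
  data.frame(c_pcr = c_grid, T_sampled = T_sampled, lambda = lambda,
             T_A = lambda * A, s_sampling_rel = s_samp,
             s_distribution_rel = s_dist,
             s_stochastic_rel = sqrt(s_samp^2 + s_dist^2))
}

#' Theoretical minimum limit of detection
#'
#' The lowest concentration detectable with confidence `1 - alpha` from the
#' analysed droplets alone: at the LOD, the probability that the analysed
#' volume `A * Vd` contains no copy at all equals `alpha`, so
#' `c_lod = -ln(alpha) / (A * Vd)` (copies/µL).
#'
#' @param A analysed droplets (`>= 1`), vectorised.
#' @param droplet_volume_nl droplet volume (nL).
#' @param alpha accepted false-negative probability (default 0.05).
#' @return LOD in copies/µL.
#' @examples
#' theoretical_min_lod(15000)  # ~0.24 copies/uL
#' theoretical_min_lod(10000)  # ~0.36 copies/uL
#' @export
theoretical_min_lod <- function(A, droplet_volume_nl = 0.834, alpha = 0.05) {
  stopifnot(is.numeric(A), all(A >= 1), droplet_volume_nl > 0)
  if (alpha <= 0 || alpha >= 1) stop_ddpcr("alpha must be in (0, 1)")
  -log(alpha) / (A * droplet_volume_nl * 1e-3)
}

#' Simulated maximum threshold uncertainty as a function of rain
#'
#' For each rain fraction on a grid, simulates replicate wells with
#' amplitudes, re-analyses every well under the four threshold variants
#' (midpoint, low, high, rain removal) with the cluster boundaries of the
#' generating configuration, and applies the within-replicate ANOVA of
#' [threshold_variability()]. With no rain all variants agree exactly and the
#' component is zero; it grows with the rain fraction.
#'
#' @param rain_fraction_grid rain fractions to scan (each in `[0, 1)`).
#' @param c_pcr PCR-mix concentration to simulate at (copies/µL).
#' @param config a [sim_config()] template (its concentration and rain
#'   fraction are overridden).
#' @param n_reps replicate wells per grid point (`>= 2`).
#' @param seed optional integer seed.
#' @return A data frame: `rain_fraction`, `s_thres_rel`, `mean_rain_droplets`.
#' @export
max_threshold_uncertainty_sim <- function(rain_fraction_grid, c_pcr,
                                          config = sim_config(c_pcr),
                                          n_reps = 8, seed = NULL) {
  stopifnot(all(rain_fraction_grid >= 0), all(rain_fraction_grid < 1),
            n_reps >= 2)
  bounds <- make_thresholds(list(neg_mean = config$neg_cluster[1],
                                 neg_sd = config$neg_cluster[2],
                                 pos_mean = config$pos_cluster[1],
                                 pos_sd = config$pos_cluster[2]))
  vd <- config$droplet_volume_nl
  with_seed(seed, {
    rows <- lapply(rain_fraction_grid, function(rf) {
      cfg <- config
      cfg$true_concentration <- c_pcr
      cfg$rain_fraction <- rf
      cfg <- do.call(sim_config, cfg[setdiff(names(cfg), NULL)])
      wells <- simulate_plate(cfg, n_wells = n_reps)
      per_rep <- lapply(wells, function(w) {
        vapply(c("midpoint", "low", "high", "rain_removal"), function(v) {
          thr <- if (v == "high") bounds$high
                 else if (v == "low") bounds$low else bounds$midpoint
          res <- classify_well(w, thr, rain_removal = v == "rain_removal",
                               bounds = bounds)
          concentration_from_counts(res$P, res$A, vd,
                                    allow_saturated = TRUE)$c_pcr
        }, numeric(1))
      })
      rain_counts <- vapply(wells, function(w) w$meta$n_rain, numeric(1))
      data.frame(rain_fraction = rf,
                 s_thres_rel = threshold_variability(per_rep)$s_thres_rel,
                 mean_rain_droplets = mean(rain_counts))
    })
    do.call(rbind, rows)
  })
}
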