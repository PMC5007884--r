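#' Configuration for the droplet-plate simulator
#'
#' Collects the generative parameters of the droplet digital PCR simulator:
#' template concentration in the PCR mix, accepted-droplet count distribution,
#' droplet volume and its relative uncertainty, the fluorescence amplitude
#' clusters of negative and positive droplets, the expected fraction of "rain"
#' droplets (intermediate amplitudes), and the sizes of multiplicative run and
#' assay effects.
#'
#' Defaults reflect a validated BCR-ABL ddPCR method: around 17,000 accepted
#' droplets per well, a droplet volume of 0.834 nL with 1.8 % relative standard
#' uncertainty, a negative cluster at amplitude 1764 (SD 135) and a positive
#' cluster at 5418 (SD 212). Cluster boundaries are taken as mean ± 4 SD;
#' simulated cluster amplitudes are truncated at those boundaries so that the
#' boundaries contain the whole cluster by construction, and rain droplets are
#' drawn uniformly strictly between the negative upper and positive lower
#' boundary (no mechanistic rain model is assumed).
#'
#' @param true_concentration template concentration in the PCR mix
#'   (copies/µL), `>= 0`.
#' @param droplet_count_mean,droplet_count_sd mean and SD of the accepted
#'   droplet count per well; counts are drawn from a normal distribution
#'   truncated below at 1 and rounded to integer.
#' @param droplet_volume_nl nominal droplet volume in nanolitres.
#' @param droplet_volume_rel_sd relative standard uncertainty of the droplet
#'   volume (fraction); carried into the uncertainty budget and optionally used
#'   as a between-run volume perturbation.
#' @param neg_cluster,pos_cluster length-2 numeric vectors `c(mean, sd)` of the
#'   fluorescence amplitude clusters.
#' @param rain_fraction expected fraction of accepted droplets re-assigned an
#'   intermediate ("rain") amplitude, in `[0, 1]`.
#' @param run_effect_rel_sd relative SD of the multiplicative per-run
#'   concentration factor.
#' @param assay_effect_rel_sd relative SD of the multiplicative per-assay
#'   concentration factor.
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(true_concentration = 250)
#' cfg
#' @export
sim_config <- function(true_concentration,
                       droplet_count_mean = 17000,
                       droplet_count_sd = 1000,
                       droplet_volume_nl = 0.834,
                       droplet_volume_rel_sd = 0.018,
                       neg_cluster = c(mean = 1764, sd = 135),
                       pos_cluster = c(mean = 5418, sd = 212),
                       rain_fraction = 0,
                       run_effect_rel_sd = 0,
                       assay_effect_rel_sd = 0) {
  stopifnot(is.numeric(true_concentration), length(true_concentration) == 1L,
            is.finite(true_concentration), true_concentration >= 0,
            droplet_count_mean > 0, droplet_count_sd >= 0,
            droplet_volume_nl > 0, droplet_volume_rel_sd >= 0,
            length(neg_cluster) == 2L, length(pos_cluster) == 2L,
            neg_cluster[2] >= 0, pos_cluster[2] >= 0,
            rain_fraction >= 0, rain_fraction <= 1,
            run_effect_rel_sd >= 0, assay_effect_rel_sd >= 0)
  neg_cluster <- unname(as.numeric(neg_cluster))
  pos_cluster <- unname(as.numeric(pos_cluster))
  if (pos_cluster[1] <= neg_cluster[1])
    stop_ddpcr("positive cluster mean must exceed negative cluster mean")
  low  <- neg_cluster[1] + 4 * neg_cluster[2]
  high <- pos_cluster[1] - 4 * pos_cluster[2]
  if (rain_fraction > 0 && low >= high)
    stop_ddpcr("cluster boundaries overlap (neg mean + 4 SD >= pos mean - 4 SD): ",
               "no room for rain droplets")
  structure(list(true_concentration = true_concentration,
                 droplet_count_mean = droplet_count_mean,
                 droplet_count_sd = droplet_count_sd,
                 droplet_volume_nl = droplet_volume_nl,
                 droplet_volume_rel_sd = droplet_volume_rel_sd,
                 neg_cluster = neg_cluster,
                 pos_cluster = pos_cluster,
                 rain_fraction = rain_fraction,
                 run_effect_rel_sd = run_effect_rel_sd,
                 assay_effect_rel_sd = assay_effect_rel_sd),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ddPCR simulation config\n")
  cat(sprintf("  c_PCR: %g copies/uL, droplets ~ %g (SD %g), Vd %g nL (u_rel %s)\n",
              x$true_concentration, x$droplet_count_mean, x$droplet_count_sd,
              x$droplet_volume_nl, pct(x$droplet_volume_rel_sd)))
  cat(sprintf("  clusters: neg %g (SD %g), pos %g (SD %g); rain fraction %g\n",
              x$neg_cluster[1], x$neg_cluster[2],
              x$pos_cluster[1], x$pos_cluster[2], x$rain_fraction))
  cat(sprintf("  run effect SD %s, assay effect SD %s\n",
              pct(x$run_effect_rel_sd), pct(x$assay_effect_rel_sd)))
  invisible(x)
}

# Cluster boundaries (negative upper, positive lower) at mean +/- 4 SD.
cluster_bounds <- function(config) {
  c(low  = config$neg_cluster[1] + 4 * config$neg_cluster[2],
    high = config$pos_cluster[1] - 4 * config$pos_cluster[2])
}
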