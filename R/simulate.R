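# Synthetic droplet-plate generator. The generative model is two-stage
# Poisson/multinomial: the number of template copies landing in the analysed
# droplets is Poisson(c * A * Vd), and those copies are scattered uniformly
# at random over the A droplets, so per-droplet occupancies are Poisson(c*Vd).

# normal truncated below at `lower`, via inverse-CDF
rtnorm_min <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  a <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(runif(n, min = a, max = 1))
}

# normal truncated at mean +/- 4 sd (cluster amplitudes)
rtnorm_4sd <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  p <- pnorm(c(-4, 4))
  mean + sd * qnorm(runif(n, min = p[1], max = p[2]))
}

#' Simulate a single ddPCR well
#'
#' Draws one well from the generative model: the accepted droplet count `A`
#' from a rounded truncated normal (minimum 1); the number of template copies
#' in the analysed droplets `K ~ Poisson(c * A * Vd)` with `Vd` in µL; a
#' uniform multinomial scatter of the `K` copies over the `A` droplets.
#' Droplets holding at least one copy are positive. If amplitudes are kept,
#' positive/negative droplets receive amplitudes from the positive/negative
#' cluster (truncated at mean ± 4 SD) and a `Binomial(A, rain_fraction)`
#' subset is re-assigned a uniform amplitude strictly between the cluster
#' boundaries ("rain"). The pre-rain ground truth is recorded in `meta`.
#'
#' By default copies are generated directly in the analysed volume: sampling
#' template into the PCR mix and then sub-sampling it into droplets is a
#' Poisson thinning, so the analysed-droplet copy count is marginally
#' `Poisson(c * A * Vd)` either way. `two_stage = TRUE` instead first draws
#' the copies pipetted into the `sampled_volume_ul` of mix and treats the
#' realised mix concentration as the rate for the analysed volume; the
#' per-well estimator SD then reproduces the additive sampling-plus-
#' distribution decomposition of [stochastic_curve()] rather than the exact
#' one-stage law.
#'
#' @param config a [sim_config()].
#' @param well_id,run_id,level_id,assay_id labels attached to the well.
#' @param df_sample,df_pcr dilution factors (dimensionless, `>= 1`).
#' @param run_factor,assay_factor,volume_factor multiplicative effects applied
#'   to the concentration (run/assay) or droplet volume, normally supplied by
#'   [simulate_validation_study()].
#' @param keep_amplitudes if `FALSE`, skip amplitude generation and record the
#'   positive count directly (requires `rain_fraction = 0`).
#' @param two_stage simulate the pipette-sampling stage explicitly (see
#'   Details); `sampled_volume_ul` is the PCR-mix volume prepared per well.
#' @param seed optional integer seed; identical seeds give identical wells.
#' @return An object of class `"droplet_well"`: a list with fields `well_id`,
#'   `run_id`, `level_id`, `assay_id`, `accepted`, `positives` (`NA` when
#'   amplitudes are present, classification decides), `amplitudes` (or `NULL`),
#'   `df_sample`, `df_pcr`, and a `meta` list holding the ground truth
#'   (`true_concentration`, `true_positives`, `n_rain`, `copies`).
#' @examples
#' w <- simulate_well(sim_config(250), seed = 1)
#' w$accepted
#' @export
simulate_well <- function(config, well_id = "A01", run_id = "run1",
                          level_id = "L1", assay_id = "assay1",
                          df_sample = 1, df_pcr = 1,
                          run_factor = 1, assay_factor = 1, volume_factor = 1,
                          keep_amplitudes = TRUE, two_stage = FALSE,
                          sampled_volume_ul = 20, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), df_sample >= 1, df_pcr >= 1,
            run_factor > 0, assay_factor > 0, volume_factor > 0)
  if (!keep_amplitudes && config$rain_fraction > 0)
    stop_ddpcr("rain droplets require amplitudes; set keep_amplitudes = TRUE")
  with_seed(seed, {
    A <- as.integer(round(rtnorm_min(1, config$droplet_count_mean,
                                     config$droplet_count_sd, lower = 1)))
    A <- max(A, 1L)
    vd_ul <- config$droplet_volume_nl * 1e-3 * volume_factor
    c_eff <- config$true_concentration * run_factor * assay_factor
    rate <- if (two_stage && c_eff > 0) {
      stopifnot(sampled_volume_ul > 0)
      rpois(1, c_eff * sampled_volume_ul) / sampled_volume_ul
    } else c_eff
    K <- rpois(1, rate * A * vd_ul)
    occupancy <- if (K > 0) tabulate(sample.int(A, K, replace = TRUE), nbins = A)
                 else integer(A)
    is_pos <- occupancy > 0L
    true_pos <- sum(is_pos)

    amplitudes <- NULL
    n_rain <- 0L
    if (keep_amplitudes) {
      amplitudes <- numeric(A)
      amplitudes[is_pos]  <- rtnorm_4sd(true_pos, config$pos_cluster[1],
                                        config$pos_cluster[2])
      amplitudes[!is_pos] <- rtnorm_4sd(A - true_pos, config$neg_cluster[1],
                                        config$neg_cluster[2])
      if (config$rain_fraction > 0) {
        n_rain <- rbinom(1, A, config$rain_fraction)
        if (n_rain > 0) {
          b <- cluster_bounds(config)
          idx <- sample.int(A, n_rain)
          amplitudes[idx] <- runif(n_rain, min = b["low"], max = b["high"])
        }
      }
    }
    structure(list(well_id = well_id, run_id = run_id, level_id = level_id,
                   assay_id = assay_id,
                   accepted = A,
                   positives = if (keep_amplitudes) NA_integer_ else true_pos,
                   amplitudes = amplitudes,
                   df_sample = df_sample, df_pcr = df_pcr,
                   meta = list(true_concentration = c_eff,
                               true_positives = true_pos,
                               n_rain = n_rain, copies = K)),
              class = "droplet_well")
  })
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("ddPCR well %s (run %s, level %s, assay %s)\n",
              x$well_id, x$run_id, x$level_id, x$assay_id))
  cat(sprintf("  accepted %d, positives %s, amplitudes %s\n", x$accepted,
              ifelse(is.na(x$positives), "unclassified", x$positives),
              if (is.null(x$amplitudes)) "absent" else "present"))
  invisible(x)
}

well_plate_id <- function(i) {
  sprintf("%s%02d", LETTERS[(i - 1L) %/% 12L + 1L], (i - 1L) %% 12L + 1L)
}

#' Simulate a plate of replicate wells
#'
#' @param config a [sim_config()].
#' @param n_wells number of replicate wells.
#' @param ... further arguments passed to [simulate_well()].
#' @param seed optional integer seed for the whole plate.
#' @return A list of [simulate_well()] objects.
#' @examples
#' plate <- simulate_plate(sim_config(250), n_wells = 4, seed = 1)
#' @export
simulate_plate <- function(config, n_wells, ..., seed = NULL) {
  stopifnot(n_wells >= 1)
  with_seed(seed, lapply(seq_len(n_wells), function(i)
    simulate_well(config, well_id = well_plate_id(i), ...)))
}

#' Simulate a multi-run, multi-level validation study
#'
#' Emulates the nested design of a single-laboratory validation: several
#' concentration levels, each measured in several runs with (possibly
#' unbalanced) replicate counts. Each run receives one multiplicative
#' concentration factor drawn from `Normal(1, run_effect_rel_sd)`; each assay
#' (if several) one factor from `Normal(1, assay_effect_rel_sd)`. A per-run
#' droplet-volume perturbation (`Normal(1, droplet_volume_rel_sd)`) can be
#' switched on with `volume_effect = TRUE`; it is off by default because a
#' run-level volume factor is statistically indistinguishable from the run
#' effect itself.
#'
#' @param levels named numeric vector of PCR-mix concentrations (copies/µL);
#'   names become `level_id`s.
#' @param n_runs number of runs (`>= 1`).
#' @param replicates replicates per run: scalar or length-`n_runs` vector
#'   (e.g. `c(12, 16, 12)` for an unbalanced design).
#' @param config a [sim_config()] template; its `true_concentration` is
#'   overridden per level.
#' @param run_effect_rel_sd relative SD of the per-run factor; defaults to the
#'   value in `config`.
#' @param assay_ids character vector of assay labels (default one assay).
#' @param volume_effect apply a per-run droplet-volume perturbation.
#' @param keep_amplitudes keep per-droplet amplitudes (see [simulate_well()]).
#' @param seed optional integer seed.
#' @return An object of class `"ddpcr_study"`: a list with `wells` (list of
#'   wells), `design` (data frame of labels and ground truth) and `config`.
#' @examples
#' st <- simulate_validation_study(c(d = 255), n_runs = 3,
#'                                 replicates = c(4, 4, 4),
#'                                 config = sim_config(255),
#'                                 keep_amplitudes = FALSE, seed = 1)
#' nrow(st$design)
#' @export
simulate_validation_study <- function(levels, n_runs = 3,
                                      replicates = c(12, 16, 12),
                                      config = sim_config(levels[[1]]),
                                      run_effect_rel_sd = config$run_effect_rel_sd,
                                      assay_ids = "assay1",
                                      volume_effect = FALSE,
                                      keep_amplitudes = FALSE,
                                      seed = NULL) {
  stopifnot(is.numeric(levels), length(levels) >= 1, all(levels >= 0),
            n_runs >= 1, all(replicates >= 1))
  if (length(replicates) == 1L) replicates <- rep(replicates, n_runs)
  stopifnot(length(replicates) == n_runs)
  if (is.null(names(levels)))
    names(levels) <- sprintf("level%d", seq_along(levels))
  with_seed(seed, {
    run_factors <- rnorm(n_runs, 1, run_effect_rel_sd)
    vol_factors <- if (volume_effect)
      rnorm(n_runs, 1, config$droplet_volume_rel_sd) else rep(1, n_runs)
    assay_factors <- if (length(assay_ids) > 1L)
      rnorm(length(assay_ids), 1, config$assay_effect_rel_sd)
      else rep(1, length(assay_ids))
    names(assay_factors) <- assay_ids
    if (any(run_factors <= 0) || any(vol_factors <= 0) || any(assay_factors <= 0))
      stop_ddpcr("a drawn run/assay/volume factor was <= 0; ",
                 "effect SDs this large are not supported")
    wells <- list(); rows <- list(); i <- 0L
    for (a in assay_ids) for (r in seq_len(n_runs)) {
      for (lv in names(levels)) for (k in seq_len(replicates[r])) {
        i <- i + 1L
        cfg <- config
        cfg$true_concentration <- levels[[lv]]
        w <- simulate_well(cfg, well_id = well_plate_id(i),
                           run_id = sprintf("run%d", r), level_id = lv,
                           assay_id = a,
                           run_factor = run_factors[r],
                           assay_factor = assay_factors[[a]],
                           volume_factor = vol_factors[r],
                           keep_amplitudes = keep_amplitudes)
        wells[[i]] <- w
        rows[[i]] <- data.frame(well_id = w$well_id, run_id = w$run_id,
                                level_id = lv, assay_id = a,
                                true_concentration = levels[[lv]],
                                run_factor = run_factors[r],
                                stringsAsFactors = FALSE)
      }
    }
    structure(list(wells = wells, design = do.call(rbind, rows),
                   config = config, seed = seed),
              class = "ddpcr_study")
  })
}

#' @export
print.ddpcr_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("ddPCR study: %d wells, %d level(s) x %d run(s) x %d assay(s)\n",
              nrow(d), length(unique(d$level_id)), length(unique(d$run_id)),
              length(unique(d$assay_id))))
  invisible(x)
}

#' Simulate a gravimetric dilution series
#'
#' Computes the expected concentration after each gravimetric dilution step
#' (via [gravimetric_dilution_factor()]) and simulates replicate wells at each
#' resulting concentration. The cumulative dilution factor is recorded as
#' `df_sample` so quantification recovers the stock concentration.
#'
#' @param stock_concentration concentration of the undiluted stock (copies/µL).
#' @param steps data frame with columns `mass_sample_g` and `mass_diluent_g`
#'   (one row per sequential dilution step); equal densities are assumed for
#'   sample and buffer diluent.
#' @param config a [sim_config()] template.
#' @param n_wells replicate wells per dilution level.
#' @param keep_amplitudes,seed see [simulate_validation_study()].
#' @return A `"ddpcr_study"` whose levels are the dilution steps; the design
#'   carries `df_cumulative` and the expected concentration per level.
#' @examples
#' steps <- data.frame(mass_sample_g = 1, mass_diluent_g = 9)
#' st <- simulate_dilution_series(1000, steps, sim_config(1000),
#'                                n_wells = 2, seed = 1)
#' st$design$true_concentration  # 100 copies/uL after a 10x step
#' @export
simulate_dilution_series <- function(stock_concentration, steps,
                                     config = sim_config(stock_concentration),
                                     n_wells = 8, keep_amplitudes = FALSE,
                                     seed = NULL) {
  stopifnot(stock_concentration >= 0, is.data.frame(steps),
            all(c("mass_sample_g", "mass_diluent_g") %in% names(steps)))
  dfs <- mapply(gravimetric_dilution_factor,
                mass_sample_g = steps$mass_sample_g,
                mass_added_g = steps$mass_diluent_g)
  df_cum <- cumprod(dfs)
  conc <- stock_concentration / df_cum
  levels <- stats::setNames(conc, sprintf("dilution%d", seq_along(conc)))
  st <- simulate_validation_study(levels, n_runs = 1, replicates = n_wells,
                                  config = config, run_effect_rel_sd = 0,
                                  keep_amplitudes = keep_amplitudes, seed = seed)
  st$design$df_cumulative <- df_cum[match(st$design$level_id, names(levels))]
  for (i in seq_along(st$wells))
    st$wells[[i]]$df_sample <- st$design$df_cumulative[i]
  st
}
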