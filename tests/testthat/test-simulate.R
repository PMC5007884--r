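# Generative model of the droplet-plate simulator.

test_that("no template and no rain means no positive droplets", {
  cfg <- sim_config(0)
  for (s in 1:5)
    expect_identical(simulate_well(cfg, keep_amplitudes = FALSE,
                                   seed = s)$positives, 0L)
})

test_that("identical seeds reproduce bit-identical wells and studies", {
  cfg <- sim_config(250, rain_fraction = 0.005)
  expect_identical(simulate_well(cfg, seed = 99), simulate_well(cfg, seed = 99))
  st1 <- simulate_validation_study(c(a = 26, b = 255), n_runs = 2,
                                   replicates = 3, config = sim_config(26),
                                   keep_amplitudes = FALSE, seed = 5)
  st2 <- simulate_validation_study(c(a = 26, b = 255), n_runs = 2,
                                   replicates = 3, config = sim_config(26),
                                   keep_amplitudes = FALSE, seed = 5)
  expect_identical(st1$wells, st2$wells)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(100, neg_cluster = c(3000, 300),
                          pos_cluster = c(4000, 100), rain_fraction = 0.01),
               "overlap")
  expect_error(sim_config(-1), "true_concentration")
  expect_error(sim_config(100, pos_cluster = c(1000, 10)), "exceed")
  expect_error(simulate_well(sim_config(100, rain_fraction = 0.01),
                             keep_amplitudes = FALSE), "amplitudes")
})

test_that("positives equal occupied droplets when there is no rain", {
  cfg <- sim_config(300, droplet_count_mean = 5000, droplet_count_sd = 100)
  w <- simulate_well(cfg, seed = 3)
  # amplitudes split exactly at any midpoint threshold reproduce ground truth
  expect_equal(classify_well(w, 3591)$P, w$meta$true_positives)
  w2 <- simulate_well(cfg, keep_amplitudes = FALSE, seed = 3)
  expect_equal(w2$positives, w2$meta$true_positives)
})

test_that("injected rain count is Binomial(A, rain_fraction)", {
  cfg <- sim_config(250, droplet_count_mean = 2000, droplet_count_sd = 0,
                    rain_fraction = 0.01)
  rain <- vapply(1:500, function(i)
    simulate_well(cfg, seed = 1000 + i)$meta$n_rain, numeric(1))
  # chi-square goodness of fit against Binomial(2000, 0.01), binned tails
  brk <- c(-Inf, 13, 16, 19, 22, 25, Inf)
  obs <- table(cut(rain, brk))
  p <- diff(pbinom(c(-Inf, 13, 16, 19, 22, 25, Inf), 2000, 0.01))
  expect_gt(chisq.test(as.vector(obs), p = p)$p.value, 0.01)
  # rain amplitudes stay strictly inside the cluster boundaries
  w <- simulate_well(sim_config(250, rain_fraction = 0.05), seed = 2)
  b <- c(1764 + 4 * 135, 5418 - 4 * 212)
  mid <- w$amplitudes[w$amplitudes > b[1] & w$amplitudes < b[2]]
  expect_equal(length(mid), w$meta$n_rain)
})

test_that("mean of quantified wells recovers the true concentration", {
  st <- simulate_validation_study(c(L = 250), n_runs = 1, replicates = 200,
                                  config = sim_config(250),
                                  keep_amplitudes = FALSE, seed = 11)
  expect_lt(abs(mean(study_cpcr(st)) / 250 - 1), 0.02)
})

test_that("a null run effect is clamped to zero in about half the seeds", {
  clamped <- vapply(1:30, function(s) {
    st <- simulate_validation_study(c(L = 1000), n_runs = 3, replicates = 8,
                                    config = sim_config(1000,
                                                        droplet_count_mean = 2000,
                                                        droplet_count_sd = 100),
                                    keep_amplitudes = FALSE, seed = s)
    precision_from_runs(split(study_cpcr(st),
                              st$design$run_id))$run_clamped
  }, logical(1))
  expect_gt(mean(clamped), 0.2)
  expect_lt(mean(clamped), 0.8)
})

test_that("a 5 % run effect is recovered by the nested ANOVA", {
  rec <- vapply(1:4, function(s) {
    st <- simulate_validation_study(c(L = 1000), n_runs = 10, replicates = 20,
                                    config = sim_config(1000,
                                                        droplet_count_mean = 5000,
                                                        droplet_count_sd = 200,
                                                        run_effect_rel_sd = 0.05),
                                    keep_amplitudes = FALSE, seed = s)
    precision_from_runs(split(study_cpcr(st), st$design$run_id))$s_run_rel
  }, numeric(1))
  expect_true(all(rec > 0.03 & rec < 0.07))
})

test_that("the unbalanced multi-level design has the declared shape", {
  levels <- c(b = 5400, c = 2575, d = 255, e = 26, f = 2.5)
  st <- simulate_validation_study(levels, n_runs = 3,
                                  replicates = c(12, 16, 12),
                                  config = sim_config(5400,
                                                      droplet_count_mean = 2000,
                                                      droplet_count_sd = 0),
                                  keep_amplitudes = FALSE, seed = 21)
  expect_equal(nrow(st$design), 5 * (12 + 16 + 12))
  expect_equal(as.vector(table(st$design$run_id)), c(5 * 12, 5 * 16, 5 * 12))
  expect_setequal(unique(st$design$level_id), names(levels))
})

test_that("gravimetric dilution series lands at the expected concentrations", {
  steps <- data.frame(mass_sample_g = 1, mass_diluent_g = 9)
  st <- simulate_dilution_series(1000, steps, sim_config(1000),
                                 n_wells = 3, seed = 2)
  expect_equal(unique(st$design$true_concentration), 100)
  # quantification through df_sample recovers the stock scale
  q <- quantify_study(st)
  expect_equal(q$c_sample, q$c_pcr * 10)

  steps3 <- data.frame(mass_sample_g = c(5, 5, 5),
                       mass_diluent_g = c(15.2, 14.8, 15))
  st3 <- simulate_dilution_series(6.4e4, steps3, sim_config(1000),
                                  n_wells = 1, seed = 3)
  df <- (5 + 15.2) / 5 * (5 + 14.8) / 5 * (5 + 15) / 5
  expect_equal(min(st3$design$true_concentration), 6.4e4 / df)

  # Df = 1 reduces to wells at the stock concentration
  st1 <- simulate_dilution_series(500, data.frame(mass_sample_g = 1,
                                                  mass_diluent_g = 0),
                                  sim_config(500), n_wells = 2, seed = 4)
  expect_equal(unique(st1$design$true_concentration), 500)
  expect_error(simulate_dilution_series(500,
                                        data.frame(mass_sample_g = 0,
                                                   mass_diluent_g = 1),
                                        sim_config(500)), "mass")
})
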