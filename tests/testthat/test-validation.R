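# Validation mathematics: ANOVA, precision, pooling, bias, variance
# components, combined uncertainty, linearity, LOD/LOQ, robustness.

test_that("one-way ANOVA matches hand computation and the brute-force oracle", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$ms_within, 1.0)
  expect_equal(a$ms_between, 1.5)
  expect_equal(a$n_bar, 3)
  expect_equal(a$grand_mean, 2.5)

  expect_equal(one_way_anova(list(c(2, 3, 4), c(2, 3, 4)))$ms_between, 0)
  expect_error(one_way_anova(list(1, 2, 3)), "singleton")

  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(g)
      rnorm(sample(2:9, 1), mean = runif(1, 0, 10), sd = runif(1, 0.1, 2)))
    got <- one_way_anova(groups)
    ref <- anova_bruteforce(groups)
    expect_equal(got$ms_within, ref$ms_within, tolerance = 1e-10)
    expect_equal(got$ms_between, ref$ms_between, tolerance = 1e-10)
  }
})

test_that("precision decomposition reproduces the exact small case", {
  p <- precision_from_runs(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(p$s_repeat_rel, 0.4)
  expect_equal(p$s_run_rel, sqrt(0.5 / 3) / 2.5)
  expect_equal(round(100 * p$s_run_rel, 2), 16.33)
  expect_equal(p$u_precision_rel, 0.2)
  expect_false(p$run_clamped)
})

test_that("the run component is clamped to zero when MS_between < MS_within", {
  p <- precision_from_runs(list(c(1, 5), c(3, 3.001)))
  expect_identical(p$s_run_rel, 0)
  expect_true(p$run_clamped)
  # and the clamp fires exactly when the mean squares cross
  p2 <- precision_from_runs(list(c(1, 2), c(5, 6)))
  expect_false(p2$run_clamped)
  expect_gt(p2$s_run_rel, 0)
})

test_that("precision uncertainty of a 3-run design of ~13 replicates is ~1.2 %", {
  u <- precision_uncertainty(0.077, 0, n_bar_repli = 40 / 3, n_run = 3)
  expect_equal(round(100 * u, 1), 1.2)
})

test_that("RMS pooling is the quadratic mean", {
  expect_equal(pool_rms(c(3, 4)), sqrt(12.5))
  expect_equal(pool_rms(7), 7)
  expect_error(pool_rms(numeric(0)), "pool")
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(2:8, 1), 0, 10)
    expect_gte(pool_rms(v), mean(v))
  }
})

test_that("bias assessment combines precision and certificate uncertainties", {
  cert <- data.frame(level_id = c("x", "y"), c_cert = c(100, 1000),
                     U_cert = c(10, 80))
  meas <- data.frame(level_id = c("x", "y"), c_meas = c(100, 1000))
  b <- bias_assessment(meas, cert, u_precision_rel = 0.02)
  expect_equal(b$per_level$bias_rel, c(0, 0))
  expect_false(b$significant)
  expect_equal(b$u_bias_rel,
               sqrt(0.02^2 + (0.05^2 + 0.04^2) / 2), tolerance = 1e-12)
  expect_equal(b$U_bias_rel, 2 * b$u_bias_rel)
  expect_error(bias_assessment(data.frame(level_id = "z", c_meas = 1), cert,
                               0.02), "not found")
})

test_that("assay variance component matches the hand-computed ANOVA", {
  a <- assay_variability(list(c(10, 11, 12), c(13, 14, 15)))
  expect_equal(a$s_assay_rel, sqrt((13.5 - 1) / 3) / 12.5)
  expect_equal(round(100 * a$s_assay_rel, 2), 16.33)
  a0 <- assay_variability(list(c(5, 6, 7), c(5, 6, 7)))
  expect_identical(a0$s_assay_rel, 0)
  expect_true(a0$clamped)
  expect_error(assay_variability(list(c(1, 2))), "two assays")
})

test_that("a simulated 5 % assay effect is recovered", {
  rec <- vapply(1:3, function(s) {
    st <- simulate_validation_study(c(L = 1000), n_runs = 1, replicates = 50,
                                    config = sim_config(1000,
                                                        droplet_count_mean = 5000,
                                                        droplet_count_sd = 200,
                                                        assay_effect_rel_sd = 0.05),
                                    assay_ids = sprintf("as%d", 1:8),
                                    keep_amplitudes = FALSE, seed = s)
    q <- quantify_study(st)
    assay_variability(split(q$c_pcr, q$assay_id))$s_assay_rel
  }, numeric(1))
  expect_true(all(rec > 0.02 & rec < 0.08))
})

test_that("threshold variance component pools within-replicate disagreement", {
  t1 <- threshold_variability(list(c(100, 102, 98, 100)))
  expect_equal(t1$s_thres_rel, sqrt(8 / 3) / 100)
  expect_equal(round(100 * t1$s_thres_rel, 2), 1.63)
  expect_identical(threshold_variability(list(c(5, 5, 5),
                                              c(7, 7, 7)))$s_thres_rel, 0)
  expect_error(threshold_variability(list(c(1))), "variants")
})

test_that("combined uncertainty is monotone in components and sample size", {
  base <- combined_uncertainty(0.06, 0.03, 0.018, 0.05, n_meas = 4)$U_meas_rel
  expect_gt(combined_uncertainty(0.08, 0.03, 0.018, 0.05,
                                 n_meas = 4)$U_meas_rel, base)
  expect_gt(combined_uncertainty(0.06, 0.03, 0.018, 0.05, s_thres_rel = 0.07,
                                 n_meas = 4)$U_meas_rel, base)
  expect_lt(combined_uncertainty(0.06, 0.03, 0.018, 0.05,
                                 n_meas = 16)$U_meas_rel, base)
  expect_identical(combined_uncertainty(0, 0, 0, 0, n_meas = 4)$U_meas_rel, 0)
  # the two readings of the run term coincide for a single run
  expect_equal(combined_uncertainty(0.06, 0.03, n_meas = 4,
                                    run_term = "variance")$U_meas_rel,
               combined_uncertainty(0.06, 0.03, n_meas = 4,
                                    run_term = "linear")$U_meas_rel)
})

test_that("through-origin linearity fit recovers proportional relations", {
  f <- linearity_fit(c(1, 10, 100), c(2, 20, 200))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  f1 <- linearity_fit(10, 8.7)
  expect_equal(f1$slope, 0.87)
  expect_equal(f1$r_squared, 1)
  set.seed(77)
  x <- 10^(0:4)
  y <- 0.87 * x * (1 + rnorm(5, 0, 0.01))
  f2 <- linearity_fit(x, y)
  expect_lt(abs(f2$slope - 0.87), 0.02)
  expect_gt(f2$r_squared, 0.999)
  expect_error(linearity_fit(c(0, 0), c(1, 2)), "zero")
})

test_that("experimental LOD summary flags all-positive replicate sets", {
  res <- data.frame(P = rep(1:3, 20), c_pcr = rep(0.5, 60))
  s <- lod_experimental(res)
  expect_true(s$all_positive)
  expect_equal(s$n_valid, 60)
  res$P[1] <- 0
  expect_false(lod_experimental(res)$all_positive)
})

test_that("replicates at 0.56 copies/uL scatter as two-stage Poisson predicts", {
  rel_sd <- vapply(1:3, function(s) {
    st <- simulate_validation_study(c(f = 0.56), n_runs = 1, replicates = 60,
                                    config = sim_config(0.56),
                                    keep_amplitudes = FALSE, seed = 300 + s)
    q <- quantify_study(st)
    sd(q$c_pcr) / mean(q$c_pcr)
  }, numeric(1))
  expect_true(all(rel_sd > 0.25 & rel_sd < 0.45))
})

test_that("LOQ assessment chains precision, bias and the budget", {
  # zero-noise level: U collapses to the volume and certificate terms
  res <- data.frame(run_id = rep(c("r1", "r2"), each = 4),
                    c_sample = rep(10, 8))
  cert_f <- data.frame(level_id = "f", c_cert = 10, U_cert = 1.5)
  l <- loq_assess(res, cert_f, u_vd_rel = 0.018, s_thres_rel = 0, n_meas = 4)
  expect_equal(l$U_meas_rel, 2 * sqrt(0.018^2 + 0.075^2), tolerance = 1e-12)
  expect_true(l$meets_loq)
  expect_equal(l$bias$mean_bias_rel, 0)
  # 40 % repeatability at 4 replicates blows the 30 % limit
  expect_gt(combined_uncertainty(0.40, 0, 0.018, 0, n_meas = 4)$U_meas_rel,
            0.40)
  # a simulated low-concentration study returns a coherent assessment
  st <- simulate_validation_study(c(f = 3.5), n_runs = 2, replicates = 12,
                                  config = sim_config(3.5),
                                  keep_amplitudes = FALSE, seed = 8)
  q <- quantify_study(st)
  l2 <- loq_assess(q, cert_f, s_thres_rel = 0.072, value = "c_pcr")
  expect_true(is.finite(l2$U_meas_rel) && l2$U_meas_rel > 0)
  expect_error(loq_assess(q[q$run_id == "run1", ], cert_f), "2 runs")
})

test_that("robustness comparison flags deviations beyond the uncertainty", {
  r <- robustness_compare(list(opt = c(279, 279), lower = c(273, 273),
                               higher = c(285, 285)), U_meas_rel = 0.142)
  expect_false(any(r$significant))
  expect_equal(r$delta_rel[1], 0)
  shifted <- robustness_compare(list(ref = c(100, 100), bad = c(130, 130)),
                                U_meas_rel = 0.142)
  expect_true(shifted$significant[shifted$condition == "bad"])
  expect_error(robustness_compare(list(a = 1, b = numeric(0)), 0.1), "empty")
  # the bundled robustness study shows no significant condition effects
  rb <- robustness_summary()
  for (smp in unique(rb$sample)) {
    g <- rb[rb$sample == smp, ]
    groups <- split(g$c_pcr_mean, seq_len(nrow(g)))
    names(groups) <- paste0("cond", seq_along(groups))
    tab <- robustness_compare(groups, U_meas_rel = 0.142)
    expect_false(any(tab$significant))
  }
})
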