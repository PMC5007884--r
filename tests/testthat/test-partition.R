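# Cluster estimation, threshold variants, rain classification and QC rules.

test_that("cluster estimation is exact on separated point masses", {
  cl <- estimate_clusters(c(1000, 1000, 6000, 6000))
  expect_equal(cl$neg_mean, 1000)
  expect_equal(cl$pos_mean, 6000)
  expect_equal(make_thresholds(cl)$midpoint, 3500)
  expect_false(cl$one_cluster)
})

test_that("identical amplitudes give a one-cluster result", {
  cl <- estimate_clusters(rep(2000, 10))
  expect_true(cl$one_cluster)
  expect_error(make_thresholds(cl), "one-cluster")
  expect_error(estimate_clusters(numeric(0)), "empty")
  expect_error(estimate_clusters(5), "2 droplets")
})

test_that("cluster estimation recovers well-separated Gaussian clusters", {
  set.seed(41)
  amp <- c(rnorm(8000, 1764, 135), rnorm(2000, 5418, 212))
  cl <- estimate_clusters(amp)
  expect_lt(abs(cl$neg_mean / 1764 - 1), 0.01)
  expect_lt(abs(cl$pos_mean / 5418 - 1), 0.01)
  expect_equal(cl$n_pos, 2000, tolerance = 0.01)
})

test_that("threshold set follows the mean +/- 4 SD boundary convention", {
  th <- make_thresholds(list(neg_mean = 1764, neg_sd = 135,
                             pos_mean = 5418, pos_sd = 212))
  expect_equal(th$midpoint, 3591)
  expect_equal(th$low, 2304)
  expect_equal(th$high, 4570)
  th2 <- make_thresholds(list(neg_mean = 0, neg_sd = 1,
                              pos_mean = 10, pos_sd = 1))
  expect_equal(unlist(th2[c("midpoint", "low", "high")]),
               c(midpoint = 5, low = 4, high = 6))
  th3 <- make_thresholds(list(neg_mean = 1764, neg_sd = 0,
                              pos_mean = 5418, pos_sd = 0))
  expect_equal(c(th3$low, th3$high), c(1764, 5418))
})

test_that("classification counts positives at the threshold (ties positive)", {
  w <- fake_well(NA, NA, amplitudes = c(1, 2, 10))
  r <- classify_well(w, threshold = 5)
  expect_equal(c(r$P, r$A), c(1, 3))
  # tie counts as positive
  expect_equal(classify_well(fake_well(NA, NA, amplitudes = c(4, 5)), 5)$P, 1)
})

test_that("rain removal drops intermediate droplets from P and A", {
  amp <- c(rep(1764, 100), rep(3500, 10), rep(5418, 50))
  th <- make_thresholds(list(neg_mean = 1764, neg_sd = 135,
                             pos_mean = 5418, pos_sd = 212))
  w <- fake_well(NA, NA, amplitudes = amp)
  r <- classify_well(w, th$midpoint, rain_removal = TRUE, bounds = th)
  expect_equal(c(r$P, r$A, r$rain), c(50, 150, 10))
  expect_error(classify_well(w, th$midpoint, rain_removal = TRUE),
               "bounds")
})

test_that("positive count is monotone in the threshold and across variants", {
  set.seed(7)
  cfg <- sim_config(500, droplet_count_mean = 3000, droplet_count_sd = 100,
                    rain_fraction = 0.01)
  th <- make_thresholds(list(neg_mean = 1764, neg_sd = 135,
                             pos_mean = 5418, pos_sd = 212))
  for (i in 1:5) {
    w <- simulate_well(cfg)
    thr <- sort(runif(10, 1000, 6000))
    P <- vapply(thr, function(t) classify_well(w, t)$P, numeric(1))
    expect_true(all(diff(P) <= 0))
    p_low <- classify_well(w, th$low)$P
    p_mid <- classify_well(w, th$midpoint)$P
    p_high <- classify_well(w, th$high)$P
    expect_true(p_low >= p_mid && p_mid >= p_high)
    expect_lte(classify_well(w, th$midpoint, rain_removal = TRUE,
                             bounds = th)$A, w$accepted)
  }
})

test_that("QC rule on the droplet count is exact and amplitude-free", {
  expect_true("min_droplets" %in% qc_well(fake_well(100, 9999))$failed_rules)
  ok <- qc_well(fake_well(100, 10000))
  expect_false("min_droplets" %in% ok$failed_rules)
  # counts-only wells cannot be judged on amplitude rules
  expect_setequal(ok$not_evaluated, c("amplitude_outlier", "low_amplitude_tail"))
})

test_that("low-amplitude tail rule fires at 5 % below the cluster floor", {
  plate_cl <- list(neg_mean = 1764, neg_sd = 135, pos_mean = 5418,
                   pos_sd = 212, one_cluster = FALSE)
  amp <- c(rep(500, 600), rep(1764, 9400))       # 6 % far below the floor
  bad <- qc_well(fake_well(NA, NA, amplitudes = amp), plate_clusters = plate_cl)
  expect_true("low_amplitude_tail" %in% bad$failed_rules)
  amp2 <- c(rep(500, 400), rep(1764, 9600))      # 4 %: tolerated
  ok <- qc_well(fake_well(NA, NA, amplitudes = amp2), plate_clusters = plate_cl)
  expect_false("low_amplitude_tail" %in% ok$failed_rules)
})

test_that("plate QC flags a well with shifted clusters and passes clean wells", {
  set.seed(9)
  cfg <- sim_config(250, droplet_count_mean = 17000, droplet_count_sd = 200)
  wells <- simulate_plate(cfg, n_wells = 6)
  shifted <- wells[[6]]
  shifted$amplitudes <- shifted$amplitudes + 1500
  wells[[6]] <- shifted
  rep <- qc_plate(wells)
  expect_true(all(vapply(rep[1:5], `[[`, logical(1), "passed")))
  expect_true("amplitude_outlier" %in% rep[[6]]$failed_rules)
})

test_that("selectivity pools droplet counts across wells", {
  blanks <- data.frame(P = c(0, 0, 0, 0), A = c(15000, 15500, 15275, 15500))
  ctrls <- data.frame(P = c(14480, 14470, 14475, 14437),
                      A = c(14480, 14475, 14490, 14450))
  stopifnot(sum(blanks$A) == 61275, sum(ctrls$A) == 57895,
            sum(ctrls$A) - sum(ctrls$P) == 33)
  s <- selectivity_metrics(blanks, ctrls)
  expect_identical(s$false_positive_fraction, 0)
  expect_equal(s$false_negative_fraction, 33 / 57895)
  expect_equal(round(100 * s$false_negative_fraction, 3), 0.057)
  expect_equal(selectivity_metrics(data.frame(P = 1, A = 10000),
                                   ctrls)$false_positive_fraction, 1e-4)
  expect_error(selectivity_metrics(data.frame(P = 0, A = 0), ctrls), "zero")
})

test_that("analyze_wells produces a coherent results table", {
  cfg <- sim_config(250, droplet_count_mean = 12000, droplet_count_sd = 100)
  wells <- simulate_plate(cfg, n_wells = 6, seed = 13)
  tab <- analyze_wells(wells)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$qc_passed))
  expect_true(all(tab$P <= tab$A))
  expect_equal(tab$c_pcr,
               concentration_from_counts(tab$P, tab$A)$c_pcr)
  # counts-only wells skip classification but still quantify
  tab2 <- analyze_wells(list(fake_well(3000, 17000)))
  expect_equal(tab2$c_pcr, concentration_from_counts(3000, 17000)$c_pcr)
  expect_error(analyze_wells(list(fake_well(3000, 17000)), variant = "low"),
               "amplitudes")
})
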