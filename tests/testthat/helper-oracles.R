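# Independent brute-force oracles used across the suite.

# One-way ANOVA by explicit sums of squares (no lm/aov).
anova_bruteforce <- function(groups) {
  x <- unlist(groups)
  k <- length(groups)
  n <- length(x)
  gm <- mean(x)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  list(ms_within = ss_within / (n - k), ms_between = ss_between / (k - 1))
}

# Build a counts-only droplet well by hand (no simulator).
fake_well <- function(P, A, well_id = "A01", run_id = "run1",
                      level_id = "L1", amplitudes = NULL) {
  structure(list(well_id = well_id, run_id = run_id, level_id = level_id,
                 assay_id = "assay1",
                 accepted = if (is.null(amplitudes)) as.integer(A)
                            else length(amplitudes),
                 positives = if (is.null(amplitudes)) as.integer(P)
                             else NA_integer_,
                 amplitudes = amplitudes, df_sample = 1, df_pcr = 1,
                 meta = list()),
            class = "droplet_well")
}

# Per-well PCR concentrations for a simulated counts-only study.
study_cpcr <- function(study) quantify_study(study)$c_pcr
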