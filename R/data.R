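#' Certified copy number concentrations of the ERM-AD623 reference materials
#'
#' The ERM-AD623 set consists of six solutions of a double-stranded linearized
#' plasmid carrying the human *BCR-ABL* b3a2 fusion sequence, certified for
#' absolute copy number concentration by chip-based digital PCR at three
#' metrology institutes. These certified values anchor the trueness (bias)
#' assessment of a droplet digital PCR method validated against them.
#'
#' @return A data frame with one row per level and columns:
#'   \describe{
#'     \item{level_id}{material code, `"AD623a"` ... `"AD623f"`.}
#'     \item{c_cert}{certified copy number concentration (copies/µL).}
#'     \item{U_cert}{expanded uncertainty of the certified value (copies/µL),
#'       coverage factor k = 2.}
#'     \item{u_cert_rel}{derived relative standard uncertainty,
#'       `(U_cert / 2) / c_cert` (fraction).}
#'   }
#' @examples
#' erm_ad623()
#' @export
erm_ad623 <- function() {
  x <- read.csv(system.file("extdata", "erm_ad623_certified.csv",
                            package = "ddpcrval"))
  x$u_cert_rel <- (x$U_cert / 2) / x$c_cert
  x
}

#' Bundled summary results of a single-laboratory ddPCR validation study
#'
#' Summary tables from an in-house validation of a BCR-ABL droplet digital PCR
#' method against the ERM-AD623 certified reference materials, shipped as
#' plain-text fixtures. `accuracy_summary()` holds the per-level accuracy
#' assessment (measured means, relative bias, repeatability, run-to-run
#' variation and precision uncertainty, in percent); `rain_summary()` the
#' threshold-setting study (mean positive/negative/rain droplet counts per
#' measurement and the threshold variance component at five concentrations);
#' `robustness_summary()` the robustness test (mean ± SD under perturbed
#' annealing temperatures and primer/probe concentrations).
#'
#' These tables are inputs for re-running the validation arithmetic (pooling,
#' bias chain, combined uncertainty) without access to the raw 200-well data.
#'
#' @return A data frame; see Details for the columns of each table.
#' @seealso [erm_ad623()], [pool_rms()], [bias_assessment()],
#'   [combined_uncertainty()]
#' @examples
#' accuracy_summary()
#' @export
accuracy_summary <- function() {
  read.csv(system.file("extdata", "accuracy_summary.csv", package = "ddpcrval"))
}

#' @rdname accuracy_summary
#' @export
rain_summary <- function() {
  read.csv(system.file("extdata", "rain_summary.csv", package = "ddpcrval"))
}

#' @rdname accuracy_summary
#' @export
robustness_summary <- function() {
  read.csv(system.file("extdata", "robustness_summary.csv", package = "ddpcrval"))
}
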