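# One-way ANOVA decomposition and RMS pooling: the primitives behind the
# precision, assay and threshold variance components.

#' One-way analysis of variance on grouped results
#'
#' Standard one-way decomposition of a set of groups (runs, assays or
#' replicates): within-group mean square `MS_within = SS_within / (N - k)` and
#' between-group mean square `MS_between = SS_between / (k - 1)`, computed via
#' [stats::lm()]/[stats::anova()]. Also returns the average group size and the
#' grand mean of all observations.
#'
#' @param groups list of numeric vectors, one per group (`>= 2` groups, at
#'   least one group with `>= 2` values).
#' @return A list: `ms_within`, `ms_between`, `n_bar` (arithmetic mean group
#'   size), `n_groups`, `n_total`, `grand_mean`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop_ddpcr("every group needs at least one value")
  if (all(sizes < 2L))
    stop_ddpcr("all groups are singletons: MS_within undefined")
  x <- unlist(groups, use.names = FALSE)
  stopifnot(is.numeric(x), all(is.finite(x)))
  g <- factor(rep(seq_along(groups), sizes))
  # suppress the "perfect fit" warning: degenerate inputs are legitimate here
  tab <- suppressWarnings(anova(lm(x ~ g)))
  list(ms_within = tab[["Mean Sq"]][2L],
       ms_between = tab[["Mean Sq"]][1L],
       n_bar = mean(sizes),
       n_groups = length(groups),
       n_total = length(x),
       grand_mean = mean(x))
}

#' Root-mean-square (quadratic mean) pooling
#'
#' Pools several relative standard deviations (one per concentration level)
#' into a single value: the square root of the mean of the squared values.
#' Always at least the arithmetic mean for non-negative inputs.
#'
#' @param values non-empty numeric vector of non-negative values (fractions
#'   or percent — the operation is scale-invariant).
#' @return The pooled value, on the input scale.
#' @examples
#' pool_rms(c(4.7, 5.6, 4.8, 7.7, 7.3))  # 6.1 (percent scale)
#' @export
pool_rms <- function(values) {
  if (length(values) == 0L) stop_ddpcr("no values to pool")
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  sqrt(mean(values^2))
}
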