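#' Tidy a simulated family
#'
#' One row per progeny with its total true genetic value.
#'
#' @param x A `seg_family`.
#' @param ... Unused.
#' @return Tibble with `progeny`, `parent1`, `parent2` and
#'   `genetic_value` (when effects were available).
#' @export
tidy.seg_family <- function(x, ...) {
  tibble(
    progeny = seq_len(x$n),
    parent1 = x$parent1,
    parent2 = x$parent2,
    genetic_value = x$genetic_values %||% rep(NA_real_, x$n)
  )
}

#' Glance at a simulated family
#'
#' One-row summary: family size, the M1/M2 variance estimates and the
#' inter-chromosome covariance of the sample.
#'
#' @inheritParams tidy.seg_family
#' @return One-row tibble (`parent1`, `parent2`, `n`, `m1`, `m2`,
#'   `cov_total`).
#' @export
glance.seg_family <- function(x, ...) {
  family_variance(x)
}

#' Tidy a scenario result
#'
#' @param x A `seg_scenario`.
#' @param ... Unused.
#' @return Long tibble of per-run metrics (`run`, `comparison`, `pcc`,
#'   `rmsd`).
#' @export
tidy.seg_scenario <- function(x, ...) {
  x$runs
}

#' Glance at a scenario result
#'
#' @inheritParams tidy.seg_scenario
#' @return One row per comparison: the scenario configuration plus the
#'   median `pcc` and `rmsd` across runs.
#' @export
glance.seg_scenario <- function(x, ...) {
  dplyr::bind_cols(x$config[rep(1, nrow(x$medians)), ], x$medians)
}
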