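#' Haldane mapping function
#'
#' Converts a genetic map distance (Morgan) into a recombination fraction
#' under the assumption of no crossover interference:
#' \eqn{c = 0.5\,(1 - e^{-2d})}.
#'
#' @param d Numeric vector of map distances in Morgan, all `>= 0`.
#' @return Recombination fractions in `[0, 0.5)`, same length as `d`.
#' @examples
#' haldane(c(0, 0.1, 0.5, 5))
#' @seealso [haldane_inv()]
#' @export
haldane <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0)) {
    abort("`d` must be a non-negative numeric vector of Morgan distances.")
  }
  0.5 * (1 - exp(-2 * d))
}

#' Inverse Haldane mapping function
#'
#' Map distance (Morgan) corresponding to a recombination fraction.
#'
#' @param c_rate Recombination fractions in `[0, 0.5)`.
#' @return Map distances in Morgan.
#' @export
haldane_inv <- function(c_rate) {
  if (!is.numeric(c_rate) || anyNA(c_rate) ||
      any(c_rate < 0) || any(c_rate >= 0.5)) {
    abort("`c_rate` must lie in [0, 0.5).")
  }
  -0.5 * log(1 - 2 * c_rate)
}

check_rec_rate <- function(c_rate, arg = "c_rate") {
  if (!is.numeric(c_rate) || anyNA(c_rate) ||
      any(c_rate < 0) || any(c_rate > 0.5)) {
    abort(sprintf("`%s` must be a recombination rate in [0, 0.5].", arg))
  }
  invisible(c_rate)
}
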