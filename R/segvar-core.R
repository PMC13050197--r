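#' @title Closed-form segregation variance
#'
#' @description
#' The additive segregation variance of an F1 family from the cross
#' P1 x P2 is the quadratic form \eqn{\sigma^2_{P1 \times P2} =
#' \beta^T \, var(X_{P1 \times P2}) \, \beta} over the progeny dosage
#' covariance matrix. With phased parental haplotypes the off-diagonal
#' entries follow from the parental linkage phase attenuated by
#' \eqn{(1 - 2c)}; without phase the matrix is taken diagonal. Because the
#' covariance vanishes at c = 0.5, the matrix is block-diagonal by
#' chromosome and the quadratic form is accumulated per chromosome.
#'
#' @name segvar-core
NULL

# The phase-dependent LD term shared by the bivalent and double-reduction
# covariances: (1/3) sum_h (A_h B_h) summed over parents minus
# (1/12) (x_A x_B) summed over parents.
bracket_term <- function(H1, H2, iA, iB) {
  (sum(H1[, iA] * H1[, iB]) + sum(H2[, iA] * H2[, iB])) / 3 -
    (sum(H1[, iA]) * sum(H1[, iB]) + sum(H2[, iA]) * sum(H2[, iB])) / 12
}

#' Closed-form two-locus progeny covariance (phased parents)
#'
#' Covariance between progeny dosages at two loci under bivalent meiosis:
#' \deqn{cov(x_A, x_B) = \left\{\tfrac13 \sum_h (A_h^{P1} B_h^{P1} +
#' A_h^{P2} B_h^{P2}) - \tfrac1{12}(x_A^{P1} x_B^{P1} +
#' x_A^{P2} x_B^{P2})\right\} (1 - 2c).}
#' Equals the brute-force enumeration [cov_brute_force()] exactly; it is 0
#' at c = 0.5 (unlinked loci) and linear in \eqn{1 - 2c}.
#'
#' @inheritParams enumerate_progeny
#' @return A single covariance value.
#' @export
cov_phased <- function(haplotypes, parent1 = NULL, parent2 = NULL,
                       locus_a, locus_b, c_rate) {
  check_rec_rate(c_rate)
  H1 <- resolve_haps(haplotypes, parent1)
  H2 <- resolve_haps(haplotypes, parent2)
  iA <- locus_index(H1, locus_a)
  iB <- locus_index(H1, locus_b)
  bracket_term(H1, H2, iA, iB) * (1 - 2 * c_rate)
}

#' Closed-form single-locus progeny variance from parental dosages
#'
#' Variance of the progeny dosage at one locus, which depends on the
#' parental genotypes only through their dosages:
#' \deqn{var(x_A) = \tfrac13 (x_A^{P1} + x_A^{P2}) -
#' \tfrac1{12}\left[(x_A^{P1})^2 + (x_A^{P2})^2\right].}
#'
#' @param x1,x2 Parental allele dosages, integers in 0-4 (vectorised).
#' @return Progeny dosage variance(s), `>= 0`; 0 iff both parents are
#'   monomorphic (dosage 0 or 4) at the locus.
#' @examples
#' var_locus(2, 2)  # duplex x duplex: 2/3
#' var_locus(1, 0)  # simplex x nulliplex: 1/4
#' @export
var_locus <- function(x1, x2) {
  if (anyNA(x1) || anyNA(x2) || !all(x1 %in% 0:4) || !all(x2 %in% 0:4)) {
    abort("parental dosages must be integers in 0..4.")
  }
  (x1 + x2) / 3 - (x1^2 + x2^2) / 12
}

#' Two-locus progeny covariance under complete double reduction
#'
#' Closed-form covariance when meiosis proceeds through complete
#' quadrivalent pairing with double-reduction rate `alpha` at the
#' centromere-proximal locus A, assuming the locus order
#' centromere - A - B:
#' \deqn{cov(x_A, x_B) = \{\cdot\}\,(1 - \tfrac43 c)(1 + 2\alpha_A),}
#' with the same phase-dependent bracket as [cov_phased()]. At
#' `alpha = 0` this does not reduce to the bivalent formula for c > 0:
#' the pairing model differs (the factors agree only at c = 0). The
#' assumptions (complete quadrivalents, centromere-A-B order) are strong
#' and rarely met in real meioses; treat this mode as an upper-bound
#' exploration, not a default.
#'
#' @inheritParams cov_phased
#' @param alpha Double-reduction rate at locus A, in `[0, 1/6]` (the
#'   classical maximum under complete quadrivalent pairing).
#' @return A single covariance value, increasing in `alpha` whenever the
#'   phase bracket is positive.
#' @export
cov_double_reduction <- function(haplotypes, parent1 = NULL, parent2 = NULL,
                                 locus_a, locus_b, c_rate, alpha) {
  check_rec_rate(c_rate)
  check_alpha(alpha)
  H1 <- resolve_haps(haplotypes, parent1)
  H2 <- resolve_haps(haplotypes, parent2)
  iA <- locus_index(H1, locus_a)
  iB <- locus_index(H1, locus_b)
  bracket_term(H1, H2, iA, iB) * (1 - 4 * c_rate / 3) * (1 + 2 * alpha)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1 / 6) {
    abort("`alpha` must be a double-reduction rate in [0, 1/6].")
  }
  invisible(alpha)
}

#' Per-chromosome progeny covariance blocks
#'
#' Builds the progeny dosage covariance matrix of a cross as one symmetric
#' block per chromosome (inter-chromosome covariances are structurally 0
#' at c = 0.5, so the full matrix is never materialised). Pairwise
#' recombination fractions come from the Haldane function on map-position
#' differences.
#'
#' @param data Aligned dataset from [seg_align()].
#' @param parent1,parent2 Parent ids.
#' @param mode `"phased"` (LD off-diagonals from parental phase),
#'   `"unphased"` (diagonal matrix of [var_locus()]) or
#'   `"double_reduction"` (see [cov_double_reduction()]).
#' @param alpha Genome-wide double-reduction rate used by the
#'   `"double_reduction"` mode.
#' @return Named list (one element per chromosome) of symmetric matrices
#'   with marker dimnames.
#' @export
build_cov_blocks <- function(data, parent1, parent2,
                             mode = c("phased", "unphased", "double_reduction"),
                             alpha = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "seg_data"))
  if (mode != "unphased" && !data$phased) {
    abort(sprintf("phased haplotypes are required for mode = '%s'.", mode))
  }
  if (mode == "double_reduction") check_alpha(alpha)
  d1 <- data$dosages[parent1, ]
  d2 <- data$dosages[parent2, ]
  chroms <- split(seq_len(nrow(data$map)), data$map$chrom)
  lapply(chroms, function(idx) {
    mk <- data$map$marker[idx]
    if (mode == "unphased") {
      v <- var_locus(d1[mk], d2[mk])
      m <- diag(v, nrow = length(mk))
      dimnames(m) <- list(mk, mk)
      return(m)
    }
    H1 <- data$haplotypes[[parent1]][, mk, drop = FALSE]
    H2 <- data$haplotypes[[parent2]][, mk, drop = FALSE]
    B <- (crossprod(H1) + crossprod(H2)) / 3 -
      (tcrossprod(d1[mk]) + tcrossprod(d2[mk])) / 12
    cc <- haldane(abs(outer(data$map$pos[idx], data$map$pos[idx], "-")))
    att <- if (mode == "phased") 1 - 2 * cc
           else (1 - 4 * cc / 3) * (1 + 2 * alpha)
    m <- B * att
    dimnames(m) <- list(mk, mk)
    m
  })
}

#' Segregation variance from covariance blocks and marker effects
#'
#' Accumulates \eqn{\beta^T M \beta} over the per-chromosome blocks.
#' Tiny negative round-off (within -1e-9) is clamped to 0 with a warning;
#' larger negatives indicate inconsistent inputs and raise an error.
#'
#' @param blocks List of per-chromosome matrices from [build_cov_blocks()].
#' @param effects Named numeric vector of additive marker effects (or a
#'   data frame with `marker` and `effect` columns).
#' @return The additive segregation variance (a single number).
#' @export
segregation_variance <- function(blocks, effects) {
  if (is.data.frame(effects)) {
    effects <- setNames(effects$effect, effects$marker)
  }
  tot <- sum(vapply(blocks, function(m) {
    b <- effects[colnames(m)]
    if (anyNA(b)) abort("effects are missing for some markers in the blocks.")
    drop(crossprod(b, m %*% b))
  }, numeric(1)))
  clamp_variance(tot)
}

clamp_variance <- function(x) {
  if (x < -1e-9) {
    abort(sprintf("negative segregation variance (%.3g): inconsistent inputs.", x))
  }
  if (x < 0) {
    warn(sprintf("variance %.3g clamped to 0 (floating-point round-off).", x))
    x <- 0
  }
  x
}

# Fast path for many crosses: per chromosome precompute
# K = attenuation(c) * (beta beta^T); then for each cross
# beta' (B * att) beta = (1/3) sum_h [h' K h over both parents]
#                        - (1/12) [d1' K d1 + d2' K d2].
segvar_phased_fast <- function(data, crosses, dr = FALSE, alpha = 0) {
  chroms <- split(seq_len(nrow(data$map)), data$map$chrom)
  Ks <- lapply(chroms, function(idx) {
    b <- unname(data$effects[data$map$marker[idx]])
    cc <- haldane(abs(outer(data$map$pos[idx], data$map$pos[idx], "-")))
    att <- if (dr) (1 - 4 * cc / 3) * (1 + 2 * alpha) else 1 - 2 * cc
    att * tcrossprod(b)
  })
  qf <- function(M, v) drop(crossprod(v, M %*% v))
  vapply(seq_len(nrow(crosses)), function(i) {
    p1 <- crosses$parent1[i]; p2 <- crosses$parent2[i]
    tot <- 0
    for (ch in seq_along(chroms)) {
      idx <- chroms[[ch]]
      mk <- data$map$marker[idx]
      K <- Ks[[ch]]
      H1 <- data$haplotypes[[p1]][, mk, drop = FALSE]
      H2 <- data$haplotypes[[p2]][, mk, drop = FALSE]
      hk <- sum((H1 %*% K) * H1) + sum((H2 %*% K) * H2)
      dk <- qf(K, unname(data$dosages[p1, mk])) +
        qf(K, unname(data$dosages[p2, mk]))
      tot <- tot + hk / 3 - dk / 12
    }
    clamp_variance(tot)
  }, numeric(1))
}

segvar_unphased_fast <- function(data, crosses) {
  b2 <- unname(data$effects[data$map$marker])^2
  D <- data$dosages[, data$map$marker, drop = FALSE]
  vapply(seq_len(nrow(crosses)), function(i) {
    v <- var_locus(D[crosses$parent1[i], ], D[crosses$parent2[i], ])
    sum(b2 * v)
  }, numeric(1))
}

#' Predict segregation variance for a set of crosses
#'
#' Computes the closed-form additive segregation variance for each cross
#' of a half-diallel (or a supplied cross list), in the requested modes.
#'
#' @param data Aligned dataset from [seg_align()]; must carry effects.
#' @param crosses Optional data frame with columns `parent1`, `parent2`;
#'   defaults to all half-diallel pairs of the parents in `data`.
#' @param mode Character vector among `"phased"`, `"unphased"`,
#'   `"double_reduction"`; all requested modes become columns.
#' @param alpha Double-reduction rate for the `"double_reduction"` mode.
#' @return A tibble of class `seg_prediction` with columns `parent1`,
#'   `parent2` and `sigma2_phased` / `sigma2_unphased` / `sigma2_dr` as
#'   requested.
#' @examples
#' panel <- synth_parents(n_parents = 4, n_chrom = 2, markers_per_chrom = 20,
#'                        seed = 1)
#' eff <- draw_qtl_effects(panel$map, n_qtl = 10)
#' dat <- seg_align(panel$haplotypes, panel$map, eff)
#' predict_crosses(dat)
#' @export
predict_crosses <- function(data, crosses = NULL,
                            mode = c("phased", "unphased"), alpha = 0) {
  stopifnot(inherits(data, "seg_data"))
  mode <- match.arg(mode, c("phased", "unphased", "double_reduction"),
                    several.ok = TRUE)
  if (is.null(data$effects)) abort("`data` carries no marker effects.")
  if (any(mode != "unphased") && !data$phased) {
    abort("phased haplotypes are required for phased/double-reduction modes.")
  }
  crosses <- if (is.null(crosses)) half_diallel(data) else
    tibble::as_tibble(crosses[c("parent1", "parent2")])
  out <- crosses
  if ("phased" %in% mode) {
    out$sigma2_phased <- segvar_phased_fast(data, crosses)
  }
  if ("unphased" %in% mode) {
    out$sigma2_unphased <- segvar_unphased_fast(data, crosses)
  }
  if ("double_reduction" %in% mode) {
    check_alpha(alpha)
    out$sigma2_dr <- segvar_phased_fast(data, crosses, dr = TRUE,
                                        alpha = alpha)
    attr(out, "alpha") <- alpha
  }
  class(out) <- c("seg_prediction", class(out))
  out
}

#' Predict segregation variance for a single cross
#'
#' Convenience wrapper around [predict_crosses()] for one parent pair.
#'
#' @inheritParams predict_crosses
#' @param parent1,parent2 Parent ids.
#' @return A one-row `seg_prediction` tibble.
#' @export
predict_cross <- function(data, parent1, parent2,
                          mode = c("phased", "unphased"), alpha = 0) {
  predict_crosses(data, tibble(parent1 = parent1, parent2 = parent2),
                  mode = mode, alpha = alpha)
}
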