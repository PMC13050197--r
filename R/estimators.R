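#' @title Progeny-based variance estimators and evaluation metrics
#'
#' @description
#' Two estimators of the segregation variance from a (simulated) family's
#' true genetic values: M1 sums the per-chromosome sample variances,
#' ignoring covariance between QTL on different chromosomes; M2 is the
#' sample variance of the total genetic values, which includes it. Their
#' difference is exactly the summed effect-weighted inter-chromosome
#' sample covariance (`cov_total`), the finite-family correction that can
#' be added to the closed-form phased prediction. All sample statistics
#' use the unbiased n - 1 divisor; the identity `m2 = m1 + cov_total`
#' holds exactly because all three use the same sample and divisor.
#'
#' @name estimators
NULL

family_gchrom <- function(family) {
  if (!inherits(family, "seg_family")) abort("`family` must be a seg_family.")
  if (is.null(family$g_by_chrom)) {
    abort("the family carries no genetic values; simulate with effects.")
  }
  if (family$n < 2) abort("at least 2 progenies are required.")
  family$g_by_chrom
}

#' M1: per-chromosome variance sum
#'
#' Sum over chromosomes of the sample variance of per-chromosome genetic
#' values, ignoring covariance between QTL on different chromosomes. The
#' Monte-Carlo counterpart of the block-diagonal closed-form prediction.
#'
#' @param family A `seg_family` from [simulate_family()] (with effects).
#' @return A single variance value.
#' @export
estimate_m1 <- function(family) {
  g <- family_gchrom(family)
  sum(apply(g, 2, var))
}

#' M2: total variance
#'
#' Sample variance of the total true genetic values, including the
#' covariance between QTL on different chromosomes.
#'
#' @inheritParams estimate_m1
#' @return A single variance value.
#' @export
estimate_m2 <- function(family) {
  g <- family_gchrom(family)
  var(rowSums(g))
}

#' Summed inter-chromosome covariance of a finite family
#'
#' The effect-weighted sample covariance between markers on different
#' chromosomes, \eqn{\sum_{chr \ne chr'} \sum_{i,j} \beta_i\,
#' cov(x_i, x_j)\, \beta_j}, with each unordered chromosome pair counted
#' twice (both ordered pairs), so that `m1 + cov_total = m2` exactly.
#' Computed from per-chromosome genetic-value sums, not marker pairs:
#' it is the off-diagonal mass of the covariance matrix of the
#' n x n_chrom genetic-value matrix.
#'
#' In an infinite family this quantity is 0 (unlinked loci are
#' independent); in small families genetic drift makes it non-zero, which
#' is why closed-form predictions assuming equilibrium drift away from
#' small-family estimates.
#'
#' @inheritParams estimate_m1
#' @return A single (signed) covariance value; 0 for a single-chromosome
#'   genome.
#' @export
cov_total <- function(family) {
  g <- family_gchrom(family)
  if (ncol(g) < 2) return(0)
  cm <- stats::cov(g)
  sum(cm) - sum(diag(cm))
}

# Marker-pair reference implementation of cov_total, O(p^2); retained as
# an independent oracle for the aggregated path.
cov_total_pairwise <- function(family) {
  if (family$n < 2) abort("at least 2 progenies are required.")
  chroms <- split(family$map$marker, family$map$chrom)
  if (length(chroms) < 2) return(0)
  tot <- 0
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (a == b) next
      mka <- chroms[[a]]; mkb <- chroms[[b]]
      cab <- stats::cov(family$dosages[, mka, drop = FALSE],
                        family$dosages[, mkb, drop = FALSE])
      ba <- unname(family$effects[mka]); bb <- unname(family$effects[mkb])
      tot <- tot + drop(crossprod(ba, cab %*% bb))
    }
  }
  tot
}

#' M1, M2 and cov_total of a family in one tibble
#'
#' @inheritParams estimate_m1
#' @return One-row tibble with `parent1`, `parent2`, `n`, `m1`, `m2`,
#'   `cov_total`.
#' @export
family_variance <- function(family) {
  tibble(parent1 = family$parent1, parent2 = family$parent2,
         n = family$n, m1 = estimate_m1(family), m2 = estimate_m2(family),
         cov_total = cov_total(family))
}

#' Finite-family correction of a closed-form prediction
#'
#' Adds the observed inter-chromosome covariance of a progeny sample to
#' the equilibrium phased prediction:
#' \eqn{\sigma^2_{phased-finite} = \sigma^2_{phased} + cov_{total}}.
#' The identity holds exactly by construction.
#'
#' @param pred A `seg_prediction` tibble containing `sigma2_phased` (one
#'   row matching the family's parents, or a single row).
#' @param family A `seg_family` providing the progeny sample.
#' @return `pred` with columns `cov_total` and `sigma2_phased_finite`
#'   filled for the matching cross.
#' @export
finite_prediction <- function(pred, family) {
  if (!"sigma2_phased" %in% names(pred)) {
    abort("`pred` must contain a `sigma2_phased` column.")
  }
  ct <- cov_total(family)
  hit <- pred$parent1 == family$parent1 & pred$parent2 == family$parent2
  if (!any(hit)) {
    hit <- pred$parent1 == family$parent2 & pred$parent2 == family$parent1
  }
  if (!any(hit)) abort("no row of `pred` matches the family's parents.")
  if (!"cov_total" %in% names(pred)) {
    pred$cov_total <- NA_real_
    pred$sigma2_phased_finite <- NA_real_
  }
  pred$cov_total[hit] <- ct
  pred$sigma2_phased_finite[hit] <- pred$sigma2_phased[hit] + ct
  pred
}

#' Mean squared correlation between unlinked loci
#'
#' Average squared Pearson correlation of progeny dosages over a random
#' subsample of marker pairs on different chromosomes. In an infinite
#' family this is 0; in a family of size n the null expectation is of
#' order 1/(n - 1), so the statistic shrinks as families grow. Pairs with
#' zero dosage variance are skipped.
#'
#' @inheritParams estimate_m1
#' @param n_pairs Number of inter-chromosome pairs to sample (default
#'   1e5; capped at the number available).
#' @return Mean squared correlation, or `NaN` (with a warning) when no
#'   polymorphic pair exists.
#' @export
r2_unlinked <- function(family, n_pairs = 1e5) {
  if (!inherits(family, "seg_family")) abort("`family` must be a seg_family.")
  if (family$n < 3) abort("at least 3 progenies are required.")
  chrom <- family$map$chrom[match(colnames(family$dosages),
                                  family$map$marker)]
  sds <- apply(family$dosages, 2, sd)
  ok <- which(sds > 0)
  if (length(ok) < 2 || dplyr::n_distinct(chrom[ok]) < 2) {
    warn("no polymorphic inter-chromosome pair; returning NaN.")
    return(NaN)
  }
  i <- sample(ok, n_pairs, replace = TRUE)
  j <- sample(ok, n_pairs, replace = TRUE)
  keep <- chrom[i] != chrom[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) {
    warn("no polymorphic inter-chromosome pair; returning NaN.")
    return(NaN)
  }
  Z <- scale(family$dosages[, ok, drop = FALSE])
  colnames(Z) <- NULL
  zi <- Z[, match(i, ok), drop = FALSE]
  zj <- Z[, match(j, ok), drop = FALSE]
  r <- colSums(zi * zj) / (family$n - 1)
  mean(r^2)
}

#' Agreement metrics between two estimate vectors
#'
#' Pearson correlation (PCC), root mean square deviation (RMSD) and,
#' when a reference scale `ybar` is supplied, the coefficient of
#' variation of the RMSD, `cv_rmsd = rmsd / ybar`.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @param ybar Optional reference mean used to scale the RMSD.
#' @return One-row tibble with `pcc`, `rmsd`, `cv_rmsd`. `pcc` is `NA`
#'   (with a warning) when either vector is constant.
#' @examples
#' metrics(c(0, 1, 2), c(0, 1, 5))  # rmsd = sqrt(3)
#' @export
metrics <- function(a, b, ybar = NULL) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must have equal length >= 2.")
  }
  pcc <- if (sd(a) == 0 || sd(b) == 0) {
    warn("constant vector: PCC undefined.")
    NA_real_
  } else {
    cor(a, b)
  }
  rmsd <- sqrt(mean((a - b)^2))
  tibble(pcc = pcc, rmsd = rmsd,
         cv_rmsd = if (is.null(ybar)) NA_real_ else rmsd / ybar)
}
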