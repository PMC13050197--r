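#' @title Forward simulation of autotetraploid bivalent meiosis
#'
#' @description
#' Per chromosome, the four homologs of a parent are partitioned uniformly
#' at random into two bivalents (three equiprobable pairings); each
#' bivalent transmits one chromatid, generated from a random starting
#' homolog with crossovers from a Poisson process of rate 1 per Morgan
#' (no interference). The per-interval homolog switch probability then
#' equals the Haldane recombination fraction, so two-locus gamete
#' frequencies match the exact 36-gamete table. A gamete carries one
#' chromatid per bivalent; an F1 progeny is the union of one gamete per
#' parent.
#'
#' @name meiosis-sim
NULL

#' Simulate gametes of one parent
#'
#' Draws `n` gametes (two chromatids each) for every chromosome of an
#' aligned dataset.
#'
#' @param data Aligned, phased dataset from [seg_align()].
#' @param parent Parent id.
#' @param n Number of gametes.
#' @param origins If `TRUE`, also return the homolog of origin (1-4) of
#'   each chromatid at every marker (used by gamete-classification tests).
#' @return For `n > 1` a list with `dosage` (n x p integer matrix of
#'   gamete allele counts, 0-2) plus chromatid allele matrices `ch1`,
#'   `ch2` (and `o1`, `o2` when `origins = TRUE`). For `n = 1` and
#'   `origins = FALSE`, [simulate_gamete()] gives a plain 2 x p matrix.
#' @export
simulate_gametes <- function(data, parent, n, origins = FALSE) {
  stopifnot(inherits(data, "seg_data"), n >= 1)
  H <- parent_haps(data, parent)
  chroms <- split(seq_len(nrow(data$map)), data$map$chrom)
  parts <- lapply(chroms, function(idx) {
    .sim_gametes_chr(H[, data$map$marker[idx], drop = FALSE],
                     data$map$pos[idx], as.integer(n), origins)
  })
  bind <- function(name) {
    m <- do.call(cbind, lapply(parts, `[[`, name))
    colnames(m) <- data$map$marker
    m
  }
  out <- list(ch1 = bind("ch1"), ch2 = bind("ch2"))
  out$dosage <- out$ch1 + out$ch2
  if (origins) {
    out$o1 <- bind("o1")
    out$o2 <- bind("o2")
  }
  out
}

#' Simulate a single gamete
#'
#' @inheritParams simulate_gametes
#' @return A 2 x p 0/1 matrix: the two transmitted chromatids.
#' @export
simulate_gamete <- function(data, parent) {
  g <- simulate_gametes(data, parent, n = 1)
  rbind(g$ch1[1, ], g$ch2[1, ])
}

#' Simulate an F1 family of a bi-parental cross
#'
#' Generates `n` progenies as unions of one simulated gamete per parent
#' and, when the dataset carries marker effects, their true genetic values
#' \eqn{g = x \beta} (additive, so genetic value = breeding value).
#'
#' @inheritParams simulate_gametes
#' @param parent1,parent2 Parent ids.
#' @param n Family size (`>= 1`).
#' @param keep_haplotypes Keep the four progeny chromatid matrices
#'   (memory-heavy; default `FALSE`).
#' @return An object of class `seg_family`: list with `parent1`,
#'   `parent2`, `n`, `dosages` (n x p integer matrix),
#'   `genetic_values` (length-n vector or `NULL`), `g_by_chrom`
#'   (n x n_chrom matrix of per-chromosome genetic values or `NULL`),
#'   `map`, `effects`, and `haplotypes` (list of four n x p chromatid
#'   matrices) when requested.
#' @examples
#' panel <- synth_parents(n_parents = 2, n_chrom = 2, markers_per_chrom = 10,
#'                        seed = 1)
#' eff <- draw_qtl_effects(panel$map, n_qtl = 5)
#' dat <- seg_align(panel$haplotypes, panel$map, eff)
#' fam <- simulate_family(dat, "P01", "P02", n = 20)
#' glance(fam)
#' @export
simulate_family <- function(data, parent1, parent2, n,
                            keep_haplotypes = FALSE) {
  stopifnot(inherits(data, "seg_data"), n >= 1)
  g1 <- simulate_gametes(data, parent1, n)
  g2 <- simulate_gametes(data, parent2, n)
  dos <- g1$dosage + g2$dosage
  fam <- list(parent1 = parent1, parent2 = parent2, n = as.integer(n),
              dosages = dos, map = data$map, effects = data$effects,
              genetic_values = NULL, g_by_chrom = NULL)
  if (!is.null(data$effects)) {
    chroms <- split(data$map$marker, data$map$chrom)
    fam$g_by_chrom <- vapply(chroms, function(mk) {
      drop(dos[, mk, drop = FALSE] %*% unname(data$effects[mk]))
    }, numeric(n))
    if (n == 1) fam$g_by_chrom <- matrix(fam$g_by_chrom, nrow = 1,
                                         dimnames = list(NULL, names(chroms)))
    fam$genetic_values <- rowSums(fam$g_by_chrom)
  }
  if (keep_haplotypes) {
    fam$haplotypes <- list(p1_ch1 = g1$ch1, p1_ch2 = g1$ch2,
                           p2_ch1 = g2$ch1, p2_ch2 = g2$ch2)
  }
  structure(fam, class = "seg_family")
}

#' @method print seg_family
#' @export
print.seg_family <- function(x, ...) {
  cat(sprintf("<seg_family> %s x %s: %d progenies, %d markers\n",
              x$parent1, x$parent2, x$n, ncol(x$dosages)))
  invisible(x)
}

#' Draw additive QTL effects
#'
#' Assigns gamma-distributed additive effects (shape `k = 2`, scale
#' `theta = 0.2` by default, hence mean 0.4) to a random subset of
#' `n_qtl` markers; all other markers get effect 0. Effects are positive
#' (gamma support); sign randomisation is available but off by default.
#'
#' @param map Genetic map tibble (`marker`, `chrom`, `pos`).
#' @param n_qtl Number of QTL (markers with non-zero effect).
#' @param shape,scale Gamma parameters of the effect-size distribution.
#' @param effect_values Optional vector of `n_qtl` effect sizes to assign
#'   to freshly drawn positions (used by the scenario runner, which fixes
#'   effect sizes across runs while re-drawing positions).
#' @param random_sign If `TRUE`, flip each effect's sign with probability
#'   1/2.
#' @return Tibble with columns `marker`, `effect` covering every map
#'   marker.
#' @export
draw_qtl_effects <- function(map, n_qtl = 2000, shape = 2, scale = 0.2,
                             effect_values = NULL, random_sign = FALSE) {
  stopifnot(shape > 0, scale > 0)
  p <- nrow(map)
  if (n_qtl > p) abort("`n_qtl` exceeds the number of mapped markers.")
  if (is.null(effect_values)) {
    effect_values <- rgamma(n_qtl, shape = shape, scale = scale)
  }
  stopifnot(length(effect_values) == n_qtl)
  if (random_sign) {
    effect_values <- effect_values * sample(c(-1, 1), n_qtl, replace = TRUE)
  }
  qtl <- sample.int(p, n_qtl)
  eff <- numeric(p)
  eff[qtl] <- effect_values
  tibble(marker = map$marker, effect = eff)
}
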