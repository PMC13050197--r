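#' @title Exact two-locus gamete and progeny model
#'
#' @description
#' Under bivalent tetrasomic meiosis (no double reduction), an
#' autotetraploid genotype A1B1/A2B2/A3B3/A4B4 at two linked loci produces
#' 36 distinct gametes, each an unordered pair of chromatids. Gametes fall
#' in three classes: 2P (two parental chromatids, probability
#' \eqn{(1-c)^2/6} each), 1P1R (one parental, one recombinant,
#' \eqn{c(1-c)/12} each) and 2R (two recombinant chromatids, \eqn{c^2/6}
#' each), where c is the recombination fraction between the loci. Crossing
#' two parents yields 36 x 36 = 1,296 progeny genotype combinations with
#' product probabilities. This exhaustive model is the brute-force oracle
#' for the closed-form covariance used in [cov_phased()].
#'
#' @name gamete-model
NULL

# The 36 gametes in canonical row order: homolog of origin of the two
# chromatids at locus A and locus B. Recombinant-pair (2R) rows represent
# the allele-content classes (each pools the two chromatid pairs carrying
# the same homolog sets at A and at B, hence probability c^2/6 not c^2/12).
gamete_rows <- function() {
  tp <- combn(4, 2)
  two_p <- cbind(tp[1, ], tp[1, ], tp[2, ], tp[2, ])
  two_r <- rbind(
    c(1, 2, 3, 4), c(1, 2, 4, 3), c(2, 1, 3, 4),
    c(2, 1, 4, 3), c(3, 1, 4, 2), c(1, 3, 2, 4)
  )
  one_p1r <- rbind(
    c(1, 1, 3, 4), c(1, 1, 4, 3), c(2, 2, 3, 4), c(2, 2, 4, 3),
    c(3, 3, 1, 2), c(4, 4, 1, 2), c(3, 3, 2, 1), c(4, 4, 2, 1),
    c(1, 1, 2, 4), c(1, 1, 4, 2), c(3, 3, 2, 4), c(3, 3, 4, 2),
    c(2, 2, 1, 3), c(4, 4, 1, 3), c(2, 2, 3, 1), c(4, 4, 3, 1),
    c(1, 1, 2, 3), c(1, 1, 3, 2), c(4, 4, 2, 3), c(4, 4, 3, 2),
    c(2, 2, 1, 4), c(3, 3, 1, 4), c(2, 2, 4, 1), c(3, 3, 4, 1)
  )
  g <- rbind(two_p, two_r, one_p1r)
  colnames(g) <- c("ha1", "hb1", "ha2", "hb2")
  g
}

gamete_types <- function() {
  rep(c("2P", "2R", "1P1R"), times = c(6, 6, 24))
}

gamete_type_prob <- function(type, c_rate) {
  dplyr::case_when(
    type == "2P"   ~ (1 - c_rate)^2 / 6,
    type == "2R"   ~ c_rate^2 / 6,
    type == "1P1R" ~ c_rate * (1 - c_rate) / 12
  )
}

#' The 36-gamete probability table
#'
#' Probabilities of the 36 two-locus gametes of an autotetraploid genotype
#' under bivalent meiosis, at recombination fraction `c_rate`.
#'
#' @param c_rate Recombination fraction between the two loci, in `[0, 0.5]`.
#' @return Tibble with columns `index`, `gamete` (label such as
#'   `"A1B1/A2B2"`), `type` (`2P`, `1P1R`, `2R`) and `probability`.
#'   Probabilities sum to 1 for any `c_rate`.
#' @examples
#' gamete_probabilities(0)        # only the six parental gametes survive
#' sum(gamete_probabilities(0.3)$probability)
#' @export
gamete_probabilities <- function(c_rate) {
  check_rec_rate(c_rate)
  stopifnot(length(c_rate) == 1)
  g <- gamete_rows()
  type <- gamete_types()
  tibble(
    index = seq_len(36),
    gamete = sprintf("A%dB%d/A%dB%d", g[, 1], g[, 2], g[, 3], g[, 4]),
    type = type,
    probability = gamete_type_prob(type, c_rate)
  )
}

#' Resolve a haplotype argument to one 4 x p matrix (internal)
#' @noRd
resolve_haps <- function(haplotypes, parent = NULL) {
  if (is.list(haplotypes) && !is.data.frame(haplotypes) &&
      !inherits(haplotypes, "seg_data")) {
    if (is.null(parent)) abort("`parent` is required with a list of matrices.")
    return(resolve_haps(haplotypes[[parent]]))
  }
  if (is.matrix(haplotypes)) {
    if (nrow(haplotypes) != 4 || !all(haplotypes %in% c(0, 1))) {
      abort("a haplotype matrix must be 4 x p with 0/1 entries.")
    }
    return(haplotypes)
  }
  if (inherits(haplotypes, "seg_data")) {
    if (is.null(parent)) abort("`parent` is required with a seg_data input.")
    return(parent_haps(haplotypes, parent))
  }
  mats <- hap_matrices(haplotypes)
  mk <- marker_cols(haplotypes)
  mats <- lapply(mats, function(m) { colnames(m) <- mk; m })
  if (is.null(parent)) {
    if (length(mats) != 1) abort("`parent` is required when several parents are present.")
    return(mats[[1]])
  }
  h <- mats[[parent]]
  if (is.null(h)) abort(sprintf("unknown parent '%s'.", parent))
  h
}

locus_index <- function(H, locus) {
  if (is.character(locus)) {
    i <- match(locus, colnames(H))
    if (is.na(i)) abort(sprintf("unknown marker '%s'.", locus))
    return(i)
  }
  as.integer(locus)
}

#' Enumerate the 36 gametes of one parent at two loci
#'
#' Attaches to the gamete probability table the alternative-allele counts
#' contributed by each gamete at the two loci, given the parent's phased
#' haplotypes.
#'
#' @param haplotypes Haplotype table, 4 x p 0/1 matrix, or `seg_data`.
#' @param parent Parent id (needed unless `haplotypes` is a matrix or a
#'   single-parent table).
#' @param locus_a,locus_b Marker names or column indices of the two loci.
#' @param c_rate Recombination fraction in `[0, 0.5]`.
#' @return The [gamete_probabilities()] tibble plus integer columns `a`
#'   and `b`: alternative-allele dosage (0-2) of the gamete at each locus.
#' @examples
#' H <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))  # AB/AB/ab/ab
#' enumerate_gametes(H, locus_a = 1, locus_b = 2, c_rate = 0)
#' @export
enumerate_gametes <- function(haplotypes, parent = NULL, locus_a, locus_b,
                              c_rate) {
  H <- resolve_haps(haplotypes, parent)
  iA <- locus_index(H, locus_a)
  iB <- locus_index(H, locus_b)
  g <- gamete_rows()
  gamete_probabilities(c_rate) |>
    dplyr::mutate(
      a = H[g[, "ha1"], iA] + H[g[, "ha2"], iA],
      b = H[g[, "hb1"], iB] + H[g[, "hb2"], iB]
    )
}

#' Enumerate the 1,296 progeny genotype combinations of a cross
#'
#' Cross product of the two parental 36-gamete distributions. Each row is a
#' pair of parental gametes; its probability is the product of the two
#' gamete probabilities and `xA`, `xB` are the progeny allele dosages (0-4)
#' at the two loci.
#'
#' @inheritParams enumerate_gametes
#' @param parent1,parent2 Parent ids.
#' @param c_rate2 Recombination fraction for parent 2 (defaults to
#'   `c_rate`; the two parents share one genetic map).
#' @return Tibble of 1,296 rows: `gamete1`, `gamete2` (indices into the
#'   36-gamete table), `xA`, `xB`, `probability`.
#' @export
enumerate_progeny <- function(haplotypes, parent1 = NULL, parent2 = NULL,
                              locus_a, locus_b, c_rate, c_rate2 = c_rate) {
  g1 <- enumerate_gametes(haplotypes, parent1, locus_a, locus_b, c_rate)
  g2 <- enumerate_gametes(haplotypes, parent2, locus_a, locus_b, c_rate2)
  idx <- expand.grid(gamete1 = g1$index, gamete2 = g2$index)
  tibble(
    gamete1 = idx$gamete1,
    gamete2 = idx$gamete2,
    xA = g1$a[idx$gamete1] + g2$a[idx$gamete2],
    xB = g1$b[idx$gamete1] + g2$b[idx$gamete2],
    probability = g1$probability[idx$gamete1] * g2$probability[idx$gamete2]
  )
}

#' Brute-force two-locus progeny covariance
#'
#' Computes \eqn{cov(x_A, x_B) = E(x_A x_B) - E(x_A)E(x_B)} by exhaustive
#' enumeration of the 1,296 progeny genotype combinations. This is the
#' oracle against which the closed form [cov_phased()] is validated; the
#' two agree to machine precision for every phasing and every c.
#'
#' @inheritParams enumerate_progeny
#' @return A single covariance value.
#' @examples
#' H <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
#' N <- matrix(0L, 4, 2)
#' hap <- list(P1 = H, P2 = N)
#' # coupling duplex x nulliplex at c = 0 gives 1/3
#' cov_brute_force(rbind(
#'   tibble::tibble(parent = "P1", homolog = 1:4, A = H[, 1], B = H[, 2]),
#'   tibble::tibble(parent = "P2", homolog = 1:4, A = 0L, B = 0L)
#' ), "P1", "P2", "A", "B", c_rate = 0)
#' @export
cov_brute_force <- function(haplotypes, parent1 = NULL, parent2 = NULL,
                            locus_a, locus_b, c_rate, c_rate2 = c_rate) {
  pr <- enumerate_progeny(haplotypes, parent1, parent2, locus_a, locus_b,
                          c_rate, c_rate2)
  sum(pr$probability * pr$xA * pr$xB) -
    sum(pr$probability * pr$xA) * sum(pr$probability * pr$xB)
}

#' Brute-force single-locus progeny variance
#'
#' [cov_brute_force()] with the second locus equal to the first and
#' `c_rate = 0`: the exact variance of the progeny dosage at one locus.
#'
#' @inheritParams cov_brute_force
#' @param locus Marker name or column index.
#' @return A single variance value.
#' @export
var_brute_force <- function(haplotypes, parent1 = NULL, parent2 = NULL,
                            locus) {
  cov_brute_force(haplotypes, parent1, parent2, locus, locus, c_rate = 0)
}
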