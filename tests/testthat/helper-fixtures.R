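# Shared fixtures: canonical two-locus parents and small synthetic panels.

# haplotype tibble from a named list of 4 x p matrices
hap_tbl <- function(mats, markers = NULL) {
  p <- ncol(mats[[1]])
  markers <- markers %||% paste0("M", seq_len(p))
  purrr::imap_dfr(mats, function(H, id) {
    colnames(H) <- markers
    dplyr::bind_cols(tibble::tibble(parent = id, homolog = 1:4),
                     tibble::as_tibble(H))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# AB/AB/ab/ab: coupling duplex at both loci
H_coupling_duplex <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
# AB/Ab/aB/ab: balanced coupling/repulsion duplex (zero phase bracket)
H_balanced <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
H_nulliplex <- matrix(0L, 4, 2)

# all 4 x 2 binary phasings (256)
all_two_locus_phasings <- function() {
  lapply(0:255, function(k) {
    bits <- as.integer(intToBits(k))[1:8]
    matrix(bits, nrow = 4, ncol = 2)
  })
}

# per-parent gamete-level covariance by literal 36-row enumeration; the
# progeny covariance of a cross is the sum of the two parents' values
# because the two gametes are drawn independently
gamete_cov_enum <- function(H, c_rate) {
  g <- enumerate_gametes(H, locus_a = 1, locus_b = 2, c_rate = c_rate)
  sum(g$probability * g$a * g$b) -
    sum(g$probability * g$a) * sum(g$probability * g$b)
}

tiny_aligned <- function(n_parents = 4, n_chrom = 2, markers_per_chrom = 12,
                         n_qtl = 8, seed = 11) {
  panel <- synth_parents(n_parents, n_chrom, markers_per_chrom, seed = seed)
  set.seed(seed + 1)
  eff <- draw_qtl_effects(panel$map, n_qtl = n_qtl)
  seg_align(panel$haplotypes, panel$map, eff)
}
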