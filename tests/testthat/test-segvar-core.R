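test_that("haldane converts Morgan distances to recombination fractions", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.5), 0.5 * (1 - exp(-1)))
  expect_equal(haldane(50), 0.5, tolerance = 1e-12)
  d <- seq(0, 3, by = 0.1)
  expect_true(all(diff(haldane(d)) > 0))
  expect_error(haldane(-0.1), "non-negative")
  expect_equal(haldane_inv(haldane(0.37)), 0.37, tolerance = 1e-12)
})

test_that("cov_phased anchors: zero at c = 0.5, coupling and balanced phases", {
  hap <- hap_tbl(list(P1 = H_coupling_duplex, P2 = H_nulliplex))
  expect_identical(cov_phased(hap, "P1", "P2", "M1", "M2", 0.5), 0)
  expect_equal(cov_phased(hap, "P1", "P2", "M1", "M2", 0), 1 / 3)
  bal <- hap_tbl(list(P1 = H_balanced, P2 = H_balanced))
  for (cc in c(0, 0.1, 0.3, 0.5)) {
    expect_equal(cov_phased(bal, "P1", "P2", "M1", "M2", cc), 0)
  }
})

test_that("var_locus matches brute-force enumeration for all dosage pairs", {
  phase_of <- function(x) {
    H <- matrix(0L, 4, 2)
    if (x > 0) H[seq_len(x), ] <- 1L
    H
  }
  for (x1 in 0:4) {
    for (x2 in 0:4) {
      hap <- hap_tbl(list(P1 = phase_of(x1), P2 = phase_of(x2)))
      expect_equal(var_locus(x1, x2),
                   var_brute_force(hap, "P1", "P2", "M1"),
                   tolerance = 1e-13)
    }
  }
  expect_equal(var_locus(0, 0), 0)
  expect_equal(var_locus(4, 4), 0)
  expect_error(var_locus(5, 0), "0..4")
})

test_that("double-reduction covariance: limits, monotonicity and bounds", {
  hap <- hap_tbl(list(P1 = H_coupling_duplex, P2 = H_nulliplex))
  # at alpha = 0 and c = 0 both pairing models give the bare phase bracket
  expect_equal(cov_double_reduction(hap, "P1", "P2", "M1", "M2", 0, 0),
               cov_phased(hap, "P1", "P2", "M1", "M2", 0))
  # strictly increasing in alpha when the bracket is positive
  vals <- vapply(c(0, 0.05, 0.1, 1 / 6), function(a) {
    cov_double_reduction(hap, "P1", "P2", "M1", "M2", 0.1, a)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # at alpha = 0, c > 0 the quadrivalent attenuation (1 - 4c/3) differs
  # from the bivalent (1 - 2c)
  bracket <- cov_phased(hap, "P1", "P2", "M1", "M2", 0)
  expect_equal(cov_double_reduction(hap, "P1", "P2", "M1", "M2", 0.25, 0),
               bracket * (1 - 1 / 3))
  expect_equal(cov_phased(hap, "P1", "P2", "M1", "M2", 0.25), bracket / 2)
  expect_error(cov_double_reduction(hap, "P1", "P2", "M1", "M2", 0.1, 0.2),
               "1/6")
})

test_that("covariance blocks: structure per mode", {
  dat <- tiny_aligned(n_parents = 3, n_chrom = 2, markers_per_chrom = 6,
                      n_qtl = 6)
  p <- seg_parents(dat)

  unph <- build_cov_blocks(dat, p[1], p[2], mode = "unphased")
  expect_length(unph, 2)
  for (m in unph) {
    expect_true(all(m[upper.tri(m)] == 0))
    mk <- colnames(m)
    expect_equal(diag(m),
                 setNames(var_locus(dat$dosages[p[1], mk],
                                    dat$dosages[p[2], mk]), mk))
  }

  ph <- build_cov_blocks(dat, p[1], p[2], mode = "phased")
  for (m in ph) expect_equal(m, t(m))
  # diagonal of the phased block is the single-locus variance
  expect_equal(diag(ph[[1]]), diag(unph[[1]]))

  # off-diagonal entries match cov_phased pair by pair
  mk <- colnames(ph[[1]])
  pos <- dat$map$pos[match(mk, dat$map$marker)]
  for (i in 1:2) {
    for (j in 3:4) {
      cc <- haldane(abs(pos[i] - pos[j]))
      expect_equal(ph[[1]][i, j],
                   cov_phased(dat, p[1], p[2], mk[i], mk[j], cc),
                   tolerance = 1e-13)
    }
  }
})

test_that("co-located markers get the full (c = 0) phase covariance", {
  H1 <- H_coupling_duplex
  H2 <- matrix(rbinom(8, 1, 0.5), 4, 2)
  hap <- hap_tbl(list(P1 = H1, P2 = H2))
  map <- tibble::tibble(marker = c("M1", "M2"), chrom = "c1",
                        pos = c(0.2, 0.2))
  dat <- seg_align(hap, map)
  blk <- build_cov_blocks(dat, "P1", "P2", mode = "phased")[[1]]
  expect_equal(blk["M1", "M2"],
               cov_phased(hap, "P1", "P2", "M1", "M2", 0))
})

test_that("segregation_variance accumulates the quadratic form", {
  dat <- tiny_aligned(n_parents = 2, n_chrom = 2, markers_per_chrom = 8,
                      n_qtl = 8)
  p <- seg_parents(dat)
  blocks <- build_cov_blocks(dat, p[1], p[2], mode = "phased")
  # zero effects give zero variance
  zero <- setNames(numeric(nrow(dat$map)), dat$map$marker)
  expect_equal(segregation_variance(blocks, zero), 0)
  # reference: dense quadratic form over the block-diagonal matrix
  b <- dat$effects
  ref <- sum(vapply(blocks, function(m) {
    bb <- b[colnames(m)]
    drop(crossprod(bb, m %*% bb))
  }, numeric(1)))
  expect_equal(segregation_variance(blocks, b), ref)
})

test_that("a single duplex QTL gives beta^2 * 2/3", {
  H <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  hap <- hap_tbl(list(P1 = H, P2 = H), markers = "q")
  map <- tibble::tibble(marker = "q", chrom = "c1", pos = 0)
  eff <- tibble::tibble(marker = "q", effect = 1.7)
  dat <- seg_align(hap, map, eff)
  pred <- predict_cross(dat, "P1", "P2")
  expect_equal(pred$sigma2_phased, 1.7^2 * 2 / 3)
  expect_equal(pred$sigma2_unphased, 1.7^2 * 2 / 3)
})

test_that("fast prediction equals the block-matrix path in every mode", {
  dat <- tiny_aligned(n_parents = 4, n_chrom = 3, markers_per_chrom = 10,
                      n_qtl = 20)
  crosses <- half_diallel(dat)
  pred <- predict_crosses(dat, crosses,
                          mode = c("phased", "unphased", "double_reduction"),
                          alpha = 0.08)
  for (i in seq_len(nrow(crosses))) {
    p1 <- crosses$parent1[i]; p2 <- crosses$parent2[i]
    for (md in c("phased", "unphased", "double_reduction")) {
      blocks <- build_cov_blocks(dat, p1, p2, mode = md, alpha = 0.08)
      ref <- segregation_variance(blocks, dat$effects)
      col <- c(phased = "sigma2_phased", unphased = "sigma2_unphased",
               double_reduction = "sigma2_dr")[[md]]
      expect_equal(pred[[col]][i], ref, tolerance = 1e-10)
    }
  }
})

test_that("unphased prediction is the effect-weighted locus-variance sum", {
  dat <- tiny_aligned(n_parents = 3, n_chrom = 2, markers_per_chrom = 15,
                      n_qtl = 12)
  p <- seg_parents(dat)
  pred <- predict_cross(dat, p[1], p[2], mode = "unphased")
  b <- unname(dat$effects[dat$map$marker])
  v <- var_locus(dat$dosages[p[1], dat$map$marker],
                 dat$dosages[p[2], dat$map$marker])
  expect_equal(pred$sigma2_unphased, sum(b^2 * v))
})

test_that("coupling-phase parents gain variance over the unphased model", {
  # both parents duplex in coupling at every locus, positive effects:
  # every off-diagonal bracket is positive, so phased > unphased
  H <- rbind(rep(1, 6), rep(1, 6), rep(0, 6), rep(0, 6))
  hap <- hap_tbl(list(P1 = H, P2 = H))
  map <- tibble::tibble(marker = paste0("M", 1:6), chrom = "c1",
                        pos = seq(0, 0.5, by = 0.1))
  eff <- tibble::tibble(marker = map$marker, effect = 0.3)
  dat <- seg_align(hap, map, eff)
  pred <- predict_cross(dat, "P1", "P2")
  expect_gt(pred$sigma2_phased, pred$sigma2_unphased)

  # balanced coupling/repulsion phasing kills the off-diagonal bracket
  hapb <- hap_tbl(list(P1 = H_balanced, P2 = H_balanced))
  mapb <- tibble::tibble(marker = c("M1", "M2"), chrom = "c1",
                         pos = c(0, 0.1))
  effb <- tibble::tibble(marker = mapb$marker, effect = 0.3)
  datb <- seg_align(hapb, mapb, effb)
  predb <- predict_cross(datb, "P1", "P2")
  expect_equal(predb$sigma2_phased, predb$sigma2_unphased, tolerance = 1e-12)
})

test_that("monomorphic parents give zero variance throughout", {
  H <- matrix(0L, 4, 4)
  hap <- hap_tbl(list(P1 = H, P2 = H))
  map <- tibble::tibble(marker = paste0("M", 1:4), chrom = "c1",
                        pos = seq(0, 0.3, by = 0.1))
  eff <- tibble::tibble(marker = map$marker, effect = runif(4))
  dat <- seg_align(hap, map, eff)
  pred <- predict_cross(dat, "P1", "P2")
  expect_equal(pred$sigma2_phased, 0)
  expect_equal(pred$sigma2_unphased, 0)
})

test_that("phased modes refuse dosage-only input", {
  panel <- synth_parents(2, 1, 5, seed = 9)
  dos <- dosage_of(panel$haplotypes)
  eff <- draw_qtl_effects(panel$map, n_qtl = 3)
  dat <- seg_align(dos, panel$map, eff)
  expect_false(dat$phased)
  expect_error(predict_crosses(dat, mode = "phased"), "phased")
  expect_silent(predict_crosses(dat, mode = "unphased"))
})
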