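two_locus_data <- function(H, d_morgan) {
  hap <- hap_tbl(list(P1 = H))
  map <- tibble::tibble(marker = c("M1", "M2"), chrom = "c1",
                        pos = c(0, d_morgan))
  seg_align(hap, map)
}

# classify simulated gametes into the 36 allele-content classes by the
# homolog sets of origin at the two loci
classify_gametes <- function(g) {
  key <- function(o_a1, o_b1, o_a2, o_b2) {
    a <- pmin(o_a1, o_a2) * 10 + pmax(o_a1, o_a2)
    b <- pmin(o_b1, o_b2) * 10 + pmax(o_b1, o_b2)
    paste(a, b, sep = "/")
  }
  key(g$o1[, 1], g$o1[, 2], g$o2[, 1], g$o2[, 2])
}

table_keys <- function() {
  g <- tetrasegvar:::gamete_rows()
  a <- pmin(g[, "ha1"], g[, "ha2"]) * 10 + pmax(g[, "ha1"], g[, "ha2"])
  b <- pmin(g[, "hb1"], g[, "hb2"]) * 10 + pmax(g[, "hb1"], g[, "hb2"])
  paste(a, b, sep = "/")
}

test_that("at c = 0 every simulated gamete is one of the 6 parental pairs", {
  dat <- two_locus_data(H_coupling_duplex, d_morgan = 0)
  set.seed(101)
  g <- simulate_gametes(dat, "P1", n = 6000, origins = TRUE)
  keys <- classify_gametes(g)
  expected <- table_keys()[1:6]  # the 2P rows
  expect_true(all(keys %in% expected))
  freq <- table(factor(keys, levels = expected)) / length(keys)
  expect_true(all(abs(freq - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / 6000)))
})

test_that("two-locus gamete class frequencies match the exact table", {
  cc <- 0.2
  dat <- two_locus_data(H_coupling_duplex, d_morgan = haldane_inv(cc))
  set.seed(103)
  n <- 2e5
  g <- simulate_gametes(dat, "P1", n = n, origins = TRUE)
  keys <- classify_gametes(g)
  expected <- gamete_probabilities(cc)
  expected$key <- table_keys()
  obs <- table(factor(keys, levels = expected$key)) / n
  se <- sqrt(expected$probability * (1 - expected$probability) / n)
  expect_true(all(abs(as.numeric(obs) - expected$probability) <= 3.5 * se))
})

test_that("single-locus gamete dosage of a duplex parent is hypergeometric", {
  hap <- hap_tbl(list(P1 = matrix(c(1L, 1L, 0L, 0L), 4, 1)), markers = "M1")
  map <- tibble::tibble(marker = "M1", chrom = "c1", pos = 0)
  dat <- seg_align(hap, map)
  set.seed(107)
  n <- 1e5
  g <- simulate_gametes(dat, "P1", n = n)
  freq <- tabulate(g$dosage[, 1] + 1L, nbins = 3) / n
  exp_p <- c(1 / 6, 2 / 3, 1 / 6)
  expect_true(all(abs(freq - exp_p) < 3 * sqrt(exp_p * (1 - exp_p) / n)))
})

test_that("families have Mendelian means and the exact locus variance", {
  dat <- tiny_aligned(n_parents = 2, n_chrom = 2, markers_per_chrom = 10,
                      n_qtl = 10, seed = 17)
  p <- seg_parents(dat)
  set.seed(109)
  fam <- simulate_family(dat, p[1], p[2], n = 20000)
  mid <- (dat$dosages[p[1], ] + dat$dosages[p[2], ]) / 2
  expect_equal(unname(colMeans(fam$dosages)), unname(mid), tolerance = 0.02)

  # duplex x duplex single locus: sample variance near 2/3
  H <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  hap <- hap_tbl(list(A = H, B = H), markers = "q")
  dat1 <- seg_align(hap, tibble::tibble(marker = "q", chrom = "c1", pos = 0))
  set.seed(110)
  fam1 <- simulate_family(dat1, "A", "B", n = 1e5)
  expect_equal(var(fam1$dosages[, 1]), 2 / 3, tolerance = 0.03)
})

test_that("monomorphic parents yield invariant progenies", {
  H <- matrix(1L, 4, 3)
  hap <- hap_tbl(list(A = H, B = H))
  map <- tibble::tibble(marker = paste0("M", 1:3), chrom = "c1",
                        pos = c(0, 0.1, 0.2))
  dat <- seg_align(hap, map)
  fam <- simulate_family(dat, "A", "B", n = 50)
  expect_true(all(fam$dosages == 4L))
})

test_that("progeny dosages equal the sums of the four inherited chromatids", {
  dat <- tiny_aligned(n_parents = 2, n_chrom = 2, markers_per_chrom = 8,
                      seed = 23)
  p <- seg_parents(dat)
  set.seed(111)
  fam <- simulate_family(dat, p[1], p[2], n = 200, keep_haplotypes = TRUE)
  hp <- fam$haplotypes
  expect_equal(fam$dosages,
               hp$p1_ch1 + hp$p1_ch2 + hp$p2_ch1 + hp$p2_ch2)
  expect_true(all(unlist(hp) %in% 0:1))
  # genetic values recompute exactly from dosages and effects
  expect_equal(fam$genetic_values,
               drop(fam$dosages[, fam$map$marker] %*%
                      unname(fam$effects[fam$map$marker])))
})

test_that("simulation is reproducible under a fixed seed", {
  dat <- tiny_aligned(seed = 29)
  p <- seg_parents(dat)
  set.seed(500)
  f1 <- simulate_family(dat, p[1], p[2], n = 50)
  set.seed(500)
  f2 <- simulate_family(dat, p[1], p[2], n = 50)
  expect_identical(f1$dosages, f2$dosages)
  expect_identical(f1$genetic_values, f2$genetic_values)
})

test_that("QTL effects are gamma draws on a random marker subset", {
  panel <- synth_parents(2, 3, 50, seed = 31)
  set.seed(113)
  eff <- draw_qtl_effects(panel$map, n_qtl = 40)
  expect_equal(nrow(eff), 150)
  expect_equal(sum(eff$effect != 0), 40)
  expect_true(all(eff$effect >= 0))
  set.seed(200)
  e1 <- draw_qtl_effects(panel$map, n_qtl = 40)
  set.seed(200)
  e2 <- draw_qtl_effects(panel$map, n_qtl = 40)
  expect_identical(e1, e2)
  # mean of the gamma(2, 0.2) effect-size law is 0.4
  big <- synth_parents(1, 1, 50000, seed = 33)
  set.seed(114)
  eff_big <- draw_qtl_effects(big$map, n_qtl = 50000)
  expect_equal(mean(eff_big$effect), 0.4, tolerance = 0.015)
  expect_error(draw_qtl_effects(panel$map, n_qtl = 1000), "exceeds")
})
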