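#' @title Simulation-study scenario runner
#'
#' @description
#' Reproduces the factorial simulation study design: family size per cross
#' in \{10, 20, 50, 100, 200, 500, 1000, 2000, 5000\}, family-size
#' distribution uniform or gamma, and number of families in
#' \{10, 50, 100, 250, 500\} - 90 scenarios in the default grid. In each
#' of the (default 30) runs of a scenario, crosses are sampled from the
#' half-diallel, QTL positions are re-drawn (effect sizes stay fixed
#' across runs), families are simulated, and the progeny-based estimators
#' M1/M2 are compared against the phased and unphased closed-form
#' predictions by PCC and RMSD; medians are taken across runs.
#'
#' @name scenario-runner
NULL

#' Synthesise a phased autotetraploid founder panel
#'
#' Random phased founders: each homolog allele is an independent
#' Bernoulli(`allele_freq`) draw; marker positions are uniform on
#' `[0, chrom_length]` per chromosome (sorted). A stand-in for a
#' resequencing panel with randomly assigned phases.
#'
#' @param n_parents Number of founders.
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_length Chromosome length in Morgan.
#' @param allele_freq Alternative-allele frequency per homolog.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `haplotypes` (haplotype table: `parent`, `homolog`,
#'   marker columns) and `map` (tibble `marker`, `chrom`, `pos` in
#'   Morgan).
#' @examples
#' panel <- synth_parents(n_parents = 4, n_chrom = 2, markers_per_chrom = 10,
#'                        seed = 42)
#' nrow(half_diallel(unique(panel$haplotypes$parent)))
#' @export
synth_parents <- function(n_parents = 100, n_chrom = 12,
                          markers_per_chrom = 200, chrom_length = 1,
                          allele_freq = 0.5, seed = NULL) {
  stopifnot(n_parents >= 1, n_chrom >= 1, markers_per_chrom >= 1,
            chrom_length > 0, allele_freq >= 0, allele_freq <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- n_chrom * markers_per_chrom
  chrom <- sprintf("chr%02d", rep(seq_len(n_chrom), each = markers_per_chrom))
  pos <- as.vector(vapply(seq_len(n_chrom), function(i) {
    sort(runif(markers_per_chrom, 0, chrom_length))
  }, numeric(markers_per_chrom)))
  marker <- sprintf("%s_m%04d", chrom,
                    rep(seq_len(markers_per_chrom), times = n_chrom))
  map <- tibble(marker = marker, chrom = chrom, pos = pos)
  ids <- sprintf("P%02d", seq_len(n_parents))
  alle <- matrix(rbinom(4 * n_parents * p, 1, allele_freq),
                 nrow = 4 * n_parents, ncol = p)
  colnames(alle) <- marker
  haps <- tibble(parent = rep(ids, each = 4),
                 homolog = rep(1:4, times = n_parents)) |>
    dplyr::bind_cols(tibble::as_tibble(alle))
  list(haplotypes = haps, map = map)
}

#' Build the scenario grid
#'
#' Full factorial grid of family size, family-size distribution and
#' number of crosses; the defaults give the 90-scenario study grid.
#'
#' @param family_sizes Mean family sizes.
#' @param distributions Family-size distributions (`"uniform"`,
#'   `"gamma"`).
#' @param n_crosses Numbers of families.
#' @param n_runs Independent runs per scenario.
#' @param n_qtl Number of QTL.
#' @return Tibble with one row per scenario: `family_size_mean`,
#'   `size_distribution`, `n_cross`, `n_runs`, `n_qtl`.
#' @export
build_grid <- function(family_sizes = c(10, 20, 50, 100, 200, 500,
                                        1000, 2000, 5000),
                       distributions = c("uniform", "gamma"),
                       n_crosses = c(10, 50, 100, 250, 500),
                       n_runs = 30, n_qtl = 2000) {
  stopifnot(all(family_sizes >= 2), all(n_crosses >= 1),
            n_runs >= 1, n_qtl >= 1)
  distributions <- match.arg(distributions, c("uniform", "gamma"),
                             several.ok = TRUE)
  tidyr::expand_grid(
    family_size_mean = family_sizes,
    size_distribution = distributions,
    n_cross = n_crosses
  ) |>
    dplyr::mutate(n_runs = n_runs, n_qtl = n_qtl)
}

#' Draw per-family sizes
#'
#' `"uniform"` gives every family exactly the mean size; `"gamma"` draws
#' i.i.d. gamma sizes (shape `shape`, scale chosen to hit the mean),
#' rounded and floored at 2 so every family supports a sample variance.
#'
#' @param n_cross Number of families.
#' @param family_size_mean Target mean family size (`>= 2`).
#' @param size_distribution `"uniform"` or `"gamma"`.
#' @param shape Gamma shape parameter (the study convention is 2).
#' @return Integer vector of `n_cross` family sizes.
#' @export
draw_family_sizes <- function(n_cross, family_size_mean,
                              size_distribution = c("uniform", "gamma"),
                              shape = 2) {
  size_distribution <- match.arg(size_distribution)
  stopifnot(n_cross >= 1, family_size_mean >= 2, shape > 0)
  if (size_distribution == "uniform") {
    return(rep(as.integer(family_size_mean), n_cross))
  }
  pmax(2L, as.integer(round(
    rgamma(n_cross, shape = shape, scale = family_size_mean / shape)
  )))
}

scenario_comparisons <- c("m1~phased", "m2~phased", "m1~unphased",
                          "m2~unphased", "phased~unphased")

#' Run one scenario
#'
#' Executes `n_runs` independent runs of a scenario on a phased founder
#' panel: sample `n_cross` crosses from the half-diallel, re-draw QTL
#' positions (effect sizes fixed across runs), draw family sizes,
#' simulate each family, estimate M1/M2, compute the phased and unphased
#' closed-form predictions, and record PCC and RMSD for each comparison.
#'
#' @param data Aligned phased dataset from [seg_align()] (effects not
#'   required; QTL are drawn internally).
#' @param n_cross Number of families per run.
#' @param family_size_mean Mean family size.
#' @param size_distribution `"uniform"` or `"gamma"`.
#' @param n_runs Number of independent runs.
#' @param n_qtl Number of QTL per run.
#' @param effect_values Optional fixed vector of `n_qtl` effect sizes;
#'   drawn once from gamma(`shape`, `scale`) when `NULL`.
#' @param shape,scale Gamma parameters for QTL effect sizes.
#' @param size_shape Gamma shape for the family-size distribution.
#' @param seed Optional integer; run r uses seed `seed + r - 1`.
#' @return Object of class `seg_scenario`: list with `config` (tibble),
#'   `runs` (long tibble: `run`, `comparison`, `pcc`, `rmsd`) and
#'   `medians` (per-comparison medians across runs).
#' @export
run_scenario <- function(data, n_cross, family_size_mean,
                         size_distribution = c("uniform", "gamma"),
                         n_runs = 30, n_qtl = 2000, effect_values = NULL,
                         shape = 2, scale = 0.2, size_shape = 2,
                         seed = NULL) {
  stopifnot(inherits(data, "seg_data"))
  if (!data$phased) abort("the scenario runner needs phased parents.")
  size_distribution <- match.arg(size_distribution)
  pool <- half_diallel(data)
  if (n_cross > nrow(pool)) {
    abort(sprintf("n_cross = %d exceeds the %d available half-diallel pairs.",
                  n_cross, nrow(pool)))
  }
  if (is.null(effect_values)) {
    effect_values <- rgamma(n_qtl, shape = shape, scale = scale)
  }
  stopifnot(length(effect_values) == n_qtl)

  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    if (!is.null(seed)) set.seed((seed + r - 1) %% .Machine$integer.max)
    crosses <- pool[sample.int(nrow(pool), n_cross), ]
    eff <- draw_qtl_effects(data$map, n_qtl = n_qtl,
                            effect_values = effect_values)
    qtl <- eff$marker[eff$effect != 0]
    run_data <- seg_subset(data, qtl,
                           effects = setNames(eff$effect, eff$marker)[qtl])
    sizes <- draw_family_sizes(n_cross, family_size_mean,
                               size_distribution, shape = size_shape)
    est <- purrr::map_dfr(seq_len(n_cross), function(i) {
      fam <- simulate_family(run_data, crosses$parent1[i],
                             crosses$parent2[i], n = sizes[i])
      family_variance(fam)
    })
    pred <- predict_crosses(run_data, crosses,
                            mode = c("phased", "unphased"))
    pairs <- list(
      `m1~phased` = list(est$m1, pred$sigma2_phased),
      `m2~phased` = list(est$m2, pred$sigma2_phased),
      `m1~unphased` = list(est$m1, pred$sigma2_unphased),
      `m2~unphased` = list(est$m2, pred$sigma2_unphased),
      `phased~unphased` = list(pred$sigma2_phased, pred$sigma2_unphased)
    )
    purrr::imap_dfr(pairs, function(p, nm) {
      m <- metrics(p[[1]], p[[2]])
      tibble(run = r, comparison = nm, pcc = m$pcc, rmsd = m$rmsd)
    })
  })

  medians <- runs |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(pcc = median(.data$pcc), rmsd = median(.data$rmsd),
                     .groups = "drop")
  structure(
    list(
      config = tibble(n_cross = n_cross,
                      family_size_mean = family_size_mean,
                      size_distribution = size_distribution,
                      n_runs = n_runs, n_qtl = n_qtl,
                      seed = seed %||% NA_integer_),
      runs = runs, medians = medians
    ),
    class = "seg_scenario"
  )
}

#' @method print seg_scenario
#' @export
print.seg_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seg_scenario> n_cross=%d, family size ~ %s(mean %g), %d run(s)\n",
    cfg$n_cross, cfg$size_distribution, cfg$family_size_mean, cfg$n_runs))
  print(x$medians)
  invisible(x)
}

#' Run several scenarios of a grid
#'
#' Maps [run_scenario()] over the rows of a [build_grid()] tibble with a
#' shared founder panel and one fixed QTL effect-size vector.
#'
#' @inheritParams run_scenario
#' @param grid Tibble from [build_grid()] (possibly filtered).
#' @return Long tibble: the grid columns plus per-comparison medians
#'   `pcc` and `rmsd`.
#' @export
run_grid <- function(data, grid, effect_values = NULL, shape = 2,
                     scale = 0.2, size_shape = 2, seed = NULL) {
  if (is.null(effect_values)) {
    effect_values <- rgamma(grid$n_qtl[1], shape = shape, scale = scale)
  }
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sc <- run_scenario(
      data, n_cross = g$n_cross, family_size_mean = g$family_size_mean,
      size_distribution = g$size_distribution, n_runs = g$n_runs,
      n_qtl = g$n_qtl, effect_values = effect_values,
      size_shape = size_shape,
      seed = if (is.null(seed)) NULL else seed + (i - 1) * 1000L
    )
    dplyr::bind_cols(g[rep(1, nrow(sc$medians)), ], sc$medians)
  })
}
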