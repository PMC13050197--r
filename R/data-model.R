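#' @title Genotype tables and the aligned dataset
#'
#' @description
#' Parental genotypes are plain data frames. Phased genotypes ("haplotype
#' tables") have columns `parent`, `homolog` (1-4) and one 0/1 column per
#' marker: four rows per parent, one per homolog. Unphased genotypes
#' ("dosage tables") have a `parent` column and one 0-4 column per marker.
#' [seg_align()] matches genotypes, genetic map and marker effects on their
#' common marker set and returns the validated dataset that all downstream
#' functions consume.
#'
#' @name genotype-tables
NULL

marker_cols <- function(df) {
  setdiff(names(df), c("parent", "homolog"))
}

#' Convert a haplotype table to a list of 4 x p homolog matrices
#' @noRd
hap_matrices <- function(haplotypes) {
  if (!is.data.frame(haplotypes) ||
      !all(c("parent", "homolog") %in% names(haplotypes))) {
    abort("`haplotypes` must be a data frame with `parent` and `homolog` columns.")
  }
  mk <- marker_cols(haplotypes)
  if (length(mk) == 0) abort("`haplotypes` has no marker columns.")
  vals <- as.matrix(haplotypes[mk])
  if (!is.numeric(vals) || anyNA(vals) || !all(vals %in% c(0, 1))) {
    abort("haplotype entries must be 0 or 1 with no missing values.")
  }
  split(seq_len(nrow(haplotypes)), haplotypes$parent) |>
    lapply(function(rows) {
      if (length(rows) != 4) {
        abort("each parent needs exactly 4 homolog rows.")
      }
      ord <- order(haplotypes$homolog[rows])
      m <- vals[rows[ord], , drop = FALSE]
      storage.mode(m) <- "integer"
      rownames(m) <- NULL
      m
    })
}

#' Allele dosage of phased parents
#'
#' Collapses a haplotype table to allele dosages: the dosage of a marker is
#' the sum of its four homolog indicators, \eqn{x = \sum_{h=1}^4 A_h}, an
#' integer in 0-4 (nulliplex to quadruplex).
#'
#' @param haplotypes Haplotype table (see [genotype-tables]).
#' @return A tibble with one row per parent: column `parent` plus one
#'   integer dosage column per marker.
#' @examples
#' h <- tibble::tibble(
#'   parent = "P1", homolog = 1:4,
#'   M1 = c(1L, 1L, 0L, 0L), M2 = c(1L, 0L, 0L, 0L)
#' )
#' dosage_of(h)
#' @export
dosage_of <- function(haplotypes) {
  mats <- hap_matrices(haplotypes)
  out <- lapply(mats, colSums)
  tibble(parent = names(mats)) |>
    dplyr::bind_cols(tibble::as_tibble(do.call(rbind, out)))
}

#' Convert genotypes (phased or dosage table) to a parents x p dosage matrix
#' @noRd
dosage_matrix <- function(genotypes) {
  if ("homolog" %in% names(genotypes)) {
    genotypes <- dosage_of(genotypes)
  }
  mk <- marker_cols(genotypes)
  m <- as.matrix(genotypes[mk])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% 0:4)) {
    abort("dosages must be integers in 0..4 with no missing values.")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$parent
  m
}

#' Align genotypes, genetic map and marker effects
#'
#' Restricts parental genotypes, the genetic map and (optionally) marker
#' effects to their common marker set, in map order (chromosome, then
#' position), and validates all invariants: unique marker ids, four binary
#' homologs per parent (phased input), dosages in 0-4, non-negative map
#' positions. Markers missing from any input are dropped and reported.
#'
#' @param genotypes Haplotype table (phased) or dosage table (unphased);
#'   see [genotype-tables].
#' @param map Data frame with columns `marker`, `chrom`, `pos`.
#' @param effects Optional data frame with columns `marker`, `effect`.
#' @param map_unit Unit of `map$pos`: `"morgan"` (default) or `"cM"`.
#'   Positions are normalised to Morgan internally.
#' @return An object of class `seg_data`: a list with elements
#'   `haplotypes` (named list of 4 x p homolog matrices, `NULL` for
#'   unphased input), `dosages` (parents x p integer matrix), `map`
#'   (tibble, Morgan), `effects` (named numeric vector or `NULL`),
#'   `phased` (logical) and `dropped` (markers discarded per input).
#' @examples
#' panel <- synth_parents(n_parents = 4, n_chrom = 2, markers_per_chrom = 5,
#'                        seed = 1)
#' eff <- draw_qtl_effects(panel$map, n_qtl = 4)
#' seg_align(panel$haplotypes, panel$map, eff)
#' @export
seg_align <- function(genotypes, map, effects = NULL,
                      map_unit = c("morgan", "cM")) {
  map_unit <- match.arg(map_unit)
  if (inherits(genotypes, "seg_data")) {
    # idempotent: re-aligning an aligned dataset is a no-op
    return(genotypes)
  }
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    abort("`map` needs columns `marker`, `chrom`, `pos`.")
  }
  if (anyDuplicated(map$marker)) abort("duplicate marker ids in `map`.")
  gt_mk <- marker_cols(genotypes)
  if (anyDuplicated(gt_mk)) abort("duplicate marker columns in `genotypes`.")
  common <- intersect(gt_mk, map$marker)
  eff_vec <- NULL
  if (!is.null(effects)) {
    if (!all(c("marker", "effect") %in% names(effects))) {
      abort("`effects` needs columns `marker`, `effect`.")
    }
    if (anyDuplicated(effects$marker)) abort("duplicate marker ids in `effects`.")
    if (anyNA(effects$effect) || !all(is.finite(effects$effect))) {
      abort("marker effects must be finite.")
    }
    common <- intersect(common, effects$marker)
  }
  if (length(common) == 0) {
    abort("no markers shared between genotypes, map and effects.")
  }
  dropped <- list(
    genotypes = setdiff(gt_mk, common),
    map = setdiff(map$marker, common),
    effects = if (is.null(effects)) character() else
      setdiff(effects$marker, common)
  )
  n_drop <- length(unique(unlist(dropped)))
  if (n_drop > 0) {
    rlang::inform(sprintf("seg_align: dropped %d marker(s) absent from some input.",
                          n_drop))
  }
  map <- map |>
    dplyr::filter(.data$marker %in% common) |>
    dplyr::mutate(pos = if (map_unit == "cM") .data$pos / 100 else .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select("marker", "chrom", "pos") |>
    tibble::as_tibble()
  if (any(map$pos < 0)) abort("map positions must be >= 0.")
  ord <- map$marker

  phased <- "homolog" %in% names(genotypes)
  haps <- NULL
  if (phased) {
    haps <- hap_matrices(genotypes)
    haps <- lapply(haps, function(m) {
      colnames(m) <- gt_mk
      m[, ord, drop = FALSE]
    })
    dos <- do.call(rbind, lapply(haps, colSums))
    storage.mode(dos) <- "integer"
  } else {
    dos <- dosage_matrix(genotypes)[, ord, drop = FALSE]
  }
  if (!is.null(effects)) {
    eff_vec <- setNames(effects$effect, effects$marker)[ord]
  }
  structure(
    list(haplotypes = haps, dosages = dos, map = map, effects = eff_vec,
         phased = phased, dropped = dropped),
    class = "seg_data"
  )
}

#' @method print seg_data
#' @export
print.seg_data <- function(x, ...) {
  cat(sprintf(
    "<seg_data> %d parents (%s), %d markers on %d chromosome(s)%s\n",
    nrow(x$dosages), if (x$phased) "phased" else "dosage-only",
    nrow(x$map), dplyr::n_distinct(x$map$chrom),
    if (is.null(x$effects)) "" else
      sprintf(", %d non-zero effects", sum(x$effects != 0))
  ))
  invisible(x)
}

#' Parents available in an aligned dataset
#' @param data A `seg_data` object from [seg_align()].
#' @return Character vector of parent ids.
#' @export
seg_parents <- function(data) {
  stopifnot(inherits(data, "seg_data"))
  rownames(data$dosages)
}

#' All half-diallel crosses of a parent set
#'
#' Enumerates the unordered pairs of distinct parents (no selfs, no
#' reciprocals): n parents give n(n-1)/2 crosses.
#'
#' @param parents Character vector of parent ids, or a `seg_data` object.
#' @return Tibble with columns `parent1`, `parent2`.
#' @export
half_diallel <- function(parents) {
  if (inherits(parents, "seg_data")) parents <- seg_parents(parents)
  if (length(parents) < 2) abort("need at least two parents.")
  cmb <- combn(parents, 2)
  tibble(parent1 = cmb[1, ], parent2 = cmb[2, ])
}

#' Subset an aligned dataset to a marker set (internal)
#' @noRd
seg_subset <- function(data, markers, effects = NULL) {
  keep <- data$map$marker %in% markers
  map <- data$map[keep, , drop = FALSE]
  haps <- if (is.null(data$haplotypes)) NULL else
    lapply(data$haplotypes, function(m) m[, map$marker, drop = FALSE])
  eff <- effects %||% data$effects
  if (!is.null(eff)) eff <- eff[map$marker]
  structure(
    list(haplotypes = haps,
         dosages = data$dosages[, map$marker, drop = FALSE],
         map = map, effects = eff, phased = data$phased,
         dropped = data$dropped),
    class = "seg_data"
  )
}

#' Fetch one parent's homolog matrix (internal)
#' @noRd
parent_haps <- function(data, parent) {
  if (!data$phased) abort("phased haplotypes are required for this operation.")
  h <- data$haplotypes[[parent]]
  if (is.null(h)) abort(sprintf("unknown parent '%s'.", parent))
  h
}
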