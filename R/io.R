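#' @title File readers and writers
#'
#' @description
#' Plain-CSV interchange formats (comma separator, `.` decimal, UTF-8,
#' `#`-prefixed metadata lines) plus phased tetraploid VCF ingestion.
#' Haplotype CSV: header `parent,homolog,<marker ids>`, four rows per
#' parent with 0/1 entries. Dosage CSV: `parent,<marker ids>` with 0-4
#' entries. Map CSV: `marker,chrom,pos` (unit declared at read time).
#' Effects CSV: `marker,effect`.
#'
#' @name seg-io
NULL

read_checked <- function(path, required, what) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s '%s' lacks column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  df
}

#' Read a haplotype CSV
#' @param path File path.
#' @return Haplotype tibble (`parent`, `homolog`, marker columns),
#'   validated (four binary homolog rows per parent).
#' @rdname seg-io
#' @export
read_haplotypes_csv <- function(path) {
  df <- read_checked(path, c("parent", "homolog"), "haplotype CSV")
  hap_matrices(df)  # validation only
  df
}

#' Read a dosage CSV
#' @rdname seg-io
#' @export
read_dosages_csv <- function(path) {
  df <- read_checked(path, "parent", "dosage CSV")
  dosage_matrix(df)  # validation only
  df
}

#' Read a genetic map CSV
#' @param map_unit Unit of the `pos` column, `"morgan"` or `"cM"`;
#'   positions are converted to Morgan.
#' @rdname seg-io
#' @export
read_map_csv <- function(path, map_unit = c("morgan", "cM")) {
  map_unit <- match.arg(map_unit)
  df <- read_checked(path, c("marker", "chrom", "pos"), "map CSV")
  if (anyNA(df$pos) || any(df$pos < 0)) {
    bad <- which(is.na(df$pos) | df$pos < 0)[1]
    abort(sprintf("map CSV '%s': invalid position in data row %d.", path, bad))
  }
  df |>
    dplyr::mutate(pos = if (map_unit == "cM") .data$pos / 100 else .data$pos)
}

#' Read a marker-effects CSV
#' @rdname seg-io
#' @export
read_effects_csv <- function(path) {
  df <- read_checked(path, c("marker", "effect"), "effects CSV")
  if (anyNA(df$effect) || !all(is.finite(df$effect))) {
    bad <- which(!is.finite(df$effect))[1]
    abort(sprintf("effects CSV '%s': non-finite effect in data row %d.",
                  path, bad))
  }
  df
}

#' Read phased tetraploid genotypes from a VCF
#'
#' Reads ploidy-4 GT fields (e.g. `0|1|0|1`) into a haplotype table. All
#' genotypes must be phased (`|` separator) and tetraploid; an unphased
#' (`/`) call or wrong ploidy raises an error naming the sample.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Haplotype tibble (`parent`, `homolog`, one column per variant
#'   ID; `chrom_pos` when the ID field is missing).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids)) {
    fx <- vcfR::getFIX(v)
    ids <- paste(fx[, "CHROM"], fx[, "POS"], sep = "_")
  }
  samples <- colnames(gt)
  hap_rows <- lapply(samples, function(s) {
    calls <- gt[, s]
    if (any(grepl("/", calls, fixed = TRUE))) {
      abort(sprintf("sample '%s' has unphased ('/') genotypes; phased '|' GT is required.", s))
    }
    alleles <- strsplit(calls, "|", fixed = TRUE)
    ploidy <- lengths(alleles)
    if (any(ploidy != 4)) {
      abort(sprintf("sample '%s' has ploidy %d at variant %d; ploidy 4 is required.",
                    s, ploidy[ploidy != 4][1], which(ploidy != 4)[1]))
    }
    m <- matrix(as.integer(unlist(alleles)), nrow = 4)
    if (anyNA(m) || !all(m %in% c(0L, 1L))) {
      abort(sprintf("sample '%s' has non-biallelic or missing GT calls.", s))
    }
    colnames(m) <- ids
    tibble(parent = s, homolog = 1:4) |>
      dplyr::bind_cols(tibble::as_tibble(m))
  })
  dplyr::bind_rows(hap_rows)
}

#' Read allele dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise counts alternative
#' alleles in (phased or unphased) ploidy-4 GT fields.
#'
#' @inheritParams read_phased_vcf
#' @return Dosage tibble (`parent`, one 0-4 column per variant).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- t(round(ds))
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- t(apply(gt, c(1, 2), function(g) {
      a <- as.integer(strsplit(g, "[|/]")[[1]])
      if (length(a) != 4 || anyNA(a)) {
        abort("ploidy-4 GT calls without missing alleles are required.")
      }
      sum(a)
    }))
  }
  ids <- rownames(vcfR::extract.gt(v, element = "GT"))
  colnames(dos) <- ids
  tibble(parent = rownames(dos)) |>
    dplyr::bind_cols(tibble::as_tibble(dos))
}

#' Write cross predictions to CSV
#'
#' Writes a `seg_prediction` tibble with `#`-prefixed metadata header
#' lines (seed, mode) followed by the CSV body; doubles keep 17
#' significant digits so the file round-trips bit-exactly.
#'
#' @param pred A non-empty prediction tibble.
#' @param path Output path.
#' @param seed,mode Optional metadata recorded in the header.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path, seed = NULL, mode = NULL) {
  if (nrow(pred) == 0) abort("refusing to write an empty prediction set.")
  hdr <- c(
    if (!is.null(seed)) sprintf("# seed=%s", seed),
    if (!is.null(mode)) sprintf("# mode=%s", paste(mode, collapse = ","))
  )
  body <- pred |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double),
                                ~ sprintf("%.17g", .x)))
  writeLines(hdr, path)
  readr::write_csv(body, path, append = length(hdr) > 0,
                   col_names = TRUE)
  invisible(path)
}
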