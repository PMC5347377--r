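#' Normalize chromosome labels
#'
#' Strips an optional `chr` prefix (any case), uppercases `X`/`Y`/`MT` and
#' maps `M` to `MT`, so that `"chr1"` and `"1"` (or `"chrM"` and `"MT"`)
#' denote the same chromosome. Idempotent, and a bijection on
#' `{1..22, X, Y, MT}` with and without the prefix.
#'
#' @param x Character vector of chromosome labels.
#' @return Normalized character vector.
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "m", "MT"))
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  up <- toupper(x)
  sex_mt <- up %in% c("X", "Y", "M", "MT")
  x[sex_mt] <- up[sex_mt]
  x[x == "M"] <- "MT"
  x
}

# Order chromosome labels karyotype-style: 1..22, X, Y, MT, then anything else.
chrom_order <- function(chroms) {
  num <- suppressWarnings(as.integer(chroms))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chroms == "X", 23L,
                        ifelse(chroms == "Y", 24L,
                               ifelse(chroms == "MT", 25L, 26L))))
  chroms[order(rank, chroms)]
}

new_snv_sets <- function(tbl, subjects, chroms, mode) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "subjects") <- subjects
  attr(tbl, "chroms") <- chrom_order(unique(chroms))
  attr(tbl, "mode") <- mode
  class(tbl) <- c("snv_sets", class(tibble::tibble()))
  tbl
}

#' Build an SNV-set collection from a data frame
#'
#' The collection maps each subject and chromosome to a finite set of SNV
#' keys. A key is a 1-based chromosomal position, optionally carrying its
#' reference and alternate alleles (`mode = "allele"`). This is the object
#' the Jaccard distance is computed on.
#'
#' @param df Data frame with columns `subject`, `chrom`, `pos` and, for
#'   allele-aware collections, `ref` and `alt`.
#' @param subjects Ordered subject ids. Defaults to order of appearance.
#'   Subjects listed here but absent from `df` get empty sets.
#' @param chroms Chromosome universe. Defaults to the chromosomes present;
#'   listing extra chromosomes gives them empty sets for every subject.
#' @param mode `"position"` (default) keys variants by (chrom, pos) only;
#'   `"allele"` keys them by (chrom, pos, ref, alt).
#' @return A tibble of distinct SNV keys, classed `snv_sets`, with the
#'   subject order, chromosome universe and mode stored as attributes.
#' @examples
#' sets <- as_snv_sets(data.frame(
#'   subject = c("A", "A", "B"), chrom = "1", pos = c(100, 200, 100)
#' ))
#' count_snvs(sets)
#' @export
as_snv_sets <- function(df, subjects = NULL, chroms = NULL,
                        mode = c("position", "allele")) {
  mode <- match.arg(mode)
  need <- c("subject", "chrom", "pos")
  if (mode == "allele") need <- c(need, "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("SNV table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$subject <- as.character(df$subject)
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  if (nrow(df) > 0 && any(!is.finite(df$pos) | df$pos < 1)) {
    abort("SNV positions must be integers >= 1")
  }
  if (mode == "allele") {
    bad <- !(df$ref %in% c("A", "C", "G", "T")) |
      !(df$alt %in% c("A", "C", "G", "T")) | df$ref == df$alt
    if (any(bad)) abort("allele-aware keys need single-nucleotide ref != alt")
    df <- dplyr::distinct(df, .data$subject, .data$chrom, .data$pos,
                          .data$ref, .data$alt)
  } else {
    df <- dplyr::distinct(df[need], .data$subject, .data$chrom, .data$pos)
  }
  if (is.null(subjects)) subjects <- unique(df$subject)
  if (!all(df$subject %in% subjects)) {
    abort("SNV table contains subjects not in the subject list")
  }
  if (is.null(chroms)) chroms <- unique(df$chrom) else chroms <- normalize_chrom(chroms)
  new_snv_sets(df, subjects = subjects, chroms = unique(c(chroms, df$chrom)),
               mode = mode)
}

#' @export
print.snv_sets <- function(x, ...) {
  cat(sprintf("<snv_sets> %d subjects, %d chromosomes, %s mode, %d keys\n",
              length(attr(x, "subjects")), length(attr(x, "chroms")),
              attr(x, "mode"), nrow(x)))
  NextMethod()
}

snv_subjects <- function(sets) attr(sets, "subjects")
snv_chroms <- function(sets) attr(sets, "chroms")
snv_mode <- function(sets) attr(sets, "mode")

# Character keys of one subject's set at a scope ("genome" = all chromosomes
# pooled; keys carry the chromosome so the pooled union is collision-free).
subject_keys <- function(sets, subject, scope = "genome") {
  rows <- sets[sets$subject == subject, , drop = FALSE]
  if (!identical(scope, "genome")) rows <- rows[rows$chrom == scope, , drop = FALSE]
  if (identical(attr(sets, "mode"), "allele")) {
    paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")
  } else {
    paste(rows$chrom, rows$pos, sep = ":")
  }
}

#' Drop allele information from an allele-aware collection
#'
#' Projects an allele-aware collection onto position-only keys; per-subject
#' set sizes can only shrink (distinct alternate alleles at one position
#' collapse to one key).
#'
#' @param sets An `snv_sets` collection.
#' @return A position-only `snv_sets` collection over the same subjects and
#'   chromosomes.
#' @export
drop_alleles <- function(sets) {
  stopifnot(inherits(sets, "snv_sets"))
  as_snv_sets(sets[c("subject", "chrom", "pos")],
              subjects = snv_subjects(sets), chroms = snv_chroms(sets),
              mode = "position")
}
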