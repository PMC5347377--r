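#' Extract per-subject SNV sets from VCF files
#'
#' Reads one or more VCF 4.x files (multi-sample or one per subject) and
#' builds the per-subject, per-chromosome sets of SNV keys the clustering
#' operates on. A subject possesses an SNV iff its genotype carries at least
#' one called single-nucleotide alternate allele (het or hom-alt); `0/0` and
#' missing (`./.`) genotypes count as absent. INDELs and other non-SNV
#' alleles are excluded; multi-allelic records are decomposed per alternate
#' allele. Chromosome labels are normalized so `chr1` and `1` unify.
#'
#' @param vcf_paths Character vector of VCF paths (plain or gzipped).
#' @param manifest A `cohort_manifest`; every subject id must appear as a
#'   sample name in exactly one of the VCFs.
#' @param mode `"position"` (default): an SNV is identified by its (chrom,
#'   pos) only, so a multi-allelic record contributes at most one key per
#'   subject. `"allele"`: keys are (chrom, pos, ref, alt), one per
#'   single-nucleotide alternate allele the subject carries.
#' @param pass_only If `TRUE`, keep only records whose FILTER is `PASS` or
#'   `.`. Default `FALSE` (accept all records).
#' @return An [as_snv_sets()] collection with subjects in manifest order.
#' @export
extract_snv_sets <- function(vcf_paths, manifest,
                             mode = c("position", "allele"),
                             pass_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(manifest, "cohort_manifest"))
  found <- character(0)
  pieces <- list()
  contigs <- character(0)
  for (path in vcf_paths) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    samples <- colnames(vcf@gt)[-1]
    dup <- intersect(samples, found)
    if (length(dup) > 0) {
      abort(paste0("subject(s) present in more than one VCF: ",
                   paste(dup, collapse = ", ")))
    }
    take <- intersect(manifest$id, samples)
    found <- c(found, take)
    contigs <- c(contigs, vcf_contigs(vcf))
    if (length(take) > 0) {
      pieces[[path]] <- extract_one_vcf(vcf, take, mode, pass_only, path)
    }
  }
  absent <- setdiff(manifest$id, found)
  if (length(absent) > 0) {
    abort(paste0("manifest subject(s) absent from all VCFs: ",
                 paste(absent, collapse = ", ")))
  }
  tbl <- dplyr::bind_rows(pieces)
  as_snv_sets(tbl, subjects = manifest$id,
              chroms = unique(c(normalize_chrom(contigs), tbl$chrom)),
              mode = mode)
}

vcf_contigs <- function(vcf) {
  meta <- vcf@meta
  hits <- grep("^##contig=<", meta, value = TRUE)
  sub("^##contig=<ID=([^,>]+).*$", "\\1", hits)
}

# One VCF worth of (subject, chrom, pos[, ref, alt]) carrier rows.
extract_one_vcf <- function(vcf, samples, mode, pass_only, path) {
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    return(tibble::tibble(subject = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0)))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(!is.finite(pos) | pos < 1 | is.na(fix[, "CHROM"]) |
                 fix[, "CHROM"] == "")
  if (length(bad) > 0) {
    abort(sprintf("malformed VCF record in %s at data line %d", path, bad[1]))
  }
  keep <- rep(TRUE, nrow(fix))
  if (pass_only) {
    filt <- fix[, "FILTER"]
    keep <- is.na(filt) | filt %in% c("PASS", ".")
  }
  chrom <- normalize_chrom(fix[, "CHROM"])
  ref <- fix[, "REF"]
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                       ",", fixed = TRUE)
  nt <- c("A", "C", "G", "T")
  # Alt-allele indices that are genuine SNVs (single-base ref and alt).
  valid_idx <- lapply(seq_along(alt_list), function(i) {
    if (!keep[i] || !(ref[i] %in% nt)) return(integer(0))
    a <- toupper(alt_list[[i]])
    which(a %in% nt & a != ref[i])
  })
  max_k <- max(c(0L, lengths(alt_list)))
  gtm <- vcf@gt[, samples, drop = FALSE]
  gtm <- sub(":.*", "", gtm)
  # Parse each distinct genotype string once; cells index into the results.
  uv <- unique(as.vector(gtm))
  parsed <- lapply(strsplit(uv, "[/|]"),
                   function(a) suppressWarnings(as.integer(a)))
  cell <- matrix(match(gtm, uv), nrow = nrow(gtm))
  out <- list()
  for (k in seq_len(max_k)) {
    has_k <- vapply(parsed, function(a) any(a == k, na.rm = TRUE), logical(1))
    rows_k <- which(vapply(valid_idx, function(v) k %in% v, logical(1)))
    if (length(rows_k) == 0) next
    carrier <- matrix(has_k[cell[rows_k, , drop = FALSE]],
                      nrow = length(rows_k))
    hit <- which(carrier, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ri <- rows_k[hit[, 1]]
    out[[length(out) + 1]] <- tibble::tibble(
      subject = samples[hit[, 2]],
      chrom = chrom[ri],
      pos = pos[ri],
      ref = ref[ri],
      alt = toupper(vapply(ri, function(i) alt_list[[i]][k], character(1)))
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(subject = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0))
  }
  if (mode == "position") res$ref <- res$alt <- NULL
  res
}
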