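#' Read a cohort manifest
#'
#' A manifest is a tab-separated file with a header and one row per subject,
#' carrying at least the columns `id`, `group`, `population`, `sex` and `age`.
#' Extra columns (for example a `total_snvs` column transcribed from a
#' published cohort table) are kept as-is.
#'
#' @param path Path to a tab-separated manifest file.
#' @return A tibble with one row per subject, classed `cohort_manifest`.
#'   Subject ids are unique; `age` is numeric and non-negative.
#' @examples
#' manifest <- read_manifest(snvclust_example("cohort25.tsv"))
#' dplyr::count(manifest, population, group)
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort_manifest(df)
}

#' Validate a data frame as a cohort manifest
#'
#' @param df A data frame with columns `id`, `group`, `population`, `sex`, `age`.
#' @return The validated manifest tibble, classed `cohort_manifest`.
#' @export
as_cohort_manifest <- function(df) {
  required <- c("id", "group", "population", "sex", "age")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$id <- as.character(df$id)
  if (nrow(df) == 0) {
    warn("manifest has a header but no subject rows")
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated subject id(s) in manifest: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(df$age) | df$age < 0)) {
    abort("manifest ages must be finite and >= 0")
  }
  class(df) <- c("cohort_manifest", class(tibble::tibble()))
  df
}

#' Path to a file shipped with snvclust
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
snvclust_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "snvclust"))
  } else {
    p <- system.file("extdata", file, package = "snvclust")
    if (p == "") abort(paste0("no packaged example file called ", file))
    p
  }
}
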