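#' Jaccard distance between two variant sets
#'
#' The distance between two subjects' SNV sets \eqn{S_1, S_2} is
#' \deqn{J(S_1, S_2) = 1 - |S_1 \cap S_2| / |S_1 \cup S_2|,}
#' i.e. one minus the fraction of the pooled variants the two subjects
#' share. It is 0 for identical sets, 1 for disjoint non-empty sets, and a
#' true metric (it satisfies the triangle inequality). Two empty sets are
#' equal, so \eqn{J(\emptyset, \emptyset) = 0} by convention.
#'
#' @param s1,s2 Vectors interpreted as sets (duplicates ignored); typically
#'   SNV keys such as `"1:1234"`.
#' @param counts If `TRUE`, return a one-row tibble with the distance plus
#'   the diagnostic cardinalities `n1`, `n2`, `n_intersection`, `n_union`.
#' @return The distance in `[0, 1]`, or a tibble when `counts = TRUE`.
#' @examples
#' jaccard_distance(c("1:100", "1:200"), c("1:100", "1:300"))  # 1 - 1/3
#' @export
jaccard_distance <- function(s1, s2, counts = FALSE) {
  s1 <- unique(s1)
  s2 <- unique(s2)
  n_int <- sum(s1 %in% s2)
  n_uni <- length(s1) + length(s2) - n_int
  j <- if (n_uni == 0) 0 else 1 - n_int / n_uni
  if (!counts) return(j)
  tibble::tibble(distance = j, n1 = length(s1), n2 = length(s2),
                 n_intersection = n_int, n_union = n_uni)
}

#' Pairwise Jaccard distance matrix over a cohort
#'
#' Computes the full symmetric matrix of Jaccard distances between all
#' subjects of a collection, on one chromosome or genome-wide. For
#' `scope = "genome"` the per-chromosome sets are pooled; keys carry their
#' chromosome label, so the pooled sets are unions of disjoint pieces.
#'
#' @param sets An [as_snv_sets()] collection.
#' @param scope A chromosome label (normalized or not) or `"genome"`.
#' @return A labeled symmetric matrix classed `snv_dist`, with zero diagonal
#'   and entries in `[0, 1]`; the scope and key mode are kept as attributes.
#' @examples
#' sets <- as_snv_sets(data.frame(
#'   subject = rep(c("A", "B"), c(2, 2)), chrom = "1",
#'   pos = c(100, 200, 100, 300)
#' ))
#' snv_distance_matrix(sets, scope = "1")
#' @export
snv_distance_matrix <- function(sets, scope = "genome") {
  stopifnot(inherits(sets, "snv_sets"))
  if (!identical(scope, "genome")) {
    scope <- normalize_chrom(scope)
    if (!scope %in% snv_chroms(sets)) {
      abort(paste0("unknown chromosome scope '", scope, "'; available: ",
                   paste(snv_chroms(sets), collapse = ", ")))
    }
  }
  subjects <- snv_subjects(sets)
  keys <- lapply(subjects, function(s) subject_keys(sets, s, scope))
  n <- length(subjects)
  D <- matrix(0, n, n, dimnames = list(subjects, subjects))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- jaccard_distance(keys[[i]], keys[[j]])
      }
    }
  }
  new_snv_dist(D, scope = scope, mode = snv_mode(sets))
}

new_snv_dist <- function(D, scope = "genome", mode = "position") {
  attr(D, "scope") <- scope
  attr(D, "mode") <- mode
  class(D) <- c("snv_dist", "matrix", "array")
  D
}

#' @export
print.snv_dist <- function(x, ...) {
  cat(sprintf("<snv_dist> %d subjects, scope %s (%s keys)\n",
              nrow(x), attr(x, "scope"), attr(x, "mode")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' @describeIn snv_distance_matrix Long-format view of a distance matrix:
#'   one row per unordered subject pair.
#' @param x An `snv_dist` matrix.
#' @param ... Unused.
#' @export
tidy.snv_dist <- function(x, ...) {
  labels <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(subject1 = labels[idx[, 1]], subject2 = labels[idx[, 2]],
                 distance = x[idx], scope = attr(x, "scope"))
}

#' @describeIn snv_distance_matrix Heatmap of the pairwise distances.
#' @param object An `snv_dist` matrix.
#' @export
autoplot.snv_dist <- function(object, ...) {
  labels <- rownames(object)
  df <- tidyr::expand_grid(subject1 = labels, subject2 = labels)
  df$distance <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$subject2, levels = labels),
    y = factor(.data$subject1, levels = rev(labels)),
    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Jaccard\ndistance") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pairwise Jaccard distances (",
                                 attr(object, "scope"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
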