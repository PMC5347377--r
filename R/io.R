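#' Write and read PHYLIP square distance matrices
#'
#' The PHYLIP square dialect: first line is the subject count, then one row
#' per subject holding its label and the full row of distances. Values are
#' written with 15 significant digits, so a write/read round trip preserves
#' the matrix to well beyond 12 significant digits.
#'
#' @param D A labeled symmetric matrix with zero diagonal.
#' @param path Output (or input) file path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the labeled matrix, classed `snv_dist`.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as_dist_matrix(D)
  if (any(abs(diag(D)) > 0)) abort("distance matrix diagonal must be zero")
  rows <- vapply(seq_len(nrow(D)), function(i) {
    paste(c(rownames(D)[i], sprintf("%.15g", D[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(as.character(nrow(D)), rows), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) abort("first line must be the subject count")
  if (length(lines) != n + 1) {
    abort(sprintf("expected %d matrix rows, found %d", n, length(lines) - 1))
  }
  labels <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
    if (length(tok) != n + 1) {
      abort(sprintf("row %d has %d values, expected %d", i, length(tok) - 1, n))
    }
    labels[i] <- tok[1]
    D[i, ] <- as.numeric(tok[-1])
  }
  dimnames(D) <- list(labels, labels)
  if (any(!is.finite(D))) abort("distance matrix has non-numeric entries")
  bad <- which(abs(D - t(D)) > 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("matrix is not symmetric: d(%s, %s) != d(%s, %s)",
                  labels[bad[1, 1]], labels[bad[1, 2]],
                  labels[bad[1, 2]], labels[bad[1, 1]]))
  }
  if (any(abs(diag(D)) > 1e-12)) {
    i <- which(abs(diag(D)) > 1e-12)[1]
    abort(sprintf("nonzero diagonal entry for %s", labels[i]))
  }
  new_snv_dist(D, scope = NA_character_, mode = NA_character_)
}

#' Serialize a tree to Newick
#'
#' Writes standard Newick with branch lengths at 6 decimal places. Unrooted
#' trees are serialized from their trifurcating root node; a 2-leaf tree is
#' written with its single edge split evenly across a degree-2 serialization
#' node. Labels containing Newick metacharacters or whitespace are quoted.
#'
#' @param tree A `phylo` tree.
#' @param path Output file path.
#' @param digits Decimal places for branch lengths (default 6).
#' @return The Newick string, invisibly; the file holds the same string.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  fmt <- paste0("%.", digits, "f")
  node_str <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      paste0(node_str(tree$edge[e, 2]), ":",
             sprintf(fmt, tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(node_str(root), ";")
  writeLines(nwk, path)
  invisible(nwk)
}

quote_label <- function(label) {
  if (grepl("[][(){}:;,'\"[:space:]]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}
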