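# Bipartitions induced by the edges of an unrooted tree: for each edge, the
# set of leaf labels on the child side (the other side is the complement).
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- vector("list", n_node)
  fill <- function(node) {
    if (node <= n_tip) {
      below[[node]] <<- tree$tip.label[node]
    } else {
      for (k in kids[[as.character(node)]]) fill(k)
      below[[node]] <<- unlist(below[kids[[as.character(node)]]],
                               use.names = FALSE)
    }
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  fill(root)
  lapply(tree$edge[, 2], function(child) below[[child]])
}

#' Does a set of subjects form a clade?
#'
#' A leaf subset of an unrooted tree "groups together" when some edge
#' separates exactly that subset from all other leaves (a bipartition of the
#' tree; equivalently the subset is monophyletic after rooting outside it).
#' A subset and its complement are clades together; singleton and
#' all-but-one subsets are trivially clades.
#'
#' @param tree A `phylo` tree.
#' @param leaves Character vector of subject ids; must be a non-empty proper
#'   subset of the tree's leaves.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tree <- neighbor_joining(matrix(
#'   c(0, 1, 5, 5, 1, 0, 5, 5, 5, 5, 0, 1, 5, 5, 1, 0), 4,
#'   dimnames = rep(list(c("c1", "c2", "d1", "d2")), 2)))
#' is_clade(tree, c("d1", "d2"))
#' @export
is_clade <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- unique(as.character(leaves))
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown subject id(s): ", paste(unknown, collapse = ", ")))
  }
  n <- length(tree$tip.label)
  if (length(leaves) == 0 || length(leaves) == n) {
    abort("leaf subset must be a non-empty proper subset of the leaves")
  }
  misplaced_leaves(tree, leaves)$count == 0
}

# Minimum number of leaves to prune so that `group` becomes a clade, with
# one optimal removal set. Every split of a pruned tree is the restriction
# of an edge split of the full tree, so it suffices to scan each edge's
# bipartition in both orientations and count the disagreeing leaves.
misplaced_leaves <- function(tree, group) {
  tips <- tree$tip.label
  best <- list(count = length(tips), remove = tips)
  for (side in tree_bipartitions(tree)) {
    for (g_side in list(side, setdiff(tips, side))) {
      remove <- c(setdiff(group, g_side), setdiff(g_side, group))
      if (length(remove) < best$count) {
        best <- list(count = length(remove), remove = remove)
      }
    }
  }
  best
}

#' Evaluate group separation on a cluster tree
#'
#' Formalizes the visual reading of a cohort's cluster tree: does each
#' population form a clade of the full tree, and within each population do
#' the case and control groups form clades once the tree is restricted to
#' that population (other leaves pruned, degree-2 nodes suppressed)? For
#' every class the report also gives the minimum number of leaves whose
#' removal would make it a clade ("misplaced" subjects; 0 iff the clade
#' holds).
#'
#' @param tree A `phylo` tree over the manifest's subjects.
#' @param manifest A `cohort_manifest` covering every leaf.
#' @param outgroup_population Optional population label expected to behave
#'   as the outgroup; recorded in the report and required to match at least
#'   one leaf.
#' @return A tibble classed `separation_report` with one row per evaluated
#'   class: `level` (`"population"` or `"group"`), `population`, `group`,
#'   `n_members`, `n_leaves` (leaves of the tree the class was tested on),
#'   `is_clade`, `n_misplaced`, and a `misplaced` list-column of subject ids.
#' @export
separation_report <- function(tree, manifest, outgroup_population = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(manifest, "cohort_manifest"))
  tips <- tree$tip.label
  uncovered <- setdiff(tips, manifest$id)
  if (length(uncovered) > 0) {
    abort(paste0("manifest does not cover leaf(s): ",
                 paste(uncovered, collapse = ", ")))
  }
  manifest <- manifest[manifest$id %in% tips, , drop = FALSE]
  if (!is.null(outgroup_population) &&
      !any(manifest$population == outgroup_population)) {
    abort(paste0("outgroup population '", outgroup_population,
                 "' matches no leaves"))
  }
  rows <- list()
  add_row <- function(level, population, group, members, on_tree) {
    n <- length(on_tree$tip.label)
    if (length(members) == 0 || length(members) == n) return()
    mis <- misplaced_leaves(on_tree, members)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      level = level, population = population, group = group,
      n_members = length(members), n_leaves = n,
      is_clade = mis$count == 0, n_misplaced = mis$count,
      misplaced = list(sort(mis$remove)))
  }
  for (pop in unique(manifest$population)) {
    members <- manifest$id[manifest$population == pop]
    add_row("population", pop, NA_character_, members, tree)
    sub <- if (length(members) == length(tips)) tree else
      ape::keep.tip(tree, members)
    pop_manifest <- manifest[manifest$population == pop, , drop = FALSE]
    for (grp in unique(pop_manifest$group)) {
      add_row("group", pop, grp, pop_manifest$id[pop_manifest$group == grp],
              sub)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "outgroup") <- outgroup_population
  class(out) <- c("separation_report", class(tibble::tibble()))
  out
}

#' @export
print.separation_report <- function(x, ...) {
  og <- attr(x, "outgroup")
  cat("<separation_report>",
      if (!is.null(og)) paste0(" outgroup: ", og), "\n", sep = "")
  for (i in seq_len(nrow(x))) {
    what <- if (x$level[i] == "population") x$population[i] else
      paste0(x$group[i], " within ", x$population[i])
    cat(sprintf("  %-28s %s (%d/%d members%s)\n", what,
                if (x$is_clade[i]) "clade" else "not a clade",
                x$n_members[i], x$n_leaves[i],
                if (x$n_misplaced[i] > 0)
                  paste0(", ", x$n_misplaced[i], " misplaced") else ""))
  }
  invisible(x)
}

#' @describeIn separation_report One-row summary: do all evaluated classes
#'   form clades?
#' @param x A `separation_report`.
#' @param ... Unused.
#' @export
glance.separation_report <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x), n_clades = sum(x$is_clade),
                 all_clades = all(x$is_clade),
                 total_misplaced = sum(x$n_misplaced))
}
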