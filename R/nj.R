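#' Neighbor-joining cluster tree from a distance matrix
#'
#' From-scratch implementation of the Saitou–Nei neighbor-joining algorithm.
#' At each step the pair \eqn{(i, j)} minimizing
#' \deqn{Q(i, j) = (n - 2)\, d(i, j) - \sum_k d(i, k) - \sum_k d(j, k)}
#' is joined; branch lengths to the new node are
#' \eqn{l_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))} and \eqn{l_j = d(i,j) - l_i}
#' (with \eqn{r} the row sums), and distances to the new node are
#' \eqn{d(u, k) = (d(i,k) + d(j,k) - d(i,j)) / 2}. When three nodes remain
#' they are joined at a trifurcating node with the closed-form lengths.
#' Neighbor joining is exact on additive matrices: it recovers the
#' generating tree's topology and branch lengths.
#'
#' Ties in Q are broken toward the lexicographically smallest (row, column)
#' pair in the current working order, so the output is deterministic.
#' Negative branch lengths are kept by default (faithful NJ);
#' `clamp_negative = TRUE` sets a negative estimate to zero and moves the
#' deficit onto its sister branch, preserving the path length through the
#' join (Kuhner–Felsenstein convention).
#'
#' @param D A labeled symmetric distance matrix (an [snv_distance_matrix()]
#'   result, a base matrix with dimnames, or a `dist`).
#' @param clamp_negative Clamp negative branch-length estimates to zero.
#' @return An unrooted tree of class `c("cluster_tree", "phylo")` whose
#'   leaves are the matrix labels; internal nodes are binary except the
#'   trifurcation at the serialization root.
#' @examples
#' D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tree <- neighbor_joining(D)
#' tree_path_distances(tree)
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  D <- as_dist_matrix(D)
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2) abort("neighbor joining needs at least 2 subjects")

  if (n == 2) {
    # Single edge; serialized through a degree-2 node splitting it evenly.
    half <- D[1, 2] / 2
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(half, half), tip.label = labels, Nnode = 1L)
    class(tree) <- c("cluster_tree", "phylo")
    return(tree)
  }

  active <- seq_len(n)            # phylo node ids of active clusters, working order
  W <- unclass(D)
  next_id <- n + 2L               # pair-join nodes n+2 .. 2n-2; root reserved as n+1
  edges <- matrix(integer(0), 0, 2)
  lengths <- numeric(0)
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(li, lj)
  }

  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(W)
    Q <- (m - 2) * W - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    dij <- W[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clamp_negative) { l <- clamp(li, lj); li <- l[1]; lj <- l[2] }
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lengths <- c(lengths, li, lj)
    du <- (W[i, ] + W[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    W <- rbind(cbind(W[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    active <- c(active[keep], u)
  }

  # Final trifurcation: closed-form star lengths.
  root <- n + 1L
  dab <- W[1, 2]; dac <- W[1, 3]; dbc <- W[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  if (clamp_negative) {
    for (k in 1:3) {
      ls <- c(la, lb, lc)
      if (ls[k] < 0) {
        # spread the deficit over the two sister branches
        ls[-k] <- ls[-k] + ls[k] / 2
        ls[k] <- 0
        la <- ls[1]; lb <- ls[2]; lc <- ls[3]
      }
    }
  }
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                 c(root, active[3]))
  lengths <- c(lengths, la, lb, lc)

  tree <- list(edge = matrix(as.integer(edges), ncol = 2),
               edge.length = lengths, tip.label = labels,
               Nnode = n - 2L)
  class(tree) <- c("cluster_tree", "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (inherits(D, "snv_dist")) D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix")
  if (is.null(rownames(D))) rownames(D) <- colnames(D)
  if (is.null(rownames(D))) rownames(D) <- paste0("S", seq_len(nrow(D)))
  colnames(D) <- rownames(D)
  if (any(!is.finite(D))) abort("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix is not symmetric")
  D
}

#' Leaf-to-leaf path distances of a tree
#'
#' Sums branch lengths along the unique path between every pair of leaves.
#' On a tree built from an additive matrix this reproduces the input matrix.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A labeled symmetric matrix of path lengths, leaves in
#'   `tree$tip.label` order.
#' @export
tree_path_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n_tip)) {
    dist <- rep(NA_real_, n_node)
    dist[s] <- 0
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        w <- nb[k, 1]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + nb[k, 2]
          stack <- c(stack, w)
        }
      }
    }
    D[s, ] <- dist[seq_len(n_tip)]
  }
  D
}

#' @describeIn neighbor_joining Edge list of the tree as a tibble (leaf
#'   edges carry the subject id).
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @export
tidy.cluster_tree <- function(x, ...) {
  n_tip <- length(x$tip.label)
  child <- x$edge[, 2]
  tibble::tibble(parent = x$edge[, 1], child = child,
                 length = x$edge.length,
                 label = ifelse(child <= n_tip, x$tip.label[child], NA))
}
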