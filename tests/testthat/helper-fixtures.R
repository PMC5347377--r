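# Shared fixtures: in-code VCFs, random set collections, random additive
# trees, and brute-force oracles kept independent of the implementation.

write_vcf_fixture <- function(records, samples, path = tempfile(fileext = ".vcf"),
                              contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=1000000>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, ..., filter = ".") {
  paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", c(...)),
        collapse = "\t")
}

toy_manifest <- function(ids, group = "Case", population = "P1") {
  as_cohort_manifest(tibble::tibble(
    id = ids, group = rep_len(group, length(ids)),
    population = rep_len(population, length(ids)),
    sex = "Female", age = 40))
}

# Random per-subject position sets over a shared site universe.
random_collection <- function(n_subjects = 10, n_sites = 200, p = 0.3,
                              chroms = c("1", "2")) {
  universe <- tidyr::expand_grid(chrom = chroms,
                                 pos = seq_len(ceiling(n_sites / length(chroms))))
  universe <- universe[seq_len(n_sites), ]
  rows <- lapply(seq_len(n_subjects), function(i) {
    take <- universe[stats::runif(n_sites) < p, ]
    if (nrow(take) > 0) take$subject <- paste0("S", i)
    take
  })
  df <- dplyr::bind_rows(rows)
  as_snv_sets(df, subjects = paste0("S", seq_len(n_subjects)),
              chroms = chroms)
}

# Independent brute-force Jaccard on explicit sets.
oracle_jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  u <- union(s1, s2)
  if (length(u) == 0) return(0)
  1 - length(intersect(s1, s2)) / length(u)
}

# Random tree with well-separated branch lengths; its cophenetic matrix is
# additive by construction (ape is the oracle side here).
random_additive_tree <- function(n) {
  tree <- ape::rtree(n, br = NULL)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 1)
  tree$tip.label <- paste0("S", seq_len(n))
  tree
}

# Brute-force clade test: drop the edge, flood-fill the two components, and
# compare the leaf partition with the queried subset.
oracle_is_clade <- function(tree, subset) {
  tips <- tree$tip.label
  subset <- sort(unique(subset))
  n_node <- length(tips) + tree$Nnode
  for (drop in seq_len(nrow(tree$edge))) {
    adj <- vector("list", n_node)
    for (e in seq_len(nrow(tree$edge))) {
      if (e == drop) next
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    seen <- rep(FALSE, n_node)
    queue <- tree$edge[drop, 2]
    seen[queue] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    side <- sort(tips[which(seen[seq_along(tips)])])
    if (identical(side, subset) ||
        identical(sort(setdiff(tips, side)), subset)) return(TRUE)
  }
  FALSE
}

# Brute-force minimal leaf removal making `group` a clade.
oracle_misplaced <- function(tree, group, max_k = 3) {
  tips <- tree$tip.label
  clade_after <- function(remove) {
    keep <- setdiff(tips, remove)
    g <- setdiff(group, remove)
    if (length(g) == 0 || length(keep) < 2) return(FALSE)
    if (length(g) == length(keep)) return(TRUE)
    sub <- ape::keep.tip(tree, keep)
    oracle_is_clade(sub, g)
  }
  for (k in 0:max_k) {
    for (set in combn_sets(tips, k)) if (clade_after(set)) return(k)
  }
  NA_integer_
}

combn_sets <- function(x, k) {
  if (k == 0) return(list(character(0)))
  asplit(utils::combn(x, k), 2)
}

# Compact two-population cohort used for replicate experiments: 15 focal
# subjects (10 cases sharing an enriched pool vs 5 controls) plus a 10-subject
# outgroup population with a disjoint pool and roughly half the burden.
replicate_config <- function(seed, case_carriage_case = 0.9,
                             case_carriage_control = 0.1) {
  simulation_config(
    seed = seed,
    chromosomes = c("1" = 3e5, "2" = 2e5),
    populations = list(
      MA = list(n_case = 10, n_control = 5, pool_size = 2000,
                pool_carriage = 0.8, case_pool_size = 400,
                case_carriage_case = case_carriage_case,
                case_carriage_control = case_carriage_control,
                private_rate = 2e-4),
      AU = list(n_case = 5, n_control = 5, pool_size = 1000,
                pool_carriage = 0.85, case_pool_size = 0,
                case_carriage_case = 0, case_carriage_control = 0,
                private_rate = 2e-4)))
}

# One end-to-end replicate: simulate -> VCF -> extraction -> Jaccard -> NJ
# -> separation report. Returns the report plus the distance matrix.
run_replicate <- function(config) {
  sim <- simulate_cohort(config)
  on.exit(unlink(sim$vcf))
  sets <- extract_snv_sets(sim$vcf, sim$manifest)
  D <- snv_distance_matrix(sets, scope = "genome")
  tree <- neighbor_joining(D)
  report <- separation_report(tree, sim$manifest, outgroup_population = "AU")
  list(report = report, D = D, tree = tree, manifest = sim$manifest)
}

case_clade_holds <- function(report) {
  report$is_clade[report$level == "group" & report$population == "MA" &
                    report$group == "Case"]
}
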