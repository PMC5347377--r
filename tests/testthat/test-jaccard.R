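test_that("limit cases and the worked 7/8/3 example are exact", {
  expect_equal(jaccard_distance(c("1:1", "1:2"), c("1:1", "1:2")), 0)
  expect_equal(jaccard_distance(c("1:1", "1:2"), c("1:3", "1:4")), 1)
  expect_equal(jaccard_distance("1:1", c("1:1", "1:2")), 0.5)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  expect_equal(jaccard_distance(character(0), "1:5"), 1)

  # 7-element and 8-element position sets sharing exactly 3 positions:
  # J = 1 - 3 / (7 + 8 - 3) = 0.75
  a <- paste0("1:", c(110, 205, 340, 420, 515, 630, 720))
  b <- paste0("1:", c(205, 420, 630, 810, 870, 905, 950, 990))
  expect_length(unique(a), 7)
  expect_length(unique(b), 8)
  expect_length(intersect(a, b), 3)
  expect_equal(jaccard_distance(a, b), 0.75)
  d <- jaccard_distance(a, b, counts = TRUE)
  expect_equal(d$n_intersection, 3)
  expect_equal(d$n_union, 12)
  expect_equal(d$distance, 1 - d$n_intersection / d$n_union)
})

test_that("distance matrices match a brute-force oracle entry by entry", {
  withr::local_seed(101)
  sets <- random_collection(n_subjects = 10, n_sites = 200, p = 0.3)
  D <- snv_distance_matrix(sets, scope = "genome")
  tbl <- tibble::as_tibble(sets)
  for (i in rownames(D)) {
    for (j in colnames(D)) {
      ki <- paste(tbl$chrom, tbl$pos)[tbl$subject == i]
      kj <- paste(tbl$chrom, tbl$pos)[tbl$subject == j]
      expect_equal(D[i, j], oracle_jaccard(ki, kj))
    }
  }
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("the metric axioms hold on random set triples", {
  withr::local_seed(202)
  universe <- paste0("1:", 1:60)
  violations <- 0
  for (rep in 1:2000) {
    s <- lapply(1:3, function(i) sample(universe, rpois(1, 15) %% 60))
    d12 <- jaccard_distance(s[[1]], s[[2]])
    d13 <- jaccard_distance(s[[1]], s[[3]])
    d23 <- jaccard_distance(s[[2]], s[[3]])
    # symmetry and identity of indiscernibles
    expect_identical(d12, jaccard_distance(s[[2]], s[[1]]))
    same <- setequal(s[[1]], s[[2]])
    if ((d12 == 0) != same) violations <- violations + 1
    # triangle inequality (tiny slack for float roundoff of exact rationals)
    if (d13 > d12 + d23 + 1e-12) violations <- violations + 1
    if (d12 > d13 + d23 + 1e-12) violations <- violations + 1
    if (d23 > d12 + d13 + 1e-12) violations <- violations + 1
  }
  expect_equal(violations, 0)
})

test_that("adding shared keys never increases J; private keys never decrease it", {
  withr::local_seed(303)
  universe <- paste0("1:", 1:100)
  for (rep in 1:200) {
    s1 <- sample(universe, 20)
    s2 <- sample(universe, 25)
    j0 <- jaccard_distance(s1, s2)
    fresh <- setdiff(universe, union(s1, s2))
    shared <- sample(fresh, 1)
    expect_lte(jaccard_distance(c(s1, shared), c(s2, shared)), j0)
    private <- sample(setdiff(fresh, shared), 1)
    expect_gte(jaccard_distance(c(s1, private), s2), j0)
  }
})

test_that("matrices are equivariant under subject reordering", {
  withr::local_seed(404)
  sets <- random_collection(n_subjects = 6, n_sites = 80)
  D <- snv_distance_matrix(sets)
  perm <- sample(snvclust:::snv_subjects(sets))
  sets_perm <- as_snv_sets(tibble::as_tibble(sets), subjects = perm,
                           chroms = snvclust:::snv_chroms(sets))
  D_perm <- snv_distance_matrix(sets_perm)
  expect_equal(unclass(D_perm)[rownames(D), colnames(D)], unclass(D),
               ignore_attr = TRUE)
})

test_that("genome scope pools the per-chromosome sets", {
  withr::local_seed(505)
  sets <- random_collection(n_subjects = 4, n_sites = 100, chroms = c("1", "2"))
  Dg <- snv_distance_matrix(sets, scope = "genome")
  tbl <- tibble::as_tibble(sets)
  pooled <- function(s) paste(tbl$chrom, tbl$pos)[tbl$subject == s]
  expect_equal(Dg["S1", "S2"], oracle_jaccard(pooled("S1"), pooled("S2")))
  expect_error(snv_distance_matrix(sets, scope = "17"), "available: 1, 2")
  expect_equal(unclass(snv_distance_matrix(sets, scope = "chr1")),
               unclass(snv_distance_matrix(sets, scope = "1")),
               ignore_attr = TRUE)
})
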