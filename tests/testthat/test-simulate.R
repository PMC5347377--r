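small_config <- function(seed) {
  simulation_config(seed = seed, chromosomes = c("1" = 4e4, "2" = 4e4),
    populations = list(
      P1 = list(n_case = 4, n_control = 3, pool_size = 400,
                pool_carriage = 0.7, case_pool_size = 150,
                case_carriage_case = 0.9, case_carriage_control = 0.1,
                private_rate = 1e-3),
      P2 = list(n_case = 0, n_control = 4, pool_size = 200,
                pool_carriage = 0.8, case_pool_size = 0,
                case_carriage_case = 0, case_carriage_control = 0,
                private_rate = 1e-3)))
}

test_that("a fixed seed makes the emitted VCF byte-identical", {
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  simulate_cohort(small_config(3), vcf_path = p1)
  simulate_cohort(small_config(3), vcf_path = p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  p3 <- withr::local_tempfile(fileext = ".vcf")
  simulate_cohort(small_config(4), vcf_path = p3)
  expect_false(tools::md5sum(p1) == tools::md5sum(p3))
})

test_that("the emitted VCF is valid, sorted, and readable by a VCF parser", {
  cfg <- small_config(9)
  sim <- simulate_cohort(cfg)
  vcf <- vcfR::read.vcfR(sim$vcf, verbose = FALSE)
  expect_equal(colnames(vcf@gt)[-1], sim$manifest$id)
  pos <- as.integer(vcf@fix[, "POS"])
  chrom <- vcf@fix[, "CHROM"]
  expect_true(all(diff(pos[chrom == "1"]) > 0))
  expect_true(all(diff(pos[chrom == "2"]) > 0))
  expect_true(all(vcf@fix[, "REF"] %in% c("A", "C", "G", "T")))
  expect_true(all(vcf@fix[, "ALT"] %in% c("A", "C", "G", "T")))
  expect_true(all(vcf@fix[, "REF"] != vcf@fix[, "ALT"]))
  expect_true(all(unique(as.vector(vcf@gt[, -1])) %in% c("0/0", "0/1")))
})

test_that("a zero-subject config yields a valid empty VCF and empty manifest", {
  cfg <- simulation_config(seed = 1, chromosomes = c("1" = 1e4),
    populations = list(P1 = list(n_case = 0, n_control = 0, pool_size = 10,
                                 pool_carriage = 0.5, case_pool_size = 0,
                                 case_carriage_case = 0,
                                 case_carriage_control = 0,
                                 private_rate = 0)))
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$manifest), 0)
  lines <- readLines(sim$vcf)
  expect_true(any(grepl("^##fileformat=VCFv4", lines)))
  expect_true(any(grepl("^#CHROM\tPOS", lines)))
})

test_that("pool sizes larger than the genome are rejected", {
  expect_error(simulation_config(chromosomes = c("1" = 100),
    populations = list(P = list(n_case = 1, n_control = 1, pool_size = 200,
                                pool_carriage = .5, case_pool_size = 0,
                                case_carriage_case = 0,
                                case_carriage_control = 0,
                                private_rate = 0))),
    "exceeds total chromosome length")
})

test_that("observed burdens match the closed-form expectations", {
  cfg0 <- small_config(1)
  p <- cfg0$populations$P1
  total_len <- sum(cfg0$chromosomes)
  exp_case <- p$pool_size * p$pool_carriage +
    p$case_pool_size * p$case_carriage_case + p$private_rate * total_len
  var_case <- p$pool_size * p$pool_carriage * (1 - p$pool_carriage) +
    p$case_pool_size * p$case_carriage_case * (1 - p$case_carriage_case) +
    total_len * p$private_rate * (1 - p$private_rate)
  obs <- c()
  for (seed in 1:10) {
    sim <- simulate_cohort(small_config(seed))
    totals <- snv_count_totals(count_snvs(sim$sets, sim$manifest))
    obs <- c(obs, totals$total_snvs[totals$group == "Case" &
                                      totals$population == "P1"])
    unlink(sim$vcf)
  }
  se <- sqrt(var_case / length(obs))
  expect_lt(abs(mean(obs) - exp_case), 3 * se)
})

test_that("expected_jaccard limits and orderings are right", {
  det <- simulation_config(seed = 1, chromosomes = c("1" = 1e4),
    populations = list(P = list(n_case = 2, n_control = 2, pool_size = 100,
                                pool_carriage = 1, case_pool_size = 0,
                                case_carriage_case = 0,
                                case_carriage_control = 0, private_rate = 0)))
  expect_equal(expected_jaccard(det, "P/Case", "P/Control"), 0)

  disj <- simulation_config(seed = 1, chromosomes = c("1" = 1e4),
    populations = list(
      A = list(n_case = 1, n_control = 1, pool_size = 100, pool_carriage = 1,
               case_pool_size = 0, case_carriage_case = 0,
               case_carriage_control = 0, private_rate = 0),
      B = list(n_case = 1, n_control = 1, pool_size = 100, pool_carriage = 1,
               case_pool_size = 0, case_carriage_case = 0,
               case_carriage_control = 0, private_rate = 0)))
  expect_equal(expected_jaccard(disj, "A/Case", "B/Case"), 1)

  expect_error(expected_jaccard(det, "nope", "P/Case"), "role")

  # case-case closer than case-control whenever cases are enriched
  withr::local_seed(66)
  for (rep in 1:20) {
    cc <- runif(1, 0.5, 1)
    ctl <- runif(1, 0, cc - 0.1)
    cfg <- simulation_config(seed = 1, chromosomes = c("1" = 1e5),
      populations = list(P = list(
        n_case = 2, n_control = 2,
        pool_size = sample(500:2000, 1), pool_carriage = runif(1, .3, .9),
        case_pool_size = sample(100:500, 1),
        case_carriage_case = cc, case_carriage_control = ctl,
        private_rate = runif(1, 0, 5e-4))))
    expect_lt(expected_jaccard(cfg, "P/Case", "P/Case"),
              expected_jaccard(cfg, "P/Case", "P/Control"))
  }
})

test_that("Monte-Carlo mean distances converge to the closed form", {
  cfg <- small_config(1)
  expected <- expected_jaccard(cfg, "P1/Case", "P1/Case")
  obs <- c()
  for (seed in 1:8) {
    sim <- simulate_cohort(small_config(seed))
    D <- snv_distance_matrix(sim$sets)
    cases <- sim$manifest$id[sim$manifest$group == "Case" &
                               sim$manifest$population == "P1"]
    Dc <- unclass(D)[cases, cases]
    obs <- c(obs, Dc[upper.tri(Dc)])
    unlink(sim$vcf)
  }
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.002)
})
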