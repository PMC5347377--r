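test_that("SNVs are kept, INDELs excluded, and carriage follows genotypes", {
  # one SNV both samples alt, one SNV only A alt, one 2-bp deletion
  path <- write_vcf_fixture(c(
    vcf_rec("chr1", 100, "A", "G", "0/1", "1/1"),
    vcf_rec("chr1", 200, "C", "T", "0/1", "0/0"),
    vcf_rec("chr1", 300, "CTT", "C", "0/1", "0/1")),
    samples = c("A", "B"))
  sets <- extract_snv_sets(path, toy_manifest(c("A", "B")))
  counts <- snv_count_totals(count_snvs(sets))
  expect_equal(counts$total_snvs[counts$subject == "A"], 2L)
  expect_equal(counts$total_snvs[counts$subject == "B"], 1L)
  expect_false(300 %in% sets$pos)
  expect_true(all(sets$chrom == "1"))  # chr prefix normalized
})

test_that("multi-allelic records decompose per alternate allele", {
  path <- write_vcf_fixture(c(
    vcf_rec("1", 500, "A", "C,T", "1/2", "0/2", "0/0"),
    vcf_rec("1", 600, "G", "C,TT", "0/2", "1/2", "./.")),
    samples = c("A", "B", "C"))
  manifest <- toy_manifest(c("A", "B", "C"))

  pos_mode <- extract_snv_sets(path, manifest, mode = "position")
  tbl <- tibble::as_tibble(pos_mode)
  expect_equal(sum(tbl$subject == "A" & tbl$pos == 500), 1)  # one key only
  expect_equal(sum(tbl$subject == "A" & tbl$pos == 600), 0)  # TT allele is not an SNV
  expect_equal(sum(tbl$subject == "B" & tbl$pos == 600), 1)  # carries the C allele
  expect_equal(sum(tbl$subject == "C"), 0)                   # 0/0 and ./. absent

  aw <- extract_snv_sets(path, manifest, mode = "allele")
  a500 <- tibble::as_tibble(aw)[aw$subject == "A" & aw$pos == 500, ]
  expect_setequal(a500$alt, c("C", "T"))                     # two keys A->C, A->T
  b500 <- tibble::as_tibble(aw)[aw$subject == "B" & aw$pos == 500, ]
  expect_equal(b500$alt, "T")
})

test_that("phased and haploid-style genotypes and FILTER handling work", {
  path <- write_vcf_fixture(c(
    vcf_rec("1", 10, "A", "G", "0|1", "1|1"),
    vcf_rec("1", 20, "A", "G", "0/1", "0/0", filter = "q10"),
    vcf_rec("1", 30, "A", "G", "0/0", "0/1", filter = "PASS")),
    samples = c("A", "B"))
  manifest <- toy_manifest(c("A", "B"))
  all_rec <- extract_snv_sets(path, manifest)
  expect_setequal(all_rec$pos[all_rec$subject == "A"], c(10L, 20L))
  passed <- extract_snv_sets(path, manifest, pass_only = TRUE)
  expect_setequal(passed$pos[passed$subject == "A"], 10L)
  expect_setequal(passed$pos[passed$subject == "B"], c(10L, 30L))
})

test_that("subjects can be split across per-subject VCFs with mixed chrom labels", {
  pa <- write_vcf_fixture(vcf_rec("chr1", 100, "A", "G", "0/1"),
                          samples = "A", contigs = "chr1")
  pb <- write_vcf_fixture(vcf_rec("1", 100, "A", "G", "0/1"),
                          samples = "B", contigs = "1")
  sets <- extract_snv_sets(c(pa, pb), toy_manifest(c("A", "B")))
  D <- snv_distance_matrix(sets, scope = "1")
  expect_equal(D["A", "B"], 0)  # chr1:100 and 1:100 unify

  expect_error(extract_snv_sets(pa, toy_manifest(c("A", "B"))),
               "absent from all VCFs.*B")
  pb2 <- write_vcf_fixture(vcf_rec("1", 100, "A", "G", "0/1"), samples = "A")
  expect_error(extract_snv_sets(c(pa, pb2), toy_manifest("A")),
               "more than one VCF")
})

test_that("extraction is deterministic and recovers the simulator's truth sets", {
  cfg <- simulation_config(seed = 11, chromosomes = c("1" = 5e4, "2" = 5e4),
    populations = list(
      P1 = list(n_case = 3, n_control = 2, pool_size = 300,
                pool_carriage = 0.7, case_pool_size = 100,
                case_carriage_case = 0.9, case_carriage_control = 0.1,
                private_rate = 1e-3)))
  sim <- simulate_cohort(cfg)
  sets1 <- extract_snv_sets(sim$vcf, sim$manifest)
  sets2 <- extract_snv_sets(sim$vcf, sim$manifest)
  sort_keys <- function(s) dplyr::arrange(tibble::as_tibble(s), subject, chrom, pos)
  expect_identical(sort_keys(sets1), sort_keys(sets2))
  expect_identical(sort_keys(sets1), sort_keys(sim$sets))
})

test_that("malformed VCF records are reported with their line", {
  path <- write_vcf_fixture(c(
    vcf_rec("1", 100, "A", "G", "0/1"),
    vcf_rec("1", "-5", "A", "G", "0/1")),
    samples = "A")
  expect_error(suppressWarnings(extract_snv_sets(path, toy_manifest("A"))),
               "malformed VCF record.*line 2")
})
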