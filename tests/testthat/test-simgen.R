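test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_samples = 4), "at least 5")
  expect_error(sim_event("S1", "chr1", 0, 10, 2L, 0.5, "dup"),
               "inconsistent")
  expect_error(sim_event("S1", "chr1", 0, 10, 2L, 1.5, "cnloh"),
               "cell_fraction")
  ped <- tibble::tibble(child = c("A", "B"), parent1 = c("B", "A"),
                        parent2 = c("X", "Y"))
  expect_error(sim_config(pedigree = ped), "cycle")
})

test_that("generators are deterministic given the config seed", {
  cfg <- sim_config(seed = 42, n_samples = 6, n_bins = 100,
                    n_snps = 200, n_het_sites = 100,
                    pedigree = sib_pedigree(2))
  expect_identical(sim_coverage(cfg), sim_coverage(cfg))
  expect_identical(sim_phased_counts(cfg), sim_phased_counts(cfg))
  expect_identical(sim_pedigree_genotypes(cfg), sim_pedigree_genotypes(cfg))
  expect_identical(sim_variant_table(cfg, n_variants = 50),
                   sim_variant_table(cfg, n_variants = 50))
})

test_that("null coverage centers at copy number 2", {
  cfg <- sim_config(seed = 1, n_samples = 10, n_bins = 500)
  cov <- sim_coverage(cfg)
  m <- as.matrix(cov$coverage[, -(1:3)])
  expect_true(abs(mean(m) - 2) < 0.05)
})

test_that("implanted events shift expected copy number by f*(cn-2)", {
  # fixed gain to CN 3 and half-mosaic gain; mean over event bins
  cfg <- sim_config(
    seed = 7, n_samples = 10, n_bins = 1200,
    events = sim_event(c("S001", "S002"), "chr1", c(100, 600),
                       c(150, 1100), c(3L, 3L), c(1, 0.5), c("dup", "dup")))
  cov <- sim_coverage(cfg)
  m <- as.matrix(cov$coverage[, -(1:3)])
  expect_equal(mean(m[101:150, "S001"]), 3.0, tolerance = 0.02)
  # 500 replicate bins at f = 0.5: expectation 2 + 0.5 * 1
  expect_equal(mean(m[601:1100, "S002"]), 2.5, tolerance = 0.02)
})

test_that("phased BAF matches the mixture expectations", {
  cfg0 <- sim_config(seed = 2, n_samples = 5, n_bins = 300,
                     n_het_sites = 2500)
  ph0 <- sim_phased_counts(cfg0)
  baf <- with(ph0$counts, hap1_depth / (hap1_depth + hap2_depth))
  expect_gt(mean(baf), 0.49)
  expect_lt(mean(baf), 0.51)

  cfg1 <- sim_config(seed = 3, n_samples = 5, n_bins = 300,
                     n_het_sites = 2000,
                     events = sim_event("S001", "chr1", 0, 300, 2L, 1,
                                        "cnloh"))
  ph1 <- sim_phased_counts(cfg1)
  x1 <- dplyr::filter(ph1$counts, sample == "S001")
  expect_gt(mean(x1$hap1_depth / (x1$hap1_depth + x1$hap2_depth)), 0.99)

  # mosaic LOH at f = 0.4: expected phased BAF (1 + 0.4) / 2 = 0.7
  cfg2 <- sim_config(seed = 4, n_samples = 5, n_bins = 300,
                     n_het_sites = 1000,
                     events = sim_event("S001", "chr1", 0, 300, 2L, 0.4,
                                        "cnloh"))
  ph2 <- sim_phased_counts(cfg2)
  x2 <- dplyr::filter(ph2$counts, sample == "S001")
  expect_equal(mean(x2$hap1_depth / (x2$hap1_depth + x2$hap2_depth)),
               0.7, tolerance = 0.01)
})

test_that("gene drop reproduces Mendelian IBD sharing", {
  cfg <- sim_config(seed = 5, n_snps = 10000, pedigree = sib_pedigree(1))
  g <- sim_pedigree_genotypes(cfg)
  founders <- g$ibd_truth[g$ibd_truth$relationship == "unrelated", ]
  expect_true(all(founders$ibd0[founders$id1 == "F01"] == 1))
  sib <- g$ibd_truth[g$ibd_truth$relationship == "full_siblings", ]
  expect_equal(nrow(sib), 1)
  # realized IBD2 fraction over 10,000 independent meioses
  expect_equal(sib$ibd2, 0.25, tolerance = 0.02)
  expect_equal(sib$ibd1, 0.50, tolerance = 0.03)
  pc <- g$ibd_truth[g$ibd_truth$relationship == "parent_child", ]
  expect_true(all(pc$ibd1 == 1))
})

test_that("variant-table truth flags apply the printed thresholds", {
  # spot checks of the independent truth logic on constructed records
  v <- tibble::tibble(
    variant_id = c("a", "b", "c"), chrom = "chr2", pos = 1:3,
    ref = "A", alt = "T",
    filter = c("PASS", "PASS", "fail"), lcr = FALSE, segdup = FALSE,
    gnomad_pass_or_missing = TRUE,
    consequence = "missense_variant", gene = "G1",
    exac_af = 1e-4, cadd_phred = 25, dann = c(0.995, 0.95, 0.995),
    fathmm_xf = 0.5, fathmm_cancer = FALSE, cosmic_count = 0L,
    cosmic_tier1 = FALSE, loeuf = 1, cgd_inheritance = "none",
    fertility_gene = FALSE, p53_pathway = FALSE)
  gt <- tibble::tibble(variant_id = c("a", "b", "c"), sample = "S001",
                       gt = 1L, dp = 30L, gq = 90L, ab = 0.5)
  tr <- pluriscan:::sim_variant_truth(v, gt)
  expect_true(tr$pass_deleterious[tr$variant_id == "a"])
  expect_false(tr$pass_deleterious[tr$variant_id == "b"]) # DANN below 0.99
  expect_false(tr$pass_hchq[tr$variant_id == "c"]) # FILTER != PASS
})

test_that("array intensity generator shifts only true-call carriers", {
  samples <- sprintf("S%02d", 1:100)
  calls <- tibble::tibble(
    call_id = c("t1", "f1"), chrom = "chr1",
    start = c(0, 2e5), end = c(1e5, 3e5), type = "del",
    carriers = list(samples[1:3], samples[4:6]))
  truth <- tibble::tibble(call_id = c("t1", "f1"), true = c(TRUE, FALSE))
  ai <- sim_array_intensities(calls, truth, samples, effect_size = 3,
                              seed = 8)
  m <- as.matrix(ai$intensities[, -(1:3)])
  pm <- ai$probe_map
  true_rows <- which(ai$intensities$probe_id %in%
                       pm$probe_id[pm$call_id == "t1"])
  false_rows <- setdiff(seq_len(nrow(m)), true_rows)
  expect_lt(mean(m[true_rows, samples[1:3]]), -1.5)
  expect_lt(abs(mean(m[false_rows, samples[4:6]])), 0.7)
  # strong separation: carriers rank lowest at every probe of the true call
  ranks <- t(apply(m[true_rows, , drop = FALSE], 1, rank))
  expect_true(all(ranks[, samples[1:3]] <= 10))
})
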