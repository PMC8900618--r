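base_variant <- function(...) {
  v <- tibble::tibble(
    variant_id = "v1", chrom = "chr2", pos = 1000L, ref = "A", alt = "T",
    filter = "PASS", lcr = FALSE, segdup = FALSE,
    gnomad_pass_or_missing = TRUE, consequence = "missense_variant",
    gene = "G1", exac_af = 1e-4, cadd_phred = 25, dann = 0.995,
    fathmm_xf = 0.9, fathmm_cancer = TRUE, cosmic_count = 3L,
    cosmic_tier1 = TRUE, loeuf = 0.2, cgd_inheritance = "AD",
    fertility_gene = TRUE, p53_pathway = FALSE)
  dplyr::mutate(v, ...)
}
base_gt <- function(variant_id = "v1", dp = 30L, gq = 40L, ab = 0.45) {
  tibble::tibble(variant_id = variant_id, sample = "S001", gt = 1L,
                 dp = dp, gq = gq, ab = ab)
}

test_that("HC-HQ filter requires every site and genotype condition", {
  v <- base_variant()
  expect_equal(nrow(hc_hq_filter(v, base_gt())), 1)
  expect_equal(nrow(hc_hq_filter(v, base_gt(dp = 9L))), 0)
  expect_equal(nrow(hc_hq_filter(v, base_gt(gq = 19L))), 0)
  expect_equal(nrow(hc_hq_filter(v, base_gt(ab = 0.19))), 0)
  expect_equal(nrow(hc_hq_filter(dplyr::mutate(v, filter = "fail"),
                                 base_gt())), 0)
  expect_equal(nrow(hc_hq_filter(dplyr::mutate(v, lcr = TRUE),
                                 base_gt())), 0)
  expect_equal(nrow(hc_hq_filter(dplyr::mutate(v, segdup = TRUE),
                                 base_gt())), 0)
  expect_equal(nrow(hc_hq_filter(
    dplyr::mutate(v, gnomad_pass_or_missing = FALSE), base_gt())), 0)
  # one qualifying genotype among several suffices
  gts <- dplyr::bind_rows(base_gt(dp = 5L), base_gt())
  expect_equal(nrow(hc_hq_filter(v, gts)), 1)
})

test_that("consequence binning follows the printed term lists", {
  expect_equal(bin_consequence("stop_gained"), "lof")
  expect_equal(bin_consequence("splice_donor_variant"), "lof")
  expect_equal(bin_consequence("inframe_deletion"), "missense")
  expect_equal(bin_consequence("stop_retained_variant"), "synonymous")
  expect_equal(bin_consequence("intron_variant"), "other")
  expect_warning(out <- bin_consequence(""), "other")
  expect_equal(out, "other")
})

test_that("deleterious filter applies strict AF/CADD/DANN thresholds", {
  expect_equal(nrow(deleterious_filter(base_variant())), 1)
  expect_equal(nrow(deleterious_filter(base_variant(exac_af = 0.002))), 0)
  expect_equal(nrow(deleterious_filter(base_variant(cadd_phred = 20))), 0)
  expect_equal(nrow(deleterious_filter(base_variant(dann = 0.99))), 0)
  expect_equal(nrow(deleterious_filter(
    base_variant(consequence = "synonymous_variant"))), 0)
  # missing annotation fails, never passes
  expect_equal(nrow(deleterious_filter(base_variant(dann = NA_real_))), 0)
})

test_that("cancer, fertility and disease shortlists apply their criteria", {
  v <- base_variant(dann = 0.9995, exac_af = 1e-6)
  expect_equal(nrow(cancer_filter(v)), 1)
  expect_equal(nrow(cancer_filter(base_variant(cosmic_count = 1L))), 0)
  expect_equal(nrow(cancer_filter(base_variant(cosmic_tier1 = FALSE))), 0)
  expect_equal(nrow(cancer_filter(base_variant(fathmm_cancer = FALSE))), 0)

  expect_equal(nrow(fertility_filter(v)), 1)
  # LOEUF inclusive at 0.33 for the fertility shortlist
  expect_equal(nrow(fertility_filter(base_variant(loeuf = 0.33))), 1)
  expect_equal(nrow(fertility_filter(base_variant(loeuf = 0.4))), 0)
  expect_equal(nrow(fertility_filter(
    base_variant(cgd_inheritance = "AR"))), 0)
  expect_equal(nrow(fertility_filter(
    base_variant(fertility_gene = FALSE))), 0)

  expect_equal(nrow(disease_filter(v)), 1)
  # LOEUF strict below 0.33 for the disease shortlist
  expect_equal(nrow(disease_filter(dplyr::mutate(v, loeuf = 0.33))), 0)
  expect_equal(nrow(disease_filter(dplyr::mutate(v, fathmm_xf = 0.7))), 0)
  expect_equal(nrow(disease_filter(dplyr::mutate(v, dann = 0.999))), 0)
  expect_equal(nrow(disease_filter(dplyr::mutate(v, exac_af = 1e-4))), 0)
  expect_equal(nrow(disease_filter(dplyr::mutate(v, chrom = "chrX"))), 0)
})

test_that("cascade survivors are monotone and idempotent", {
  cfg <- sim_config(seed = 51, n_samples = 12)
  vt <- sim_variant_table(cfg, n_variants = 600)
  res <- run_snv_cascade(vt$variants, vt$genotypes)
  f <- res$flags
  expect_true(all(!f$pass_deleterious | f$pass_hchq))
  expect_true(all(!f$pass_cancer | f$pass_deleterious))
  expect_true(all(!f$pass_fertility | f$pass_deleterious))
  expect_true(all(!f$pass_disease | f$pass_deleterious))
  # survivor counts strictly non-increasing through the chain
  counts <- c(nrow(vt$variants), sum(f$pass_hchq), sum(f$pass_deleterious),
              sum(f$pass_disease))
  expect_true(all(diff(counts) <= 0))
  # idempotence: re-running a filter on its own output changes nothing
  dele <- res$shortlists$deleterious
  expect_equal(deleterious_filter(dplyr::select(dele, -"bin")), dele)
  expect_equal(cancer_filter(res$shortlists$cancer),
               res$shortlists$cancer)
})

test_that("cascade agrees exactly with the simulator's independent truth", {
  for (sd in c(52, 53)) {
    cfg <- sim_config(seed = sd, n_samples = 10)
    vt <- sim_variant_table(cfg, n_variants = 800)
    f <- run_snv_cascade(vt$variants, vt$genotypes)$flags
    expect_identical(f$pass_hchq, vt$truth$pass_hchq)
    expect_identical(f$bin, vt$truth$bin)
    expect_identical(f$pass_deleterious, vt$truth$pass_deleterious)
    expect_identical(f$pass_cancer, vt$truth$pass_cancer)
    expect_identical(f$pass_fertility, vt$truth$pass_fertility)
    expect_identical(f$pass_disease, vt$truth$pass_disease)
  }
})

test_that("burden summary counts carried variants per sample", {
  expect_equal(nrow(burden_summary(
    tibble::tibble(variant_id = character(), bin = character(),
                   pass_hchq = logical(), pass_deleterious = logical(),
                   pass_cancer = logical(), pass_fertility = logical(),
                   pass_disease = logical()),
    tibble::tibble(variant_id = character(), sample = character(),
                   gt = integer()),
    samples = c("A", "B"))$per_sample), 2)
  # ten samples sharing one LoF each: mean burden 1
  flags <- tibble::tibble(variant_id = sprintf("v%02d", 1:10), bin = "lof",
                          pass_hchq = TRUE, pass_deleterious = FALSE,
                          pass_cancer = FALSE, pass_fertility = FALSE,
                          pass_disease = FALSE)
  gts <- tibble::tibble(variant_id = sprintf("v%02d", 1:10),
                        sample = sprintf("S%02d", 1:10), gt = 1L)
  b <- burden_summary(flags, gts)
  expect_true(all(b$per_sample$n_lof == 1))
  expect_equal(b$cohort$mean[b$cohort$class == "lof"], 1)
  # counts equal the simulator truth tallies exactly
  cfg <- sim_config(seed = 54, n_samples = 8)
  vt <- sim_variant_table(cfg, n_variants = 400)
  got <- burden_summary(run_snv_cascade(vt$variants, vt$genotypes)$flags,
                        vt$genotypes)
  want <- vt$genotypes |>
    dplyr::filter(gt > 0) |>
    dplyr::inner_join(vt$truth, by = "variant_id") |>
    dplyr::count(sample, wt = pass_deleterious, name = "want")
  cmp <- dplyr::inner_join(got$per_sample, want, by = "sample")
  expect_equal(cmp$n_deleterious, cmp$want)
})
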