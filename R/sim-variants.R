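#' Simulate an annotated SNV call set with known cascade truth
#'
#' Generates a table of annotated single-nucleotide variants plus per-sample
#' genotype metrics, with annotation values drawn so that every stage of the
#' prioritization cascade sees both passing and failing records. A fraction of
#' records is drawn from an "enriched" regime (rare, high CADD/DANN, COSMIC /
#' constraint hits) so the deep shortlists are non-empty at modest table sizes.
#'
#' The returned `truth` flags are computed here by a direct, self-contained
#' re-application of the filter thresholds: this code path shares nothing with
#' the cascade module, so exact agreement between the two is a meaningful
#' cross-check rather than a tautology.
#'
#' @param cfg a [sim_config()] (`seed`, `n_samples` used).
#' @param n_variants number of variant records.
#' @param frac_enriched fraction drawn from the enriched regime.
#' @return list with `variants` (annotation tibble), `genotypes` (per-variant
#'   per-carrier `gt`, `dp`, `gq`, `ab`) and `truth` (per-variant stage flags).
#' @export
sim_variant_table <- function(cfg, n_variants = 500, frac_enriched = 0.3) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- sim_sample_ids(cfg$n_samples)
  n <- n_variants

  with_seed(cfg$seed + 404L, {
    consequences <- c("stop_gained", "frameshift_variant",
                      "splice_acceptor_variant", "splice_donor_variant",
                      "missense_variant", "inframe_deletion",
                      "inframe_insertion", "start_lost", "stop_lost",
                      "protein_altering_variant", "synonymous_variant",
                      "stop_retained_variant", "intron_variant",
                      "intergenic_variant", "5_prime_UTR_variant")
    enriched <- runif(n) < frac_enriched
    v <- tibble(
      variant_id = sprintf("var%05d", seq_len(n)),
      chrom = sample(c(paste0("chr", 1:22), "chrX"), n, replace = TRUE,
                     prob = c(rep(1, 22), 0.6)),
      pos = sample.int(1e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      filter = ifelse(runif(n) < 0.9, "PASS", "VQSRTrancheSNP"),
      lcr = runif(n) < 0.05,
      segdup = runif(n) < 0.05,
      gnomad_pass_or_missing = runif(n) < 0.95,
      consequence = ifelse(enriched,
                           sample(consequences[1:10], n, replace = TRUE),
                           sample(consequences, n, replace = TRUE)),
      gene = sprintf("GENE%03d", sample.int(120, n, replace = TRUE)),
      exac_af = ifelse(enriched, 10^runif(n, -8, -3.2), 10^runif(n, -6, -0.5)),
      cadd_phred = ifelse(enriched, runif(n, 15, 45), runif(n, 0, 35)),
      dann = ifelse(enriched, 1 - 10^runif(n, -5, -1.3), runif(n, 0.2, 1)),
      fathmm_xf = runif(n),
      fathmm_cancer = runif(n) < ifelse(enriched, 0.5, 0.1),
      cosmic_count = rpois(n, ifelse(enriched, 2.5, 0.3)),
      cosmic_tier1 = runif(n) < ifelse(enriched, 0.5, 0.08),
      loeuf = ifelse(enriched, runif(n, 0.02, 0.6), runif(n, 0.05, 2)),
      cgd_inheritance = sample(c("AD", "AR", "none"), n, replace = TRUE,
                               prob = c(0.35, 0.25, 0.4)),
      fertility_gene = runif(n) < ifelse(enriched, 0.3, 0.05),
      p53_pathway = runif(n) < 0.05
    )
    # sprinkle missing annotations; the cascade must treat these as failures
    for (col in c("exac_af", "cadd_phred", "dann", "fathmm_xf", "loeuf"))
      v[[col]][runif(n) < 0.02] <- NA_real_

    gt <- purrr::map_dfr(seq_len(n), function(i) {
      carriers <- sample(samples, sample(1:3, 1))
      k <- length(carriers)
      tibble(variant_id = v$variant_id[i], sample = carriers,
             gt = sample(1:2, k, replace = TRUE, prob = c(0.9, 0.1)),
             dp = rpois(k, 28), gq = sample(0:99, k, replace = TRUE),
             ab = round(runif(k, 0.05, 0.95), 3))
    })

    truth <- sim_variant_truth(v, gt)
    list(variants = v, genotypes = gt, truth = truth)
  })
}

# Independent re-application of the cascade thresholds (deliberately plain
# code, no shared helpers with the cascade module).
sim_variant_truth <- function(v, gt) {
  hq <- gt[gt$gt > 0 & gt$dp >= 10 & gt$gq >= 20 & gt$ab >= 0.2, ]
  has_hq <- v$variant_id %in% hq$variant_id

  lof_list <- c("frameshift_variant", "splice_acceptor_variant",
                "splice_donor_variant", "stop_gained")
  mis_list <- c("inframe_deletion", "inframe_insertion", "missense_variant",
                "start_lost", "stop_lost", "protein_altering_variant")
  syn_list <- c("synonymous_variant", "stop_retained_variant",
                "incomplete_terminal_codon_variant")
  bin <- rep("other", nrow(v))
  bin[v$consequence %in% lof_list] <- "lof"
  bin[v$consequence %in% mis_list] <- "missense"
  bin[v$consequence %in% syn_list] <- "synonymous"

  ok <- function(x) !is.na(x) & x
  pass_hchq <- v$filter == "PASS" & has_hq & !v$lcr & !v$segdup &
    v$gnomad_pass_or_missing
  pass_del <- pass_hchq & bin %in% c("lof", "missense") &
    ok(v$exac_af < 0.001) & ok(v$cadd_phred > 20) & ok(v$dann > 0.99)
  pass_cancer <- pass_del & v$cosmic_tier1 & v$cosmic_count >= 2 &
    v$fathmm_cancer
  pass_fert <- pass_del & v$fertility_gene & ok(v$loeuf <= 0.33) &
    v$cgd_inheritance == "AD"
  autosomal <- !v$chrom %in% c("chrX", "chrY")
  pass_dis <- pass_del & autosomal & ok(v$loeuf < 0.33) &
    v$cgd_inheritance == "AD" & ok(v$fathmm_xf > 0.75) &
    ok(v$dann > 0.999) & ok(v$exac_af < 1e-5)

  tibble(variant_id = v$variant_id, bin = bin, pass_hchq = pass_hchq,
         pass_deleterious = pass_del, pass_cancer = pass_cancer,
         pass_fertility = pass_fert, pass_disease = pass_dis)
}

#' Simulate array probe intensities around CNV calls
#'
#' Emulates the microarray signal used for intensity-rank-sum validation:
#' each call receives probes proportional to its length, all samples get
#' standard-normal baseline intensity per probe, and for calls marked true the
#' carriers' intensities are shifted by `effect_size` standard deviations
#' (down for deletions, up for duplications). Probes in false calls remain
#' i.i.d. with non-carriers.
#'
#' @param calls tibble with `call_id`, `chrom`, `start`, `end`, `type`
#'   (`"del"`/`"dup"`) and a `carriers` list-column of sample ids.
#' @param truth tibble with `call_id` and logical `true`.
#' @param samples character vector of all sample ids (carriers and not).
#' @param effect_size carrier shift in SD units (absolute value).
#' @param probe_density probes per base (default one per 20 kb).
#' @param seed integer seed.
#' @return list with `intensities` (wide tibble: `probe_id`, `chrom`, `pos`,
#'   one column per sample) and `probe_map` (`probe_id`, `call_id`).
#' @export
sim_array_intensities <- function(calls, truth, samples, effect_size = 3,
                                  probe_density = 1 / 2e4, seed = 1L) {
  stopifnot_cols(calls, c("call_id", "chrom", "start", "end", "type",
                          "carriers"), "calls")
  stopifnot_cols(truth, c("call_id", "true"), "truth")
  with_seed(seed + 505L, {
    probe_map <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
      np <- max(0L, round((calls$end[i] - calls$start[i]) * probe_density))
      if (np == 0) return(tibble())
      tibble(call_id = calls$call_id[i], chrom = calls$chrom[i],
             pos = round(seq(calls$start[i], calls$end[i],
                             length.out = np + 2)[2:(np + 1)]))
    })
    np <- nrow(probe_map)
    probe_map$probe_id <- sprintf("probe%05d", seq_len(np))
    m <- matrix(rnorm(np * length(samples)), nrow = np,
                dimnames = list(NULL, samples))
    for (i in seq_len(np)) {
      ci <- match(probe_map$call_id[i], calls$call_id)
      if (!isTRUE(truth$true[match(calls$call_id[ci], truth$call_id)])) next
      carriers <- calls$carriers[[ci]]
      shift <- if (calls$type[ci] == "del") -abs(effect_size) else
        abs(effect_size)
      m[i, carriers] <- m[i, carriers] + shift
    }
    intensities <- bind_cols(
      probe_map[, c("probe_id", "chrom", "pos")], as_tibble(m))
    list(intensities = intensities,
         probe_map = probe_map[, c("probe_id", "call_id")])
  })
}
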