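lof_consequences <- c("frameshift_variant", "splice_acceptor_variant",
                      "splice_donor_variant", "stop_gained")
missense_consequences <- c("inframe_deletion", "inframe_insertion",
                           "missense_variant", "start_lost", "stop_lost",
                           "protein_altering_variant")
synonymous_consequences <- c("synonymous_variant", "stop_retained_variant",
                             "incomplete_terminal_codon_variant")

# NA-safe strict/inclusive comparisons: missing annotations fail filters
gt_na <- function(x, thr) !is.na(x) & x > thr
lt_na <- function(x, thr) !is.na(x) & x < thr
le_na <- function(x, thr) !is.na(x) & x <= thr

#' High-confidence / high-quality variant filter
#'
#' First cascade stage. Keeps a variant only when all of: the site-level
#' filter tag is `PASS`; at least one carrier genotype meets depth >= 10,
#' genotype quality >= 20 and within-sample alternate allele fraction >= 0.2;
#' the site is in neither a low-complexity region nor a segmental
#' duplication; and the population-reference filter status is pass-or-missing.
#'
#' @param variants variant annotation tibble (one row per split biallelic
#'   variant) with `variant_id`, `filter`, `lcr`, `segdup`,
#'   `gnomad_pass_or_missing`.
#' @param genotypes per-carrier tibble with `variant_id`, `sample`, `gt`,
#'   `dp`, `gq`, `ab`.
#' @param min_dp,min_gq,min_ab genotype-quality thresholds.
#' @return the surviving rows of `variants`.
#' @export
hc_hq_filter <- function(variants, genotypes, min_dp = 10, min_gq = 20,
                         min_ab = 0.2) {
  stopifnot_cols(variants, c("variant_id", "filter", "lcr", "segdup",
                             "gnomad_pass_or_missing"), "variants")
  stopifnot_cols(genotypes, c("variant_id", "gt", "dp", "gq", "ab"),
                 "genotypes")
  hq_ids <- genotypes |>
    filter(.data$gt > 0, .data$dp >= min_dp, .data$gq >= min_gq,
           .data$ab >= min_ab) |>
    pull(.data$variant_id)
  variants |>
    filter(.data$filter == "PASS",
           .data$variant_id %in% hq_ids,
           !.data$lcr, !.data$segdup,
           .data$gnomad_pass_or_missing)
}

#' Bin a consequence string into LoF / missense / synonymous / other
#'
#' Exact membership in the canonical-transcript consequence lists; anything
#' else (including an empty string, with a warning) is `other`.
#'
#' @param consequence character vector of consequence terms.
#' @return character vector in `{"lof", "missense", "synonymous", "other"}`.
#' @export
bin_consequence <- function(consequence) {
  if (any(is.na(consequence) | consequence == ""))
    warning("empty consequence string(s) binned as 'other'")
  out <- rep("other", length(consequence))
  out[consequence %in% lof_consequences] <- "lof"
  out[consequence %in% missense_consequences] <- "missense"
  out[consequence %in% synonymous_consequences] <- "synonymous"
  out
}

#' Deleterious-variant filter
#'
#' Keeps LoF and missense variants that are rare (ExAC allele frequency
#' strictly below `af_max`) and predicted deleterious by both CADD
#' (phred strictly above `cadd_min`, the top-1% band of the phred scale) and
#' DANN (strictly above `dann_min`). Missing annotations fail.
#'
#' @param variants surviving variants from [hc_hq_filter()] with `consequence`,
#'   `exac_af`, `cadd_phred`, `dann`.
#' @param af_max,cadd_min,dann_min thresholds.
#' @return the surviving rows, with a `bin` column added.
#' @export
deleterious_filter <- function(variants, af_max = 0.001, cadd_min = 20,
                               dann_min = 0.99) {
  variants |>
    mutate(bin = bin_consequence(.data$consequence)) |>
    filter(.data$bin %in% c("lof", "missense"),
           lt_na(.data$exac_af, af_max),
           gt_na(.data$cadd_phred, cadd_min),
           gt_na(.data$dann, dann_min))
}

#' Cancer-associated shortlist
#'
#' From deleterious survivors, keeps variants in genes with documented Tier 1
#' cancer activity, observed in human cancers at least `min_count` times, and
#' predicted cancer-causing by the hidden-Markov-model classifier.
#'
#' @param variants deleterious survivors with `cosmic_tier1`, `cosmic_count`,
#'   `fathmm_cancer`.
#' @param min_count minimum catalog observation count.
#' @return surviving rows.
#' @export
cancer_filter <- function(variants, min_count = 2) {
  variants |>
    filter(.data$cosmic_tier1,
           .data$cosmic_count >= min_count,
           .data$fathmm_cancer)
}

#' Fertility-associated shortlist
#'
#' From deleterious survivors, keeps variants in literature fertility genes
#' that are loss-of-function intolerant (LOEUF at or below `loeuf_max`,
#' inclusive) and associated with autosomal dominant disease in the curated
#' clinical genomic database.
#'
#' @param variants deleterious survivors with `fertility_gene`, `loeuf`,
#'   `cgd_inheritance`.
#' @param loeuf_max inclusive LOEUF cutoff.
#' @return surviving rows.
#' @export
fertility_filter <- function(variants, loeuf_max = 0.33) {
  variants |>
    filter(.data$fertility_gene,
           le_na(.data$loeuf, loeuf_max),
           .data$cgd_inheritance == "AD")
}

#' Disease-associated shortlist
#'
#' From deleterious survivors, keeps autosomal variants in constrained genes
#' (LOEUF strictly below `loeuf_max`) associated with autosomal dominant
#' disease, predicted pathogenic by FATHMM-XF (strictly above `fathmm_min`)
#' and DANN (strictly above `dann_min`), and ultra-rare in ExAC (strictly
#' below `af_max`). Note the LOEUF edge differs from the fertility filter
#' (strict here, inclusive there), following the two filters' definitions.
#'
#' @param variants deleterious survivors with `chrom`, `loeuf`,
#'   `cgd_inheritance`, `fathmm_xf`, `dann`, `exac_af`.
#' @param loeuf_max,fathmm_min,dann_min,af_max thresholds.
#' @param autosomes chromosome names counted as autosomal.
#' @return surviving rows.
#' @export
disease_filter <- function(variants, loeuf_max = 0.33, fathmm_min = 0.75,
                           dann_min = 0.999, af_max = 1e-5,
                           autosomes = paste0("chr", 1:22)) {
  variants |>
    filter(.data$chrom %in% autosomes,
           lt_na(.data$loeuf, loeuf_max),
           .data$cgd_inheritance == "AD",
           gt_na(.data$fathmm_xf, fathmm_min),
           gt_na(.data$dann, dann_min),
           lt_na(.data$exac_af, af_max))
}

#' Run the full SNV prioritization cascade
#'
#' Chains [hc_hq_filter()], [deleterious_filter()] and the three shortlist
#' filters, and returns per-variant stage flags plus the shortlists. Each
#' stage's survivor set is a subset of the previous stage's.
#'
#' @param variants variant annotation tibble.
#' @param genotypes per-carrier genotype tibble.
#' @return list with `flags` (per variant: `bin`, `pass_hchq`,
#'   `pass_deleterious`, `pass_cancer`, `pass_fertility`, `pass_disease`) and
#'   `shortlists` (named list of surviving variant tibbles).
#' @export
run_snv_cascade <- function(variants, genotypes) {
  hchq <- hc_hq_filter(variants, genotypes)
  dele <- deleterious_filter(hchq)
  canc <- cancer_filter(dele)
  fert <- fertility_filter(dele)
  dise <- disease_filter(dele)
  flags <- variants |>
    transmute(variant_id = .data$variant_id,
              bin = suppressWarnings(bin_consequence(.data$consequence)),
              pass_hchq = .data$variant_id %in% hchq$variant_id,
              pass_deleterious = .data$variant_id %in% dele$variant_id,
              pass_cancer = .data$variant_id %in% canc$variant_id,
              pass_fertility = .data$variant_id %in% fert$variant_id,
              pass_disease = .data$variant_id %in% dise$variant_id)
  list(flags = flags,
       shortlists = list(hc_hq = hchq, deleterious = dele, cancer = canc,
                         fertility = fert, disease = dise))
}

#' Per-sample variant burden by consequence bin and shortlist
#'
#' Counts, for every sample, its carried variants per consequence bin and per
#' cascade shortlist, with cohort means and SDs.
#'
#' @param flags per-variant flag tibble from [run_snv_cascade()].
#' @param genotypes per-carrier genotype tibble (`variant_id`, `sample`,
#'   `gt`).
#' @param samples sample ids to report; default those seen in `genotypes`.
#' @return list with `per_sample` (one row per sample) and `cohort`
#'   (mean/sd per count column).
#' @export
burden_summary <- function(flags, genotypes, samples = NULL) {
  samples <- samples %||% sort(unique(genotypes$sample))
  carried <- genotypes |>
    filter(.data$gt > 0) |>
    inner_join(flags, by = "variant_id")
  per_sample <- tibble(sample = samples) |>
    left_join(
      carried |>
        group_by(.data$sample) |>
        summarise(n_lof = sum(.data$bin == "lof"),
                  n_missense = sum(.data$bin == "missense"),
                  n_synonymous = sum(.data$bin == "synonymous"),
                  n_deleterious = sum(.data$pass_deleterious),
                  n_cancer = sum(.data$pass_cancer),
                  n_fertility = sum(.data$pass_fertility),
                  n_disease = sum(.data$pass_disease),
                  .groups = "drop"),
      by = "sample") |>
    mutate(across(starts_with("n_"), ~ tidyr::replace_na(.x, 0L)))
  cohort <- per_sample |>
    summarise(across(starts_with("n_"),
                     list(mean = mean, sd = sd))) |>
    tidyr::pivot_longer(everything(), names_to = c("class", "stat"),
                        names_pattern = "n_(.*)_(mean|sd)") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  list(per_sample = per_sample, cohort = cohort)
}

#' Fraction of the deleteriousness scale above a phred-scaled cutoff
#'
#' On a phred-like scale, a cutoff `s` marks the top `10^(-s/10)` fraction of
#' ranked variants; the deleterious filter's CADD cutoff of 20 therefore
#' selects the top 1%.
#'
#' @param phred phred-scaled score cutoff.
#' @return top fraction of the ranked scale.
#' @export
#' @examples
#' phred_top_fraction(20) # 0.01
phred_top_fraction <- function(phred) 10^(-phred / 10)
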