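#' Aggregate module outputs into per-line reports
#'
#' Builds one summary row per line from the upstream module outputs: counts
#' of large fixed and mosaic structural variants, accepted CN-LOH events,
#' SNV shortlist hits, outlier polygenic-score traits, ancestry fractions and
#' sibling ids. A module passed as `NULL` leaves its fields `NA` (never a
#' silent zero). Every count is a pure recount of the corresponding upstream
#' table. Line ids present in a module output but absent from `lines` raise
#' an error naming the orphans.
#'
#' @param lines character vector of line ids to report.
#' @param large_calls classified large-CNV calls (from [scan_large_cnvs()]).
#' @param baf_segments accepted/classified imbalance segments (from
#'   [cnloh_accept()]), or NULL.
#' @param snv_flags per-variant cascade flags (from [run_snv_cascade()]).
#' @param snv_genotypes per-carrier genotype tibble for the flags.
#' @param prs_profiles PRS profile tibble (from [adjust_and_normalize()]).
#' @param relationships classified pair tibble (from
#'   [classify_relationship()]).
#' @param ancestry ancestry tibble (from [pca_ancestry()]).
#' @param aneuploid_frac a large call covering at least this fraction of a
#'   chromosome's length flags the line aneuploid.
#' @param chrom_lengths named vector of chromosome lengths (bases), required
#'   for the aneuploidy flag when `large_calls` is given.
#' @param recurrent_dup_lines line ids carrying a recurrent-duplication
#'   cluster (from [recurrent_cnv_screen()] membership), or NULL.
#' @return tibble with one row per line.
#' @export
build_report <- function(lines,
                         large_calls = NULL,
                         baf_segments = NULL,
                         snv_flags = NULL, snv_genotypes = NULL,
                         prs_profiles = NULL,
                         relationships = NULL,
                         ancestry = NULL,
                         aneuploid_frac = 0.8,
                         chrom_lengths = NULL,
                         recurrent_dup_lines = NULL) {
  check_orphans <- function(ids, what) {
    orphans <- setdiff(ids, lines)
    if (length(orphans) > 0)
      stop(what, " contains line id(s) not in `lines`: ",
           paste(orphans, collapse = ", "), call. = FALSE)
  }
  rep <- tibble(line = lines)

  if (!is.null(large_calls)) {
    check_orphans(large_calls$sample, "large_calls")
    an <- rep(FALSE, nrow(large_calls))
    if (!is.null(chrom_lengths) && nrow(large_calls) > 0)
      an <- (large_calls$end - large_calls$start) >=
        aneuploid_frac * chrom_lengths[large_calls$chrom]
    sv <- large_calls |>
      mutate(.an = an) |>
      group_by(line = .data$sample) |>
      summarise(n_large_fixed = sum(.data$status == "fixed"),
                n_large_mosaic = sum(.data$status == "mosaic"),
                aneuploid = any(.data$.an), .groups = "drop")
    rep <- left_join(rep, sv, by = "line") |>
      mutate(across(c("n_large_fixed", "n_large_mosaic"),
                    ~ tidyr::replace_na(.x, 0L)),
             aneuploid = tidyr::replace_na(.data$aneuploid, FALSE))
  } else {
    rep$n_large_fixed <- NA_integer_; rep$n_large_mosaic <- NA_integer_
    rep$aneuploid <- NA
  }

  if (!is.null(baf_segments)) {
    check_orphans(baf_segments$sample, "baf_segments")
    cn <- baf_segments |>
      filter(.data$accepted) |>
      count(line = .data$sample, name = "n_cnloh")
    rep <- left_join(rep, cn, by = "line") |>
      mutate(n_cnloh = tidyr::replace_na(.data$n_cnloh, 0L))
  } else rep$n_cnloh <- NA_integer_

  if (!is.null(snv_flags) && !is.null(snv_genotypes)) {
    check_orphans(snv_genotypes$sample, "snv_genotypes")
    counts <- snv_genotypes |>
      filter(.data$gt > 0) |>
      inner_join(snv_flags, by = "variant_id") |>
      group_by(line = .data$sample) |>
      summarise(n_cancer_snv = sum(.data$pass_cancer),
                n_fertility_snv = sum(.data$pass_fertility),
                n_disease_snv = sum(.data$pass_disease), .groups = "drop")
    rep <- left_join(rep, counts, by = "line") |>
      mutate(across(c("n_cancer_snv", "n_fertility_snv", "n_disease_snv"),
                    ~ tidyr::replace_na(.x, 0L)))
  } else {
    rep$n_cancer_snv <- NA_integer_; rep$n_fertility_snv <- NA_integer_
    rep$n_disease_snv <- NA_integer_
  }

  if (!is.null(prs_profiles)) {
    check_orphans(prs_profiles$sample, "prs_profiles")
    pr <- prs_profiles |>
      group_by(line = .data$sample) |>
      summarise(n_outlier_prs = sum(.data$outlier), .groups = "drop")
    rep <- left_join(rep, pr, by = "line")
  } else rep$n_outlier_prs <- NA_integer_

  if (!is.null(relationships)) {
    check_orphans(c(relationships$id1, relationships$id2), "relationships")
    sibs <- vapply(lines, function(l) {
      s <- c(relationships$id2[relationships$id1 == l &
                                 relationships$relationship ==
                                 "full_siblings"],
             relationships$id1[relationships$id2 == l &
                                 relationships$relationship ==
                                 "full_siblings"])
      paste(sort(unique(s)), collapse = ",")
    }, character(1))
    rep$siblings <- sibs
  } else rep$siblings <- NA_character_

  if (!is.null(ancestry)) {
    qry <- if ("is_reference" %in% names(ancestry))
      ancestry$sample[!ancestry$is_reference] else ancestry$sample
    check_orphans(qry, "ancestry")
    frac_cols <- setdiff(names(ancestry),
                         c("sample", "is_reference",
                           grep("^PC", names(ancestry), value = TRUE)))
    rep <- left_join(rep,
                     ancestry |>
                       select("sample", all_of(frac_cols)) |>
                       rename(line = "sample"),
                     by = "line")
  }

  rep$recurrent_dup <- if (is.null(recurrent_dup_lines)) NA else
    rep$line %in% recurrent_dup_lines
  rep
}

#' Default line-selection policy
#'
#' Severity per computable criterion, mirroring a tiered selection workflow:
#' aneuploidy or any large fixed structural variant is disqualifying; large
#' mosaic variants warrant caution (such lines can in principle be rescued by
#' sub-cloning); cancer- or disease-shortlist SNVs are disqualifying;
#' fertility-shortlist SNVs and many outlier polygenic scores warrant
#' caution.
#'
#' @param prs_outlier_max outlier-trait count above which to flag caution.
#' @return named list policy.
#' @export
selection_policy <- function(prs_outlier_max = 3) {
  list(
    aneuploid = "avoid",
    large_fixed_sv = "avoid",
    large_mosaic_sv = "caution",
    cnloh = "caution",
    cancer_snv = "avoid",
    disease_snv = "avoid",
    fertility_snv = "caution",
    prs_outliers = "caution",
    prs_outlier_max = prs_outlier_max
  )
}

#' Apply the tiered selection policy to line reports
#'
#' Evaluates each enabled criterion per line at the severity the policy
#' assigns (`"avoid"` > `"caution"` > `"pass"`); the overall recommendation
#' is the worst tier reached, and every non-pass carries a reason. `NA`
#' report fields (modules not run) contribute nothing.
#'
#' @param reports tibble from [build_report()].
#' @param policy list from [selection_policy()]; unknown criterion names
#'   raise an error.
#' @return tibble `line`, `overall`, `reasons` (list-column).
#' @export
select_lines <- function(reports, policy = selection_policy()) {
  known <- names(selection_policy())
  unknown <- setdiff(names(policy), known)
  if (length(unknown) > 0)
    stop("unknown criterion in policy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tier_rank <- c(pass = 0, caution = 1, avoid = 2)
  purrr::map_dfr(seq_len(nrow(reports)), function(i) {
    r <- reports[i, ]
    findings <- list()
    hit <- function(cond, key, reason) {
      if (isTRUE(cond) && !is.null(policy[[key]]))
        findings[[length(findings) + 1]] <<-
          list(tier = policy[[key]], reason = reason)
    }
    hit(r$aneuploid, "aneuploid", "aneuploidy")
    hit(r$n_large_fixed > 0, "large_fixed_sv",
        sprintf("%d large fixed structural variant(s)", r$n_large_fixed))
    hit(r$n_large_mosaic > 0, "large_mosaic_sv",
        sprintf("%d large mosaic structural variant(s); sub-cloning may rescue",
                r$n_large_mosaic))
    hit(r$n_cnloh > 0, "cnloh",
        sprintf("%d acquired CN-LOH event(s)", r$n_cnloh))
    hit(r$n_cancer_snv > 0, "cancer_snv",
        sprintf("%d cancer-shortlist SNV(s)", r$n_cancer_snv))
    hit(r$n_disease_snv > 0, "disease_snv",
        sprintf("%d disease-shortlist SNV(s)", r$n_disease_snv))
    hit(r$n_fertility_snv > 0, "fertility_snv",
        sprintf("%d fertility-shortlist SNV(s)", r$n_fertility_snv))
    hit(r$n_outlier_prs > policy$prs_outlier_max, "prs_outliers",
        sprintf("%d outlier polygenic-score trait(s)", r$n_outlier_prs))
    tiers <- vapply(findings, `[[`, character(1), "tier")
    overall <- if (length(tiers) == 0) "pass" else
      names(tier_rank)[max(tier_rank[tiers]) + 1]
    tibble(line = r$line, overall = overall,
           reasons = list(vapply(findings, `[[`, character(1), "reason")))
  })
}

#' Run the whole pipeline on synthetic inputs
#'
#' Drives the modules end to end from a single configuration: simulate
#' coverage, phased counts, pedigree genotypes and an annotated variant
#' table; scan for large CNVs and classify mosaicism; segment and classify
#' allelic imbalance; estimate relatedness; run the SNV cascade; and
#' assemble per-line reports and selection verdicts. Returns all intermediate
#' tables plus a manifest recording the seed and thresholds used.
#'
#' @param cfg a [sim_config()].
#' @return list of module outputs, `report`, `verdicts`, and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lines <- sim_sample_ids(cfg$n_samples)
  cov <- sim_coverage(cfg)
  calls <- scan_large_cnvs(cov$coverage)
  ph <- sim_phased_counts(cfg)
  segs <- purrr::map_dfr(lines, function(s)
    segment_imbalance(ph$counts, s))
  if (nrow(segs) > 0) {
    segs <- classify_segment(segs, cov$coverage)
    ends <- tibble(chrom = names(cfg$n_bins),
                   length = as.numeric(cfg$n_bins) * cfg$bin_size)
    segs <- cnloh_accept(segs, ends)
  } else segs <- NULL
  vt <- sim_variant_table(cfg)
  casc <- run_snv_cascade(vt$variants, vt$genotypes)
  ped <- sim_pedigree_genotypes(
    sim_config(seed = cfg$seed, n_samples = cfg$n_samples,
               n_snps = cfg$n_snps, maf_floor = cfg$maf_floor))
  rel <- estimate_ibd(ped$genotypes) |> classify_relationship()
  report <- build_report(
    lines, large_calls = calls, baf_segments = segs,
    snv_flags = casc$flags, snv_genotypes = vt$genotypes,
    relationships = rel,
    chrom_lengths = setNames(as.numeric(cfg$n_bins) * cfg$bin_size,
                             names(cfg$n_bins)))
  verdicts <- select_lines(report)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pluriscan")),
    seed = cfg$seed, n_samples = cfg$n_samples,
    thresholds = list(z_seed = 3, z_report = 5, min_bins = 10,
                      p_mosaic = 1e-3, lod_min = 20, min_length = 1e6),
    timestamp_free = TRUE
  )
  list(coverage = cov, large_calls = calls, baf_segments = segs,
       variants = vt, cascade = casc, relatedness = rel,
       report = report, verdicts = verdicts, manifest = manifest)
}
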