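#' Simulate phased allele depths at heterozygous sites
#'
#' Places `cfg$n_het_sites` heterozygous sites uniformly over each configured
#' chromosome and draws phased read depths per sample. Outside events the
#' expected phased B-allele frequency (fraction of reads from haplotype 1) is
#' 0.5. Inside an implanted event of cell fraction `f` the imbalance always
#' favors haplotype 1:
#' * `cnloh`: haplotype 1 retained, expected BAF `(1 + f) / 2`;
#' * `dup`: haplotype 1 duplicated, expected BAF `(1 + f) / (2 + f)` with
#'   total depth scaled by `(2 + f) / 2`;
#' * `del`: haplotype 2 lost, expected BAF `1 / (2 - f)` with depth scaled by
#'   `(2 - f) / 2`.
#'
#' Phasing is emitted perfect (no switch errors).
#'
#' @param cfg a [sim_config()].
#' @param events optional event tibble; defaults to `cfg$events`.
#' @return list with `counts` — tibble of `chrom`, `pos`, `sample`,
#'   `hap1_depth`, `hap2_depth`, `phase_set` — and `truth`.
#' @export
sim_phased_counts <- function(cfg, events = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ev <- events %||% cfg$events
  samples <- sim_sample_ids(cfg$n_samples)

  with_seed(cfg$seed + 101L, {
    sites <- purrr::map_dfr(names(cfg$n_bins), function(ch) {
      len <- cfg$n_bins[[ch]] * cfg$bin_size
      tibble(chrom = ch,
             pos = sort(sample.int(len, cfg$n_het_sites, replace = FALSE)))
    })
    long <- tidyr::expand_grid(sites, sample = samples)
    # per-site expected BAF and depth scaling
    long$p <- 0.5
    long$dscale <- 1
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        f <- ev$cell_fraction[i]
        inside <- long$sample == ev$sample[i] & long$chrom == ev$chrom[i] &
          long$pos > ev$start_bin[i] * cfg$bin_size &
          long$pos <= ev$end_bin[i] * cfg$bin_size
        if (ev$kind[i] == "cnloh") {
          long$p[inside] <- (1 + f) / 2
        } else if (ev$kind[i] == "dup") {
          long$p[inside] <- (1 + f) / (2 + f)
          long$dscale[inside] <- (2 + f) / 2
        } else {
          long$p[inside] <- 1 / (2 - f)
          long$dscale[inside] <- (2 - f) / 2
        }
      }
    }
    n <- nrow(long)
    depth <- draw_counts(n, cfg$mean_depth * long$dscale, cfg)
    hap1 <- rbinom(n, depth, long$p)
    counts <- tibble(chrom = long$chrom, pos = long$pos, sample = long$sample,
                     hap1_depth = hap1, hap2_depth = depth - hap1,
                     phase_set = paste0(long$chrom, ":ps1")) |>
      arrange(.data$sample, .data$chrom, .data$pos)
    list(counts = counts, truth = ev)
  })
}
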