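#' Simulate a binned, normalized depth-of-coverage matrix
#'
#' Draws per-bin read counts for every sample under the configured noise model
#' (Poisson by default), implants the configured copy-number events, and
#' normalizes counts first by sample mean and then by across-sample bin median
#' so that the result is on a copy-number scale where diploid = 2. A bin inside
#' an event of integer copy number `c` at cell fraction `f` has expected
#' normalized copy number `2 + f * (c - 2)`; `cnloh` events do not alter
#' coverage.
#'
#' @param cfg a [sim_config()].
#' @return list with `coverage` — wide tibble with `chrom`, `start`, `end` and
#'   one numeric column per sample — and `truth`, the event tibble actually
#'   implanted.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_samples = 6, n_bins = 200)
#' cov <- sim_coverage(cfg)
#' head(cov$coverage)
sim_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bins <- bin_table(cfg)
  nb <- nrow(bins)
  samples <- sim_sample_ids(cfg$n_samples)
  lambda <- bin_lambda(cfg)

  # expected copy number per bin per sample (truth surface)
  cn_exp <- matrix(2, nrow = nb, ncol = cfg$n_samples,
                   dimnames = list(NULL, samples))
  ev <- cfg$events
  if (nrow(ev) > 0) {
    if (!all(ev$chrom %in% names(cfg$n_bins)))
      stop("event chromosome not present in configuration", call. = FALSE)
    if (!all(ev$sample %in% samples))
      stop("event sample id not present in configuration", call. = FALSE)
    offset <- c(0, cumsum(cfg$n_bins))[match(ev$chrom, names(cfg$n_bins))]
    for (i in seq_len(nrow(ev))) {
      if (ev$end_bin[i] > cfg$n_bins[[ev$chrom[i]]])
        stop("event extends past its chromosome", call. = FALSE)
      rows <- (offset[i] + ev$start_bin[i] + 1):(offset[i] + ev$end_bin[i])
      cn_exp[rows, ev$sample[i]] <- 2 +
        ev$cell_fraction[i] * (ev$integer_cn[i] - 2)
    }
  }

  counts <- with_seed(cfg$seed, {
    matrix(draw_counts(nb * cfg$n_samples, lambda * as.vector(cn_exp) / 2, cfg),
           nrow = nb, ncol = cfg$n_samples, dimnames = list(NULL, samples))
  })

  cn <- normalize_coverage(counts)
  out <- bind_cols(bins, as_tibble(cn))
  list(coverage = out, truth = ev)
}

# counts (bins x samples) -> normalized copy-number matrix:
# divide by the sample's median bin count (robust to implanted events),
# then by the across-sample bin median, times 2.
normalize_coverage <- function(counts) {
  x <- sweep(counts, 2, matrixStats::colMedians(counts), "/")
  m <- row_median(x)
  m[m <= 0] <- NA_real_
  cn <- 2 * x / m
  cn[is.na(cn)] <- 0
  cn
}
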