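#' Segment phased allelic imbalance for one sample
#'
#' Works on phased heterozygous-site allele depths. The phased B-allele
#' frequency `b = hap1 / (hap1 + hap2)` is 0.5 in expectation in balanced
#' regions and deviates by `d` inside events. Sites are segmented per
#' chromosome by recursive binary splitting on the depth-weighted deviation
#' (split accepted when the two-sample normal statistic exceeds
#' `split_z`, roughly a Bonferroni bound over the split positions scanned).
#' Each segment is scored with a binomial log10 likelihood ratio against
#' balance: `lod = sum log10 [ Bin(k; n, 0.5 + d_hat) / Bin(k; n, 0.5) ]`,
#' with the alternative oriented toward the segment's deviated haplotype.
#' Segments with `lod > lod_min` and span greater than `min_length` bases are
#' returned.
#'
#' @param counts phased counts tibble (`chrom`, `pos`, `sample`,
#'   `hap1_depth`, `hap2_depth`).
#' @param sample sample id; default the only sample present.
#' @param lod_min LOD threshold for reporting (default 20).
#' @param min_length minimum segment span in bases (default 1 Mbp).
#' @param split_z splitting threshold for the binary segmentation.
#' @return tibble of segments: `sample`, `chrom`, `start`, `end`, `n_sites`,
#'   `d` (absolute mean phased BAF deviation), `baf` (signed mean), `lod`.
#' @export
segment_imbalance <- function(counts, sample = NULL, lod_min = 20,
                              min_length = 1e6, split_z = 4) {
  stopifnot_cols(counts, c("chrom", "pos", "sample", "hap1_depth",
                           "hap2_depth"), "counts")
  sample <- sample %||% unique(counts$sample)
  stopifnot(length(sample) == 1)
  x <- counts |>
    filter(.data$sample == !!sample,
           .data$hap1_depth + .data$hap2_depth > 0) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(x) == 0) return(empty_segments())

  purrr::map_dfr(unique(x$chrom), function(ch) {
    xi <- x[x$chrom == ch, ]
    k <- xi$hap1_depth; n <- xi$hap1_depth + xi$hap2_depth
    b <- k / n
    bounds <- binary_segment(b, n, split_z)
    purrr::map_dfr(seq_len(nrow(bounds)), function(j) {
      idx <- bounds$from[j]:bounds$to[j]
      baf <- sum(k[idx]) / sum(n[idx])
      d <- abs(baf - 0.5)
      p1 <- clip01(if (baf >= 0.5) 0.5 + d else 0.5 - d, 1e-9, 1 - 1e-9)
      lod <- sum(dbinom(k[idx], n[idx], p1, log = TRUE) -
                   dbinom(k[idx], n[idx], 0.5, log = TRUE)) / log(10)
      tibble(sample = sample, chrom = ch,
             start = xi$pos[bounds$from[j]], end = xi$pos[bounds$to[j]],
             n_sites = length(idx), d = d, baf = baf, lod = lod)
    })
  }) |>
    filter(.data$lod > lod_min, .data$end - .data$start > min_length) |>
    arrange(.data$chrom, .data$start)
}

empty_segments <- function() {
  tibble(sample = character(), chrom = character(), start = numeric(),
         end = numeric(), n_sites = integer(), d = numeric(),
         baf = numeric(), lod = numeric())
}

# recursive binary segmentation of per-site BAF with depth weights;
# returns tibble(from, to) of segment index bounds
binary_segment <- function(b, n, split_z, min_seg = 10) {
  m <- length(b)
  segs <- list(c(1L, m))
  out <- list()
  while (length(segs) > 0) {
    seg <- segs[[1]]; segs <- segs[-1]
    a <- seg[1]; z <- seg[2]
    len <- z - a + 1
    if (len < 2 * min_seg) { out <- c(out, list(seg)); next }
    bi <- b[a:z]; ni <- n[a:z]
    cw <- cumsum(bi * ni); cn <- cumsum(ni)
    tw <- cw[len]; tn <- cn[len]
    ts <- min_seg:(len - min_seg)
    mu1 <- cw[ts] / cn[ts]
    mu2 <- (tw - cw[ts]) / (tn - cn[ts])
    # binomial-scale variance of the weighted means at p ~ 0.5
    v <- 0.25 / cn[ts] + 0.25 / (tn - cn[ts])
    stat <- abs(mu1 - mu2) / sqrt(v)
    best <- which.max(stat)
    if (stat[best] > split_z) {
      cut <- a + ts[best] - 1L
      segs <- c(segs, list(c(a, cut)), list(c(cut + 1L, z)))
    } else out <- c(out, list(seg))
  }
  bounds <- do.call(rbind, out)
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  tibble(from = bounds[, 1], to = bounds[, 2])
}

#' Classify an imbalance segment using depth of coverage
#'
#' Combines the phased BAF deviation `d` of each segment with the sample's
#' normalized copy number over the segment. Coverage significantly above 2
#' gives a duplication, significantly below a deletion, otherwise a
#' copy-neutral LOH. Mosaic fractions come from the single-copy-step mixture
#' identities: `f = 4d / (1 - 2d)` (dup), `f = 4d / (1 + 2d)` (del),
#' `f = 2d` (CN-LOH). When the BAF-implied and coverage-implied fractions
#' disagree by more than `consistency_tol`, the segment is `ambiguous`.
#' CN-LOH fractions below 0.1 are flagged `low_fraction`.
#'
#' @param segments output of [segment_imbalance()].
#' @param coverage wide coverage tibble covering the segments.
#' @param alpha significance level for the coverage <>2 test.
#' @param consistency_tol allowed |f_baf - f_cn| before calling `ambiguous`.
#' @return `segments` with `class`, `mosaic_fraction`, `mean_cn`,
#'   `low_fraction` columns.
#' @export
classify_segment <- function(segments, coverage, alpha = 1e-3,
                             consistency_tol = 0.2) {
  cm <- as_cov_matrix(coverage)
  res <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    rows <- which(cm$meta$chrom == seg$chrom &
                    cm$meta$end > seg$start & cm$meta$start < seg$end)
    x <- cm$m[rows, seg$sample]
    chat <- mean(x)
    se <- sd(x) / sqrt(length(x))
    zcn <- if (is.finite(se) && se > 0) (chat - 2) / se else 0
    d <- seg$d
    if (2 * pnorm(-abs(zcn)) < alpha && zcn > 0) {
      cls <- "dup"; f <- 4 * d / (1 - 2 * d); f_cn <- chat - 2
    } else if (2 * pnorm(-abs(zcn)) < alpha && zcn < 0) {
      cls <- "del"; f <- 4 * d / (1 + 2 * d); f_cn <- 2 - chat
    } else {
      cls <- "cnloh"; f <- 2 * d; f_cn <- NA_real_
    }
    if (!is.finite(f) || f < 0 ||
        (cls != "cnloh" && abs(f - f_cn) > consistency_tol) ||
        (cls == "cnloh" && d > 0.5 + 1e-9)) {
      cls <- "ambiguous"; f <- NA_real_
    }
    tibble(class = cls,
           mosaic_fraction = if (is.na(f)) NA_real_ else min(f, 1),
           mean_cn = chat,
           low_fraction = !is.na(f) && f < 0.1)
  })
  bind_cols(segments, res)
}

#' Acceptance rule for copy-neutral LOH segments
#'
#' An imbalance segment classified CN-LOH is accepted as a culture-acquired
#' event only when it is mosaic (cell fraction strictly below 1, excluding
#' fixed runs of homozygosity from inbreeding) and it extends to a chromosome
#' terminus within one bin width — the geometry expected of a single mitotic
#' crossover.
#'
#' @param segments classified segments (from [classify_segment()]).
#' @param chrom_ends tibble with `chrom` and `length` (bases).
#' @param bin_size tolerance for "extends to the telomere", in bases.
#' @return `segments` with logical `telomeric` and `accepted` columns.
#' @export
cnloh_accept <- function(segments, chrom_ends, bin_size = 1e5) {
  if (missing(chrom_ends) || is.null(chrom_ends))
    stop("chrom_ends table is required", call. = FALSE)
  stopifnot_cols(chrom_ends, c("chrom", "length"), "chrom_ends")
  len <- setNames(chrom_ends$length, chrom_ends$chrom)
  segments |>
    mutate(
      telomeric = .data$start <= bin_size |
        .data$end >= len[.data$chrom] - bin_size,
      accepted = .data$class == "cnloh" & .data$telomeric &
        !is.na(.data$mosaic_fraction) & .data$mosaic_fraction < 1
    )
}
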