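#' Interval Z-score for one sample against the cohort
#'
#' For a contiguous range of coverage bins, computes the sample's mean
#' normalized copy number over the interval, the across-sample median and
#' (raw, unscaled) median absolute deviation of those interval means, and the
#' deviation score `Z = |coverage(S, I) - median(I)| / MAD(I)`. A zero MAD is
#' flagged degenerate and `Z` reported as `Inf`, never `NaN`.
#'
#' @param coverage wide coverage tibble (`chrom`, `start`, `end`, one column
#'   per sample), as produced by [sim_coverage()].
#' @param sample sample id (a column of `coverage`).
#' @param chrom chromosome name.
#' @param start_bin,end_bin 1-based inclusive bin indices within the
#'   chromosome.
#' @return one-row tibble with `sample`, `chrom`, `start_bin`, `end_bin`,
#'   `n_bins`, `coverage`, `median`, `mad`, `z`, `degenerate`.
#' @export
#' @examples
#' cov <- sim_coverage(sim_config(seed = 1, n_samples = 6, n_bins = 100))
#' interval_z(cov$coverage, "S001", "chr1", 10, 30)
interval_z <- function(coverage, sample, chrom, start_bin, end_bin) {
  cm <- as_cov_matrix(coverage)
  if (!sample %in% cm$samples) stop("unknown sample: ", sample, call. = FALSE)
  rows <- which(cm$meta$chrom == chrom)
  if (length(rows) < 1) stop("unknown chromosome: ", chrom, call. = FALSE)
  if (start_bin < 1 || end_bin > length(rows) || end_bin < start_bin)
    stop("invalid bin range", call. = FALSE)
  if (ncol(cm$m) < 5)
    stop("interval statistics need at least 5 samples", call. = FALSE)
  means <- colMeans(cm$m[rows[start_bin:end_bin], , drop = FALSE])
  med <- median(means)
  md <- median(abs(means - med))
  degen <- md <= 0
  z <- if (degen) {
    if (means[[sample]] == med) 0 else Inf
  } else abs(means[[sample]] - med) / md
  tibble(sample = sample, chrom = chrom, start_bin = start_bin,
         end_bin = end_bin, n_bins = end_bin - start_bin + 1L,
         coverage = unname(means[[sample]]), median = med, mad = md,
         z = z, degenerate = degen)
}

as_cov_matrix <- function(coverage) {
  stopifnot_cols(coverage, c("chrom", "start", "end"), "coverage")
  split_wide(coverage, c("chrom", "start", "end"))
}

#' Sharp-boundary test for a candidate CNV interval
#'
#' A boundary is sharp when the sample's coverage in the next adjacent bin has
#' moved more than halfway from the sample's in-interval coverage toward the
#' cohort median of that adjacent bin:
#' `|coverage(S, b) - c_in| > 0.5 * |median(b) - c_in|`.
#' Interval ends at a chromosome terminus auto-pass (no adjacent bin).
#'
#' @inheritParams interval_z
#' @return one-row tibble with logical `left_sharp`, `right_sharp`.
#' @export
boundary_is_sharp <- function(coverage, sample, chrom, start_bin, end_bin) {
  cm <- as_cov_matrix(coverage)
  rows <- which(cm$meta$chrom == chrom)
  m <- cm$m[rows, , drop = FALSE]
  c_in <- mean(m[start_bin:end_bin, sample])
  check <- function(adj) {
    if (adj < 1 || adj > nrow(m)) return(TRUE) # chromosome end auto-passes
    cov_b <- m[adj, sample]
    med_b <- median(m[adj, ])
    abs(cov_b - c_in) > 0.5 * abs(med_b - c_in)
  }
  tibble(left_sharp = check(start_bin - 1L), right_sharp = check(end_bin + 1L))
}

#' Scan a coverage matrix for large copy-number variants
#'
#' Per sample and chromosome, candidate intervals are the maximal runs of
#' consecutive bins in which the sample's normalized coverage deviates from
#' the across-sample bin median in a constant direction with single-bin
#' Z-score above `z_extend`, and which contain at least one strong seed bin
#' (single-bin Z above `z_seed`). Survivors must span at least `min_bins`
#' bins, have interval `Z > z_report`, and pass the sharp-boundary test on
#' both ends; reported calls of the same sample and direction separated by
#' at most `merge_gap` bins are merged and their statistics recomputed.
#' Call type is `dup` or `del` by the sign of `coverage - median`.
#'
#' The run-based candidate rule is purely local, which makes the scan linear
#' in the number of bins and makes its output reproducible by a naive search
#' over all contiguous intervals applying the same acceptance rules.
#'
#' @param coverage wide coverage tibble.
#' @param z_seed single-bin Z-score required of at least one bin in a
#'   candidate run.
#' @param z_extend single-bin Z-score required of every bin in a run.
#' @param z_report interval Z-score required to report a call.
#' @param min_bins minimum call length in bins (10 bins = 1 Mbp).
#' @param merge_gap maximum bin gap merged between adjacent calls.
#' @param classify if `TRUE`, run [classify_mosaicism()] on the calls.
#' @param p_mosaic mosaicism P-value threshold (used when `classify = TRUE`).
#' @return tibble of calls: `sample`, `chrom`, `start`, `end` (bases, 0-based
#'   half-open), `start_bin`, `end_bin` (1-based inclusive), `n_bins`, `type`,
#'   `z`, `mean_cn`, and when classified `status`, `p_mosaic`,
#'   `cell_fraction`.
#' @export
scan_large_cnvs <- function(coverage, z_seed = 3, z_extend = 2,
                            z_report = 5, min_bins = 10, merge_gap = 1,
                            classify = TRUE, p_mosaic = 1e-3) {
  cm <- as_cov_matrix(coverage)
  if (nrow(cm$meta) == 0 || length(cm$samples) == 0) return(empty_calls())
  out <- purrr::map_dfr(unique(cm$meta$chrom), function(ch) {
    rows <- which(cm$meta$chrom == ch)
    m <- cm$m[rows, , drop = FALSE]
    meta <- cm$meta[rows, ]
    purrr::map_dfr(cm$samples, function(s) {
      scan_one(m, s, z_seed, z_extend, z_report, min_bins, merge_gap) |>
        mutate(chrom = ch,
               start = meta$start[.data$start_bin],
               end = meta$end[.data$end_bin], .after = "sample")
    })
  })
  if (nrow(out) == 0) return(empty_calls())
  out <- arrange(out, .data$sample, .data$chrom, .data$start_bin)
  if (classify) out <- classify_mosaicism(out, coverage, p_mosaic)
  out
}

empty_calls <- function() {
  tibble(sample = character(), chrom = character(), start = numeric(),
         end = numeric(), start_bin = integer(), end_bin = integer(),
         n_bins = integer(), type = character(), z = numeric(),
         mean_cn = numeric(), status = character(), p_mosaic = numeric(),
         cell_fraction = numeric())
}

# Interval statistics for one sample; `cs` is the column-cumsum of the
# bins x samples matrix with a zero row prepended.
interval_stat <- function(cs, s, a, b) {
  means <- (cs[b + 1, ] - cs[a, ]) / (b - a + 1)
  med <- median(means)
  md <- median(abs(means - med))
  dev <- means[[s]] - med
  z <- if (md <= 0) { if (dev == 0) 0 else Inf } else abs(dev) / md
  list(z = z, mean_cn = unname(means[[s]]), dev = dev)
}

# scan one sample on one chromosome's bins x samples matrix
scan_one <- function(m, s, z_seed, z_extend, z_report, min_bins, merge_gap) {
  nb <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  dev_bin <- m[, s] - row_median(m)
  mad_bin <- row_mad(m)
  zbin <- ifelse(mad_bin > 0, abs(dev_bin) / mad_bin,
                 ifelse(dev_bin == 0, 0, Inf))
  empty <- tibble(sample = character(), start_bin = integer(),
                  end_bin = integer(), n_bins = integer(), z = numeric(),
                  mean_cn = numeric(), type = character())

  # maximal runs of same-sign deviation with single-bin z above z_extend
  state <- ifelse(zbin > z_extend & is.finite(zbin), sign(dev_bin), 0)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(a = starts[r$values != 0], b = ends[r$values != 0])
  if (nrow(runs) == 0) return(empty)
  # candidate runs must contain a strong seed bin
  has_seed <- vapply(seq_len(nrow(runs)), function(i) {
    any(zbin[runs[i, "a"]:runs[i, "b"]] > z_seed)
  }, logical(1))
  runs <- runs[has_seed, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  calls <- intervals_to_calls(cs, s, runs[, "a"], runs[, "b"])
  calls <- calls[calls$n_bins >= min_bins & calls$z > z_report, ,
                 drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  sharp <- vapply(seq_len(nrow(calls)), function(i) {
    a <- calls$start_bin[i]; b <- calls$end_bin[i]
    c_in <- calls$mean_cn[i]
    chk <- function(adj) {
      if (adj < 1 || adj > nb) return(TRUE)
      abs(m[adj, s] - c_in) > 0.5 * abs(median(m[adj, ]) - c_in)
    }
    chk(a - 1) && chk(b + 1)
  }, logical(1))
  calls <- calls[sharp, , drop = FALSE]
  if (nrow(calls) <= 1) return(calls)

  # merge same-direction calls separated by <= merge_gap bins
  calls <- arrange(calls, .data$start_bin)
  merged <- list(); cur <- calls[1, ]
  for (i in seq_len(nrow(calls))[-1]) {
    nxt <- calls[i, ]
    if (nxt$type == cur$type &&
        nxt$start_bin - cur$end_bin - 1 <= merge_gap) {
      cur$end_bin <- nxt$end_bin
    } else {
      merged <- c(merged, list(cur)); cur <- nxt
    }
  }
  merged <- bind_rows(c(merged, list(cur)))
  intervals_to_calls(cs, s, merged$start_bin, merged$end_bin)
}

# vectorized interval -> call-row conversion (one tibble, not one per call)
intervals_to_calls <- function(cs, s, a, b) {
  n <- length(a)
  z <- mean_cn <- dev <- numeric(n)
  for (i in seq_len(n)) {
    st <- interval_stat(cs, s, a[i], b[i])
    z[i] <- st$z; mean_cn[i] <- st$mean_cn; dev[i] <- st$dev
  }
  tibble(sample = s, start_bin = as.integer(a), end_bin = as.integer(b),
         n_bins = as.integer(b - a + 1), z = z, mean_cn = mean_cn,
         type = ifelse(dev >= 0, "dup", "del"))
}

#' Test divergence of mean copy number from the nearest integer
#'
#' Normal-approximation two-sided test of the null hypothesis that the true
#' mean copy number over a set of bins equals an integer copy state, using the
#' empirical between-bin standard error. Used both to classify calls as fixed
#' versus mosaic and, applied genome-wide against the nearest integer, as a
#' null-cohort calibration check.
#'
#' @param x numeric vector of normalized per-bin copy numbers.
#' @param target integer copy state under the null; default the nearest
#'   integer to the observed mean.
#' @return one-row tibble with `chat` (mean CN), `se`, `c_int`, `p`,
#'   `degenerate`.
#' @export
integer_divergence_test <- function(x, target = NULL) {
  chat <- mean(x)
  se <- sd(x) / sqrt(length(x))
  c_int <- target %||% round(chat)
  degen <- !is.finite(se) || se <= 0
  p <- if (degen) 1 else 2 * pnorm(-abs(chat - c_int) / se)
  tibble(chat = chat, se = se, c_int = c_int, p = p, degenerate = degen)
}

#' Classify CNV calls as fixed or mosaic and estimate cell fraction
#'
#' For each call, tests whether the sample's mean copy number over the call
#' interval diverges from the nearest integer copy state consistent with the
#' call type (3 or more for gains, 1 or less for losses), using
#' [integer_divergence_test()]. Calls with `p < p_threshold` are mosaic; the
#' cellular fraction is then `|chat - 2| / |c_int - 2|` under the single-copy-
#' step mixture model, clipped to (0, 1]. Fixed calls carry no cell fraction.
#' Zero within-interval variance is degenerate and classified fixed.
#'
#' @param calls call tibble from [scan_large_cnvs()] (needs `sample`, `chrom`,
#'   `start_bin`, `end_bin`, `type`).
#' @param coverage the coverage tibble the calls came from.
#' @param p_threshold mosaicism P-value threshold.
#' @return `calls` with `status`, `p_mosaic`, `cell_fraction` columns.
#' @export
classify_mosaicism <- function(calls, coverage, p_threshold = 1e-3) {
  cm <- as_cov_matrix(coverage)
  res <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    rows <- which(cm$meta$chrom == calls$chrom[i])
    x <- cm$m[rows[calls$start_bin[i]:calls$end_bin[i]], calls$sample[i]]
    chat <- mean(x)
    c_int <- if (calls$type[i] == "dup") max(3, round(chat))
             else max(0, min(1, round(chat)))
    tst <- integer_divergence_test(x, target = c_int)
    mosaic <- !tst$degenerate && tst$p < p_threshold
    f <- abs(chat - 2) / abs(c_int - 2)
    tibble(status = if (mosaic) "mosaic" else "fixed", p_mosaic = tst$p,
           cell_fraction = if (mosaic) clip01(f, 1e-9, 1) else NA_real_)
  })
  bind_cols(calls[, setdiff(names(calls),
                            c("status", "p_mosaic", "cell_fraction"))], res)
}
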