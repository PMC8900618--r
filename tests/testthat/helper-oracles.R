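# Independent brute-force oracles. These re-implement the acceptance rules
# from scratch (plain loops, no package internals) so that agreement with the
# package is a genuine cross-check.

# Exhaustive large-CNV search: test every contiguous interval against the
# full set of acceptance rules -- every bin deviates in the same direction
# with single-bin z > z_extend, the run is maximal, contains a seed bin
# (z > z_seed), spans >= min_bins bins, has interval Z > z_report and sharp
# boundaries -- then merge <= merge_gap same-type gaps.
oracle_scan <- function(coverage, z_seed = 3, z_extend = 2, z_report = 5,
                        min_bins = 10, merge_gap = 1) {
  meta <- coverage[, c("chrom", "start", "end")]
  m <- as.matrix(coverage[, setdiff(names(coverage), names(meta))])
  stopifnot(length(unique(meta$chrom)) == 1)
  nb <- nrow(m)
  med <- apply(m, 1, median)
  md <- apply(m, 1, function(x) median(abs(x - median(x))))
  out <- list()
  for (s in colnames(m)) {
    dev <- m[, s] - med
    zb <- ifelse(md > 0, abs(dev) / md, ifelse(dev == 0, 0, Inf))
    ok_bin <- zb > z_extend & is.finite(zb)
    rows <- list()
    for (a in 1:nb) {
      for (b in a:nb) {
        bins <- a:b
        if (!all(ok_bin[bins])) break # a longer interval can't qualify
        if (length(unique(sign(dev[bins]))) != 1) break
        # maximality on both sides
        if (a > 1 && ok_bin[a - 1] && sign(dev[a - 1]) == sign(dev[a]))
          next
        if (b < nb && ok_bin[b + 1] && sign(dev[b + 1]) == sign(dev[b]))
          next
        if (!any(zb[bins] > z_seed)) next
        if (b - a + 1 < min_bins) next
        means <- colMeans(m[bins, , drop = FALSE])
        mi <- median(means)
        mdi <- median(abs(means - mi))
        z <- if (mdi > 0) abs(means[[s]] - mi) / mdi else
          if (means[[s]] == mi) 0 else Inf
        if (z <= z_report) next
        c_in <- means[[s]]
        sharp <- TRUE
        for (adj in c(a - 1, b + 1)) {
          if (adj < 1 || adj > nb) next
          if (!(abs(m[adj, s] - c_in) > 0.5 * abs(median(m[adj, ]) - c_in)))
            sharp <- FALSE
        }
        if (!sharp) next
        rows[[length(rows) + 1]] <-
          data.frame(sample = s, start_bin = a, end_bin = b,
                     type = if (means[[s]] >= mi) "dup" else "del")
      }
    }
    if (length(rows) == 0) next
    df <- do.call(rbind, rows)
    df <- df[order(df$start_bin), , drop = FALSE]
    # merge small gaps of the same type
    i <- 1
    while (i < nrow(df)) {
      if (df$type[i + 1] == df$type[i] &&
          df$start_bin[i + 1] - df$end_bin[i] - 1 <= merge_gap) {
        df$end_bin[i] <- df$end_bin[i + 1]
        df <- df[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    out[[length(out) + 1]] <- df
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), start_bin = integer(),
                      end_bin = integer(), type = character()))
  res <- do.call(rbind, out)
  res[order(res$sample, res$start_bin), , drop = FALSE]
}

# per-base maximum overlap depth on a small coordinate space
oracle_minimal_region <- function(intervals, space = 10000) {
  depth <- integer(space)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start[i] + 1):intervals$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  mx <- max(depth)
  list(max_depth = mx, positions = which(depth == mx))
}

# brute-force small-CNV filter rules
oracle_small_filter <- function(calls, large_calls, del_min = 1117,
                                dup_min = 2750, max_len = 1e6) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    len <- calls$end[i] - calls$start[i]
    if (calls$type[i] == "del" && len < del_min) next
    if (calls$type[i] == "dup" && len < dup_min) next
    if (len > max_len) next
    overl <- FALSE
    if (!is.null(large_calls)) {
      for (j in seq_len(nrow(large_calls))) {
        if (large_calls$sample[j] == calls$sample[i] &&
            large_calls$chrom[j] == calls$chrom[i] &&
            large_calls$start[j] < calls$end[i] &&
            large_calls$end[j] > calls$start[i]) overl <- TRUE
      }
    }
    keep[i] <- !overl
  }
  calls[keep, , drop = FALSE]
}

# standard sibling-pedigree fixture: n couples, two children each
sib_pedigree <- function(n_pairs) {
  dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    tibble::tibble(child = sprintf("C%02d%s", i, c("a", "b")),
                   parent1 = sprintf("F%02d", i),
                   parent2 = sprintf("M%02d", i))
  }))
}
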