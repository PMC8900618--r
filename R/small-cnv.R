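#' Post-filter small CNV calls
#'
#' Applies the validated length thresholds and large-event masking to a small
#' CNV call set: deletions shorter than `del_min` bases and duplications
#' shorter than `dup_min` bases are dropped (the thresholds at which array
#' validation achieved the target false-discovery rate), calls longer than
#' `max_len` are dropped as large-event territory, and any call overlapping a
#' large call in the same sample is removed to avoid fragmenting large events
#' into small calls.
#'
#' @param calls tibble with `sample`, `chrom`, `start`, `end`, `type`
#'   (`"del"`/`"dup"`).
#' @param large_calls optional tibble of large calls (`sample`, `chrom`,
#'   `start`, `end`).
#' @param del_min,dup_min minimum lengths in bases.
#' @param max_len maximum length handled as a small call.
#' @return filtered tibble, sorted by sample, chromosome, start.
#' @export
filter_small_cnvs <- function(calls, large_calls = NULL,
                              del_min = 1117, dup_min = 2750, max_len = 1e6) {
  stopifnot_cols(calls, c("sample", "chrom", "start", "end", "type"), "calls")
  out <- calls |>
    mutate(.len = .data$end - .data$start) |>
    filter(!(.data$type == "del" & .data$.len < del_min),
           !(.data$type == "dup" & .data$.len < dup_min),
           .data$.len <= max_len) |>
    select(-".len")
  if (!is.null(large_calls) && nrow(large_calls) > 0) {
    hit <- vapply(seq_len(nrow(out)), function(i) {
      any(large_calls$sample == out$sample[i] &
            large_calls$chrom == out$chrom[i] &
            large_calls$start < out$end[i] &
            large_calls$end > out$start[i])
    }, logical(1))
    out <- out[!hit, , drop = FALSE]
  }
  arrange(out, .data$sample, .data$chrom, .data$start)
}

# Cluster calls into identity classes by >= frac reciprocal overlap
# (same chromosome and type). Returns an integer cluster id per row.
cluster_reciprocal <- function(calls, frac = 0.5) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    idx <- idx[order(calls$start[idx])]
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (b in seq_along(idx)[-seq_len(a)]) {
        j <- idx[b]
        if (calls$start[j] >= calls$end[i]) break
        if (!is.null(calls$type) && calls$type[i] != calls$type[j]) next
        ov <- min(calls$end[i], calls$end[j]) -
          max(calls$start[i], calls$start[j])
        li <- calls$end[i] - calls$start[i]
        lj <- calls$end[j] - calls$start[j]
        if (ov >= frac * li && ov >= frac * lj)
          parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Screen for CNVs recurrent in stem cell lines but rare in controls
#'
#' Clusters calls across cohorts into identity classes by at least
#' `reciprocal` reciprocal overlap (same chromosome and type), then reports
#' classes carried by at least `min_lines` distinct stem cell lines, absent
#' from the European control cohort, and present in less than
#' `max_other_frac` of the other control cohort.
#'
#' @param hesc_calls,euro_calls,other_calls call tibbles (`sample`, `chrom`,
#'   `start`, `end`, `type`).
#' @param min_lines minimum number of distinct carrier lines.
#' @param max_other_frac maximum carrier fraction in the other-control cohort.
#' @param reciprocal reciprocal-overlap fraction defining call identity.
#' @param n_euro,n_other cohort sizes; default the number of distinct sample
#'   ids in each call set (pass explicitly when carriers are a subset).
#' @return tibble of candidate regions with carrier counts, member lists and
#'   a `vacuous_controls` flag raised when a control cohort was empty.
#' @export
recurrent_cnv_screen <- function(hesc_calls, euro_calls, other_calls,
                                 min_lines = 5, max_other_frac = 0.10,
                                 reciprocal = 0.5,
                                 n_euro = NULL, n_other = NULL) {
  all_calls <- bind_rows(
    mutate(hesc_calls, .cohort = "hesc"),
    mutate(euro_calls, .cohort = "euro"),
    mutate(other_calls, .cohort = "other")
  )
  if (nrow(all_calls) == 0) return(tibble())
  n_euro <- n_euro %||% n_distinct(euro_calls$sample)
  n_other <- n_other %||% n_distinct(other_calls$sample)
  vacuous <- n_euro == 0 || n_other == 0
  all_calls$.cluster <- cluster_reciprocal(all_calls, reciprocal)
  all_calls |>
    group_by(.data$.cluster) |>
    summarise(
      chrom = first(.data$chrom), start = min(.data$start),
      end = max(.data$end), type = first(.data$type),
      n_hesc = n_distinct(.data$sample[.data$.cohort == "hesc"]),
      n_euro_carriers = n_distinct(.data$sample[.data$.cohort == "euro"]),
      n_other_carriers = n_distinct(.data$sample[.data$.cohort == "other"]),
      members = list(sort(unique(.data$sample[.data$.cohort == "hesc"]))),
      .groups = "drop"
    ) |>
    mutate(frac_other = if (n_other > 0)
             .data$n_other_carriers / n_other else 0,
           vacuous_controls = vacuous) |>
    filter(.data$n_hesc >= min_lines,
           .data$n_euro_carriers == 0,
           .data$frac_other < max_other_frac) |>
    select(-".cluster") |>
    arrange(.data$chrom, .data$start)
}

#' Per-sample singleton CNV counts
#'
#' A singleton is a call whose identity class (by at least `reciprocal`
#' reciprocal overlap across the full combined call set) has exactly one
#' member. Callers should pass a call set already reduced to one
#' representative per sibship so that events shared between first-degree
#' relatives are not miscounted as recurrent.
#'
#' @param calls combined call tibble across all cohorts and reference sets.
#' @param samples samples to report counts for; default all in `calls`.
#' @param reciprocal reciprocal-overlap fraction defining identity.
#' @return tibble of `sample`, `n_singleton`.
#' @export
singleton_burden <- function(calls, samples = NULL, reciprocal = 0.5) {
  samples <- samples %||% sort(unique(calls$sample))
  if (nrow(calls) == 0)
    return(tibble(sample = samples, n_singleton = 0L))
  cl <- cluster_reciprocal(calls, reciprocal)
  sizes <- table(cl)
  singleton <- cl %in% as.integer(names(sizes)[sizes == 1])
  counts <- calls[singleton, ] |> count(.data$sample, name = "n_singleton")
  tibble(sample = samples) |>
    left_join(counts, by = "sample") |>
    mutate(n_singleton = tidyr::replace_na(.data$n_singleton, 0L))
}
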