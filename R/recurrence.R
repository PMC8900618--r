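#' Minimal shared region of a set of intervals
#'
#' Boundary-sweep over one chromosome's intervals: returns the region(s) of
#' maximum overlap depth, with depth and contributing lines. Ties in depth
#' report every tied segment (their union describes the minimal region).
#' Fully disjoint inputs return the deepest (depth 1) segments flagged
#' `disjoint`.
#'
#' @param intervals tibble with `line`, `chrom`, `start`, `end` (0-based
#'   half-open), all on one chromosome for a minimal-region query.
#' @return tibble of maximal-depth segments: `chrom`, `start`, `end`,
#'   `depth`, `lines` (list-column), `disjoint`.
#' @export
#' @examples
#' iv <- tibble::tibble(line = c("a", "b"), chrom = "chr1",
#'                      start = c(100, 300), end = c(500, 900))
#' minimal_region(iv) # [300, 500), depth 2
minimal_region <- function(intervals) {
  stopifnot_cols(intervals, c("line", "chrom", "start", "end"), "intervals")
  if (length(unique(intervals$chrom)) != 1)
    stop("minimal-region queries expect a single chromosome", call. = FALSE)
  if (nrow(intervals) < 1) return(tibble())
  bp <- sort(unique(c(intervals$start, intervals$end)))
  segs <- tibble(chrom = intervals$chrom[1],
                 start = bp[-length(bp)], end = bp[-1])
  segs$depth <- vapply(seq_len(nrow(segs)), function(i) {
    sum(intervals$start <= segs$start[i] & intervals$end >= segs$end[i])
  }, numeric(1))
  segs$lines <- lapply(seq_len(nrow(segs)), function(i) {
    sort(intervals$line[intervals$start <= segs$start[i] &
                          intervals$end >= segs$end[i]])
  })
  top <- segs[segs$depth == max(segs$depth), , drop = FALSE]
  # merge adjacent tied segments with identical contributing lines
  if (nrow(top) > 1) {
    keep <- logical(nrow(top)); keep[1] <- TRUE; j <- 1
    for (i in seq_len(nrow(top))[-1]) {
      if (top$start[i] == top$end[j] &&
          identical(top$lines[[i]], top$lines[[j]])) {
        top$end[j] <- top$end[i]
      } else { j <- i; keep[i] <- TRUE }
    }
    top <- top[keep, , drop = FALSE]
  }
  top$disjoint <- max(segs$depth) == 1 && nrow(intervals) > 1
  as_tibble(top)
}

#' Scan sequence windows for a tandem microsatellite motif
#'
#' Searches each window (e.g. the flanks of recurrent-CNV breakpoints) for
#' maximal tandem runs of a repeat unit, counting all cyclic rotations of the
#' unit and of its reverse complement as equivalent phases — the pattern set
#' is therefore closed under reverse complementation of the window. The
#' default unit GGAAT (equivalently AATGG) is the human satellite 3 repeat.
#'
#' @param windows named character vector of DNA sequences (uppercase ACGTN).
#' @param unit repeat unit (default `"GGAAT"`).
#' @param min_units minimum number of tandem units to report a hit.
#' @return tibble of hits: `window`, `phase` (matched rotation), `start`
#'   (1-based), `length`, `n_units`.
#' @export
motif_scan <- function(windows, unit = "GGAAT", min_units = 3) {
  if (is.null(names(windows)))
    names(windows) <- sprintf("window%02d", seq_along(windows))
  rots <- function(u) {
    vapply(seq_len(nchar(u)), function(i) {
      paste0(substr(u, i, nchar(u)), substr(u, 1, i - 1))
    }, character(1))
  }
  phases <- unique(c(rots(toupper(unit)), rots(revcomp(toupper(unit)))))
  purrr::map_dfr(names(windows), function(w) {
    seq_w <- toupper(windows[[w]])
    purrr::map_dfr(phases, function(ph) {
      pat <- sprintf("(?:%s){%d,}", ph, min_units)
      hits <- gregexpr(pat, seq_w, perl = TRUE)[[1]]
      if (hits[1] == -1) return(tibble())
      tibble(window = w, phase = ph, start = as.integer(hits),
             length = attr(hits, "match.length"),
             n_units = attr(hits, "match.length") %/% nchar(ph))
    }) |>
      merge_phase_hits()
  })
}

# keep one maximal hit per physical tandem run: the same run matches
# several rotations at shifted offsets, so overlapping hits are clustered
# and the longest (earliest on ties) representative is kept
merge_phase_hits <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  hits <- arrange(hits, .data$start)
  cluster <- cumsum(c(1, hits$start[-1] >=
                        cummax(hits$start + hits$length)[-nrow(hits)]))
  hits |>
    mutate(.cl = cluster) |>
    group_by(.data$.cl) |>
    arrange(desc(.data$length), .data$start, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".cl")
}

#' GC fraction of genomic intervals
#'
#' Computes the G+C base fraction of each interval from reference sequences,
#' excluding N bases from the denominator; intervals consisting only of N
#' are dropped and counted. When two cohort labels are present, distribution
#' quantiles per cohort are returned alongside.
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `cohort`.
#' @param sequences named character vector of chromosome sequences, or a path
#'   to a FASTA file (read with Biostrings when available).
#' @return list with `per_interval` (intervals + `gc`) and `cohort_summary`
#'   (quantiles per cohort, NULL when no cohort column), plus `n_excluded`.
#' @export
gc_profile <- function(intervals, sequences) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "intervals")
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  }
  gc <- vapply(seq_len(nrow(intervals)), function(i) {
    s <- substr(sequences[[intervals$chrom[i]]],
                intervals$start[i] + 1, intervals$end[i])
    bases <- strsplit(toupper(s), "")[[1]]
    informative <- bases %in% c("A", "C", "G", "T")
    if (!any(informative)) return(NA_real_)
    sum(bases %in% c("G", "C")) / sum(informative)
  }, numeric(1))
  per_interval <- mutate(intervals, gc = gc)
  n_excluded <- sum(is.na(gc))
  per_interval <- filter(per_interval, !is.na(.data$gc))
  cohort_summary <- NULL
  if ("cohort" %in% names(per_interval)) {
    cohort_summary <- per_interval |>
      group_by(.data$cohort) |>
      summarise(n = n(),
                q25 = quantile(.data$gc, 0.25), median = median(.data$gc),
                q75 = quantile(.data$gc, 0.75), mean = mean(.data$gc),
                .groups = "drop")
  }
  list(per_interval = per_interval, cohort_summary = cohort_summary,
       n_excluded = n_excluded)
}

#' Regress per-line variant burdens on candidate covariates
#'
#' Ordinary least squares of each burden class (count column) on the supplied
#' covariates, one model per class, reporting coefficients with two-sided
#' p-values. Collinear covariates are dropped by the fit with a warning.
#' Returns a `burden_reg` object with [generics::tidy()] and
#' [generics::glance()] methods.
#'
#' @param table per-line tibble of burden counts and covariates.
#' @param burden_cols names of the count columns to model.
#' @param covariate_cols names of the covariate columns.
#' @return object of class `burden_reg`.
#' @export
burden_regression <- function(table, burden_cols, covariate_cols) {
  stopifnot_cols(table, c(burden_cols, covariate_cols), "burden table")
  if (nrow(table) <= length(covariate_cols) + 2)
    stop("need more lines than covariates + 2", call. = FALSE)
  fits <- lapply(setNames(burden_cols, burden_cols), function(bc) {
    fit <- lm(stats::reformulate(covariate_cols, response = bc),
              data = table)
    if (anyNA(coef(fit))) {
      dropped <- names(coef(fit))[is.na(coef(fit))]
      warning("dropping collinear covariate(s) for ", bc, ": ",
              paste(dropped, collapse = ", "))
    }
    fit
  })
  structure(list(fits = fits, n = nrow(table)), class = "burden_reg")
}

#' @export
print.burden_reg <- function(x, ...) {
  cat("Burden regression over", x$n, "lines;",
      length(x$fits), "burden class(es):\n")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' Tidy the coefficient table of a burden regression
#'
#' @param x a `burden_reg` object.
#' @param ... unused.
#' @return tibble with `burden`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.burden_reg <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, bc) {
    s <- summary(fit)$coefficients
    tibble(burden = bc, term = rownames(s), estimate = s[, 1],
           std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
  })
}

#' One-row model summaries for a burden regression
#'
#' @param x a `burden_reg` object.
#' @param ... unused.
#' @return tibble with `burden`, `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`.
#' @export
glance.burden_reg <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, bc) {
    s <- summary(fit)
    tibble(burden = bc, r.squared = s$r.squared,
           adj.r.squared = s$adj.r.squared, sigma = s$sigma,
           df.residual = fit$df.residual, nobs = length(fit$residuals))
  })
}
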