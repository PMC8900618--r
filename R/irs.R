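#' Intensity rank sum test for one CNV call
#'
#' Ranks every sample's array intensity at each probe assigned to the call
#' (midranks for ties), pools the carrier ranks over probes, and computes a
#' one-sided p-value against the null of random ranks — low ranks for
#' deletions, high for duplications. With a single carrier and no ties the
#' null distribution is computed exactly by convolving the per-probe uniform
#' rank distributions; otherwise a normal approximation with continuity
#' correction is used (per-probe variance of a without-replacement rank sum).
#' Completely tied intensities give p = 0.5.
#'
#' @param intensity matrix of probes x samples (rows are the call's probes).
#' @param carriers sample ids (column names) predicted to carry the call.
#' @param type `"del"` (carriers expected low) or `"dup"` (high).
#' @return one-sided p-value.
#' @export
#' @examples
#' m <- rbind(c(0.1, 1:9), c(0.2, 2:10)) # carrier lowest at both probes
#' colnames(m) <- paste0("S", 1:10)
#' irs_test(m, "S1", "del") # exact: (1/10)^2
irs_test <- function(intensity, carriers, type = c("del", "dup")) {
  type <- match.arg(type)
  stopifnot(is.matrix(intensity), !is.null(colnames(intensity)))
  if (!all(carriers %in% colnames(intensity)))
    stop("carriers must be columns of the intensity matrix", call. = FALSE)
  n <- ncol(intensity)
  nc <- length(carriers)
  if (nc < 1 || nc >= n)
    stop("need at least one carrier and one non-carrier", call. = FALSE)
  ranks <- t(apply(intensity, 1, rank, ties.method = "average"))
  if (nrow(intensity) == 1) ranks <- matrix(ranks, nrow = 1,
                                            dimnames = dimnames(intensity))
  stat <- sum(ranks[, carriers])
  np <- nrow(intensity)
  tied <- all(apply(intensity, 1, function(x) length(unique(x)) == 1))
  if (tied) return(0.5)

  has_ties <- any(apply(intensity, 1, anyDuplicated) > 0)
  if (nc == 1 && !has_ties && np * n <= 1e6) {
    # exact: sum of np independent uniform ranks on 1..n
    pmf <- 1
    for (i in seq_len(np)) pmf <- convolve_uniform(pmf, n)
    support <- seq_along(pmf) + np - 1 # minimum sum is np
    probs <- pmf
    if (type == "del") p <- sum(probs[support <= stat])
    else p <- sum(probs[support >= stat])
    return(min(max(p, 0), 1))
  }
  mu <- np * nc * (n + 1) / 2
  v <- np * nc * (n + 1) * (n - nc) / 12
  if (v <= 0) return(0.5)
  if (type == "del") pnorm((stat - mu + 0.5) / sqrt(v))
  else pnorm((stat - mu - 0.5) / sqrt(v), lower.tail = FALSE)
}

convolve_uniform <- function(pmf, n) {
  out <- numeric(length(pmf) + n - 1)
  u <- rep(1 / n, n)
  for (i in seq_along(pmf)) {
    out[i:(i + n - 1)] <- out[i:(i + n - 1)] + pmf[i] * u
  }
  out
}

#' Run the intensity rank sum test over a call set
#'
#' @param calls tibble with `call_id`, `type` and a `carriers` list-column.
#' @param intensities wide probe intensity tibble (`probe_id`, `chrom`,
#'   `pos`, one column per sample), as from [sim_array_intensities()].
#' @param probe_map tibble `probe_id`, `call_id`.
#' @param min_probes calls with fewer assigned probes are skipped (array
#'   validation requires at least 2 probes in the call).
#' @return tibble `call_id`, `type`, `n_probes`, `p` (NA when skipped).
#' @export
run_irs <- function(calls, intensities, probe_map, min_probes = 2) {
  im <- split_wide(intensities, c("probe_id", "chrom", "pos"))
  rownames(im$m) <- intensities$probe_id
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    pid <- probe_map$probe_id[probe_map$call_id == calls$call_id[i]]
    if (length(pid) < min_probes)
      return(tibble(call_id = calls$call_id[i], type = calls$type[i],
                    n_probes = length(pid), p = NA_real_))
    p <- irs_test(im$m[pid, , drop = FALSE], calls$carriers[[i]],
                  calls$type[i])
    tibble(call_id = calls$call_id[i], type = calls$type[i],
           n_probes = length(pid), p = p)
  })
}

#' Estimate the cohort false discovery rate from IRS p-values
#'
#' Under the null (a false call) the IRS p-value is uniform, so the fraction
#' of calls with `p >= 0.5` estimates half the false fraction:
#' `FDR = 2 x fraction(p >= 0.5)`, clipped to [0, 1]. True calls concentrate
#' near 0 and contribute almost nothing to the upper half.
#'
#' @param p numeric vector of IRS p-values (NAs dropped).
#' @param min_calls minimum number of tested calls for a stable estimate.
#' @return FDR estimate in [0, 1].
#' @export
estimate_fdr <- function(p, min_calls = 20) {
  p <- p[!is.na(p)]
  if (length(p) < min_calls)
    warning("FDR estimated from fewer than ", min_calls, " calls")
  clip01(2 * mean(p >= 0.5))
}

#' Find per-type length thresholds achieving a target FDR
#'
#' For each call type, scans the observed call lengths in ascending order and
#' returns the smallest length cutoff such that the calls at or above it have
#' an estimated FDR at or below `target`. If no cutoff attains the target,
#' the cutoff minimizing the FDR is returned with `attained = FALSE`.
#'
#' @param results tibble with `type`, `length`, `p` (IRS p-values).
#' @param target target FDR (default 0.03).
#' @return tibble per type: `type`, `threshold`, `fdr`, `n_retained`,
#'   `attained`.
#' @export
threshold_search <- function(results, target = 0.03) {
  stopifnot_cols(results, c("type", "length", "p"), "results")
  purrr::map_dfr(unique(results$type), function(ty) {
    x <- results |> filter(.data$type == ty, !is.na(.data$p))
    cuts <- sort(unique(x$length))
    fdrs <- vapply(cuts, function(L) {
      suppressWarnings(estimate_fdr(x$p[x$length >= L]))
    }, numeric(1))
    hit <- which(fdrs <= target)
    if (length(hit) > 0) {
      j <- hit[1]
      tibble(type = ty, threshold = cuts[j], fdr = fdrs[j],
             n_retained = sum(x$length >= cuts[j]), attained = TRUE)
    } else {
      j <- which.min(fdrs)
      tibble(type = ty, threshold = cuts[j], fdr = fdrs[j],
             n_retained = sum(x$length >= cuts[j]), attained = FALSE)
    }
  })
}
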