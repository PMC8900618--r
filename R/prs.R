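#' Compute raw polygenic scores
#'
#' For each trait, sums `dosage x weight` over the markers whose source-study
#' association p-value is below `p_max` (default 0.5, i.e. essentially all
#' nominally oriented markers). Dosages are aligned to the effect allele:
#' when the effect allele is the reference allele the dosage is flipped to
#' `2 - dosage`. Missing dosages are imputed with the cohort mean at the
#' marker.
#'
#' @param geno wide genotype tibble (`chrom`, `pos`, `id`, optional `ref`,
#'   `alt`, one dosage column per sample). Dosages count alt alleles.
#' @param weights tibble with `id`, `effect_allele`, `weight`, `p` and
#'   optionally `trait` (default a single trait `"trait"`).
#' @param p_max markers with source p-values at or above this are excluded.
#' @return tibble `sample`, `trait`, `raw`, `n_markers`.
#' @export
compute_raw_prs <- function(geno, weights, p_max = 0.5) {
  stopifnot_cols(weights, c("id", "effect_allele", "weight", "p"), "weights")
  if (!"trait" %in% names(weights)) weights$trait <- "trait"
  gm <- as_geno_matrix(geno)
  m <- gm$m
  # mean imputation of missing dosages
  if (anyNA(m)) {
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 1]]
  }
  w <- weights |> filter(.data$p < p_max)
  if (nrow(w) == 0)
    stop("no markers overlap the score after the p-value filter",
         call. = FALSE)
  purrr::map_dfr(unique(w$trait), function(tr) {
    wt <- w[w$trait == tr, ]
    rows <- match(wt$id, geno$id)
    okv <- !is.na(rows)
    if (!any(okv))
      stop("no overlapping markers between genotypes and weights for trait ",
           tr, call. = FALSE)
    wt <- wt[okv, ]; rows <- rows[okv]
    d <- m[rows, , drop = FALSE]
    if ("ref" %in% names(geno)) {
      flip <- wt$effect_allele == geno$ref[rows]
      d[flip, ] <- 2 - d[flip, ]
    }
    tibble(sample = gm$samples,
           trait = tr,
           raw = as.numeric(crossprod(d, wt$weight)),
           n_markers = nrow(wt))
  })
}

#' Adjust polygenic scores for ancestry PCs and normalize to controls
#'
#' Per trait: ordinary least squares of the raw score on the first `n_pc`
#' principal components, fit on the control samples only; residuals are taken
#' for all samples and converted to z-scores using the control residual mean
#' and (n-1) standard deviation, so the control distribution has exactly zero
#' mean and unit SD. Samples at least `outlier_sd` SDs from the control mean
#' are flagged outliers. Collinear PCs are dropped with a warning.
#'
#' @param raw tibble from [compute_raw_prs()] (`sample`, `trait`, `raw`).
#' @param pcs tibble with `sample` and PC columns (`PC1`, `PC2`, ...).
#' @param controls character vector of control sample ids.
#' @param n_pc number of leading PCs to regress out (default 12).
#' @param outlier_sd outlier flag threshold in SD units (inclusive).
#' @return tibble `sample`, `trait`, `raw`, `adjusted`, `z`, `outlier`.
#' @export
adjust_and_normalize <- function(raw, pcs, controls, n_pc = 12,
                                 outlier_sd = 2) {
  stopifnot_cols(raw, c("sample", "trait", "raw"), "raw scores")
  stopifnot_cols(pcs, "sample", "pcs")
  pc_cols <- paste0("PC", seq_len(n_pc))
  pc_cols <- intersect(pc_cols, names(pcs))
  if (length(pc_cols) == 0) stop("no PC columns found", call. = FALSE)
  if (length(intersect(controls, pcs$sample)) <
      length(pc_cols) + 13)
    stop("need at least n_pc + 13 control samples with PCs", call. = FALSE)

  purrr::map_dfr(unique(raw$trait), function(tr) {
    x <- raw |> filter(.data$trait == tr) |> inner_join(pcs, by = "sample")
    ctrl <- x$sample %in% controls
    fit <- lm(stats::reformulate(pc_cols, response = "raw"),
              data = x[ctrl, ])
    if (anyNA(coef(fit))) {
      dropped <- names(coef(fit))[is.na(coef(fit))]
      warning("dropping collinear PC(s): ", paste(dropped, collapse = ", "))
      kept <- setdiff(pc_cols, dropped)
      fit <- lm(stats::reformulate(c("1", kept), response = "raw"),
                data = x[ctrl, ])
    }
    adj <- x$raw - predict(fit, newdata = x)
    mu <- mean(adj[ctrl]); sdev <- sd(adj[ctrl])
    z <- (adj - mu) / sdev
    tibble(sample = x$sample, trait = tr, raw = x$raw, adjusted = adj,
           z = z, outlier = abs(z) >= outlier_sd)
  })
}

#' Rank lines by combined absolute polygenic-score deviation
#'
#' Sums `|z|` over traits per line and ranks ascending, so the top-ranked
#' lines sit closest to the control population mean across all scored traits
#' ("all-purpose" lines). Lines missing any trait are excluded and flagged.
#'
#' @param profiles tibble from [adjust_and_normalize()].
#' @param n_traits expected number of traits per line; default the number of
#'   distinct traits present.
#' @return tibble `sample`, `combined`, `n_outlier_traits`, `complete`,
#'   `rank` (NA for incomplete lines), sorted by rank.
#' @export
rank_all_purpose <- function(profiles, n_traits = NULL) {
  stopifnot_cols(profiles, c("sample", "trait", "z"), "profiles")
  n_traits <- n_traits %||% n_distinct(profiles$trait)
  if (!"outlier" %in% names(profiles)) profiles$outlier <- FALSE
  out <- profiles |>
    group_by(.data$sample) |>
    summarise(combined = sum(abs(.data$z)),
              n_outlier_traits = sum(.data$outlier),
              complete = n_distinct(.data$trait) == n_traits,
              .groups = "drop") |>
    arrange(desc(.data$complete), .data$combined, .data$sample)
  out$rank <- ifelse(out$complete, cumsum(out$complete), NA_integer_)
  out
}
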