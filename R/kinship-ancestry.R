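geno_meta_cols <- c("chrom", "pos", "id", "ref", "alt")

as_geno_matrix <- function(geno) {
  stopifnot_cols(geno, "id", "genotypes")
  split_wide(geno, geno_meta_cols)
}

#' Window-based LD pruning by variance inflation factor
#'
#' Slides a window of `window` sites advancing by `step`; within each window,
#' the site with the largest variance inflation factor
#' (`VIF = 1 / (1 - R^2)` from regressing its dosage on the other window
#' sites) is removed iteratively until no VIF exceeds `vif_max`. Sites with
#' constant genotype (undefined VIF) are removed up front; perfectly
#' collinear sites are resolved by removing the site with the strongest mean
#' absolute correlation to the rest of the window.
#'
#' @param geno wide genotype tibble (`chrom`, `pos`, `id`, one dosage column
#'   per sample).
#' @param window window size in sites.
#' @param step window step in sites.
#' @param vif_max VIF threshold above which a site is pruned.
#' @return tibble of retained sites (`chrom`, `pos`, `id`).
#' @export
ld_prune <- function(geno, window = 50, step = 5, vif_max = 2) {
  gm <- as_geno_matrix(geno)
  m <- gm$m # sites x samples
  v <- matrixStats::rowVars(m, na.rm = TRUE)
  keep <- is.finite(v) & v > 0
  start <- 1
  while (start <= nrow(m)) {
    idx <- which(keep)[which(keep) >= start &
                         which(keep) < start + window]
    if (length(idx) >= 2) {
      repeat {
        r <- suppressWarnings(cor(t(m[idx, , drop = FALSE]),
                                  use = "pairwise.complete.obs"))
        r[!is.finite(r)] <- 0
        vif <- tryCatch(diag(solve(r)), error = function(e) NULL)
        if (is.null(vif) || any(!is.finite(vif))) {
          # singular window: drop the most correlated site
          worst <- which.max(rowMeans(abs(r)) - 1 / length(idx))
        } else if (max(vif) > vif_max) {
          worst <- which.max(vif)
        } else break
        keep[idx[worst]] <- FALSE
        idx <- idx[-worst]
        if (length(idx) < 2) break
      }
    }
    start <- start + step
  }
  gm$meta[keep, , drop = FALSE] |> as_tibble()
}

#' Method-of-moments IBD and kinship estimation for sample pairs
#'
#' Estimates the genome fractions shared identical-by-descent (IBD 0/1/2)
#' for each sample pair from identity-by-state counts and allele
#' frequencies, following the classic method-of-moments estimator used for
#' genome-wide relatedness screening. Estimates are clipped to the simplex;
#' `pi_hat = ibd1/2 + ibd2` and `kinship = pi_hat / 2`. `ibs0` is the
#' fraction of sites at which the pair carries opposite homozygotes.
#'
#' @param geno wide genotype tibble (ideally LD-pruned).
#' @param pairs optional tibble with `id1`, `id2`; default all pairs.
#' @param freq optional per-site allele frequency vector; default estimated
#'   from the data.
#' @param min_sites below this many shared non-missing sites a pair is
#'   flagged low-confidence.
#' @return tibble per pair: `id1`, `id2`, `n_sites`, `ibs0`, `ibd0`, `ibd1`,
#'   `ibd2`, `pi_hat`, `kinship`, `low_confidence`.
#' @export
estimate_ibd <- function(geno, pairs = NULL, freq = NULL, min_sites = 1000) {
  gm <- as_geno_matrix(geno)
  m <- gm$m
  samples <- gm$samples
  if (is.null(pairs)) {
    cmb <- utils::combn(samples, 2)
    pairs <- tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  }
  p <- freq %||% (rowMeans(m, na.rm = TRUE) / 2)
  q <- 1 - p
  # expected per-site IBS probabilities conditional on IBD state
  e_ibs0_ibd0 <- 2 * p^2 * q^2
  e_ibs1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e_ibs2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e_ibs1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e_ibs2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2

  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    g1 <- m[, pairs$id1[i]]; g2 <- m[, pairs$id2[i]]
    okv <- !is.na(g1) & !is.na(g2)
    ibs <- 2 - abs(g1[okv] - g2[okv]) # het-het counts as IBS2
    n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
    ns <- sum(okv)
    E00 <- sum(e_ibs0_ibd0[okv]); E10 <- sum(e_ibs1_ibd0[okv])
    E20 <- sum(e_ibs2_ibd0[okv]); E11 <- sum(e_ibs1_ibd1[okv])
    E21 <- sum(e_ibs2_ibd1[okv])
    ibd0 <- n0 / E00
    ibd1 <- (n1 - ibd0 * E10) / E11
    ibd2 <- (n2 - ibd0 * E20 - ibd1 * E21) / ns
    v <- clip01(c(ibd0, ibd1, ibd2))
    v <- v / sum(v)
    pi_hat <- v[2] / 2 + v[3]
    tibble(id1 = pairs$id1[i], id2 = pairs$id2[i], n_sites = ns,
           ibs0 = n0 / ns, ibd0 = v[1], ibd1 = v[2], ibd2 = v[3],
           pi_hat = pi_hat, kinship = pi_hat / 2,
           low_confidence = ns < min_sites)
  })
}

#' Classify pairwise relationships from IBD estimates
#'
#' A pair is directly related (parent-child or full sibling) when `pi_hat`
#' lies in the 35-70% window; within that window, full siblings are
#' separated from parent-child pairs by `ibd2 >= 0.10` (siblings expect
#' IBD2 = 0.25, parent-child 0). Pairs above the window are flagged
#' duplicates/monozygotic; pairs with `pi_hat` below 0.177 (the midpoint of
#' the second- and third-degree expectations) are unrelated, the remainder
#' (e.g. half siblings, expectation 0.25) are `other`.
#'
#' @param rel tibble from [estimate_ibd()].
#' @return `rel` with `relationship` and `direct` columns.
#' @export
classify_relationship <- function(rel) {
  rel |>
    mutate(
      direct = .data$pi_hat >= 0.35 & .data$pi_hat <= 0.70,
      relationship = case_when(
        .data$pi_hat > 0.70 ~ "duplicate",
        direct & .data$ibd2 >= 0.10 ~ "full_siblings",
        direct ~ "parent_child",
        .data$pi_hat < 0.177 ~ "unrelated",
        TRUE ~ "other"
      )
    )
}

#' Principal-component ancestry fractions from a labelled reference panel
#'
#' Computes a joint PCA of query and reference samples from the standardized
#' genotype relationship matrix, then fits one linear model per ancestry
#' component from the first `n_pc` principal components on the reference
#' samples (whose true fractions are supplied) and predicts fractions for all
#' samples, clipping to [0, 1] and renormalizing to sum to one.
#'
#' @param geno wide genotype tibble containing reference and query samples.
#' @param ref_labels tibble with `sample` plus one fraction column per
#'   ancestry component (reference samples only; must cover at least 3
#'   populations).
#' @param n_pc number of principal components in the linear model.
#' @return tibble per sample: `sample`, `is_reference`, `PC1..PCn`, one
#'   fraction column per ancestry component.
#' @export
pca_ancestry <- function(geno, ref_labels, n_pc = 3) {
  stopifnot_cols(ref_labels, "sample", "ref_labels")
  comps <- setdiff(names(ref_labels), "sample")
  if (length(comps) < 3)
    stop("reference panel must label at least 3 ancestry components",
         call. = FALSE)
  gm <- as_geno_matrix(geno)
  m <- gm$m # sites x samples
  p <- rowMeans(m, na.rm = TRUE) / 2
  ok <- p > 0 & p < 1 & is.finite(p)
  x <- (m[ok, , drop = FALSE] - 2 * p[ok]) / sqrt(2 * p[ok] * (1 - p[ok]))
  x[is.na(x)] <- 0
  grm <- crossprod(x) / sum(ok) # samples x samples
  ev <- eigen(grm, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(n_pc), drop = FALSE] *
    rep(sqrt(pmax(ev$values[seq_len(n_pc)], 0)), each = ncol(grm))
  colnames(pcs) <- paste0("PC", seq_len(n_pc))
  pcs_tbl <- bind_cols(tibble(sample = gm$samples), as_tibble(pcs))

  ref <- inner_join(pcs_tbl, ref_labels, by = "sample")
  if (nrow(ref) < n_pc + 2)
    stop("too few labelled reference samples", call. = FALSE)
  preds <- vapply(comps, function(k) {
    fit <- lm(stats::reformulate(colnames(pcs), response = "y"),
              data = mutate(ref, y = .data[[k]]))
    predict(fit, newdata = pcs_tbl)
  }, numeric(nrow(pcs_tbl)))
  preds <- clip01(preds)
  preds <- preds / pmax(rowSums(preds), 1e-12)
  colnames(preds) <- comps
  bind_cols(pcs_tbl, as_tibble(preds)) |>
    mutate(is_reference = .data$sample %in% ref_labels$sample,
           .after = "sample")
}
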