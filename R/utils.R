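#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad rnorm rpois rbinom runif rbeta sd pnorm lm
#'   coef resid predict complete.cases setNames dbinom cor p.adjust quantile
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Split a wide table (feature columns + one numeric column per sample) into
# its metadata part and a features x samples matrix.
split_wide <- function(tbl, meta_cols) {
  meta_cols <- intersect(meta_cols, names(tbl))
  samples <- setdiff(names(tbl), meta_cols)
  m <- as.matrix(tbl[, samples, drop = FALSE])
  colnames(m) <- samples
  list(meta = tbl[, meta_cols, drop = FALSE], m = m, samples = samples)
}

row_median <- function(m) matrixStats::rowMedians(m, na.rm = TRUE)
# raw MAD across rows, no consistency scaling
row_mad <- function(m) matrixStats::rowMads(m, constant = 1, na.rm = TRUE)

stopifnot_cols <- function(tbl, cols, what = "input") {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(tbl)
}

# reverse complement without a Biostrings dependency (used by the motif scan)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
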