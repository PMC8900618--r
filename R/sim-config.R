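#' Configuration for the synthetic-data generators
#'
#' A `sim_config` bundles every knob the generators read: cohort size, genome
#' binning, sequencing depth, the read-count noise model, the list of implanted
#' copy-number / CN-LOH events, SNP-panel settings and an optional pedigree.
#' The same configuration (including `seed`) always yields byte-identical
#' outputs from every generator.
#'
#' Depth is translated into expected reads per 100-kbp bin as
#' `mean_depth * bin_size / read_length`, i.e. roughly 20,000 fragments per bin
#' at 30x with 151-base reads, matching short-read whole-genome sequencing of
#' cell lines.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_samples number of cell lines / samples (at least 5; the read-depth
#'   scanner needs peers for its median/MAD reference).
#' @param n_bins number of 100-kbp coverage bins. Either a single count (all on
#'   one chromosome) or a named vector of bins per chromosome.
#' @param bin_size bin width in bases.
#' @param mean_depth mean sequencing depth (reads covering a site).
#' @param read_length read length in bases, used to convert depth to expected
#'   fragments per bin.
#' @param noise_model `"poisson"` (default) or `"negbinom"`.
#' @param dispersion negative-binomial size parameter (ignored for Poisson).
#' @param events tibble of implanted events, see [sim_event()].
#' @param n_snps number of biallelic SNP sites for genotype generators.
#' @param maf_floor lower bound for founder minor-allele frequencies.
#' @param pedigree tibble with columns `child`, `parent1`, `parent2`; founders
#'   are every id appearing only as a parent.
#' @param n_het_sites number of phased heterozygous sites for the allelic
#'   imbalance generator.
#' @param ld_block optional integer; when set, consecutive blocks of this many
#'   SNP sites are exact copies (perfect LD), exercising the LD pruner.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_samples = 10, n_bins = 500)
sim_config <- function(seed = 1L,
                       n_samples = 20L,
                       n_bins = 1000L,
                       bin_size = 1e5,
                       mean_depth = 30,
                       read_length = 151,
                       noise_model = c("poisson", "negbinom"),
                       dispersion = 50,
                       events = sim_event(),
                       n_snps = 10000L,
                       maf_floor = 0.01,
                       pedigree = NULL,
                       n_het_sites = 2000L,
                       ld_block = NULL) {
  noise_model <- match.arg(noise_model)
  if (n_samples < 5)
    stop("n_samples must be at least 5 (median/MAD normalization needs peers)",
         call. = FALSE)
  if (maf_floor < 0 || maf_floor > 0.5)
    stop("maf_floor must be in [0, 0.5]", call. = FALSE)
  if (is.null(names(n_bins))) n_bins <- c(chr1 = unname(n_bins))
  if (!is.null(pedigree)) {
    stopifnot_cols(pedigree, c("child", "parent1", "parent2"), "pedigree")
    check_pedigree_acyclic(pedigree)
  }
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_bins = n_bins, bin_size = bin_size, mean_depth = mean_depth,
    read_length = read_length, noise_model = noise_model,
    dispersion = dispersion, events = events, n_snps = as.integer(n_snps),
    maf_floor = maf_floor, pedigree = pedigree,
    n_het_sites = as.integer(n_het_sites), ld_block = ld_block
  ), class = "sim_config")
}

#' Declare implanted ground-truth events
#'
#' Each row describes one copy-number or copy-neutral LOH event implanted in
#' one sample: the affected bin range (0-based, half-open), the integer copy
#' number of the affected cells and the fraction of cells carrying it
#' (`cell_fraction = 1` means fixed, `< 1` mosaic).
#'
#' @param sample sample id carrying the event.
#' @param chrom chromosome name (must match a configured chromosome).
#' @param start_bin,end_bin 0-based half-open bin range.
#' @param integer_cn copy number in affected cells (2 for `cnloh`, `< 2` for
#'   `del`, `> 2` for `dup`).
#' @param cell_fraction fraction of cells carrying the event, in (0, 1].
#' @param kind `"dup"`, `"del"` or `"cnloh"`.
#' @return tibble with one row per event.
#' @export
#' @examples
#' sim_event("S01", "chr1", 100, 150, integer_cn = 3, cell_fraction = 0.5)
sim_event <- function(sample = character(), chrom = character(),
                      start_bin = integer(), end_bin = integer(),
                      integer_cn = integer(), cell_fraction = numeric(),
                      kind = character()) {
  ev <- tibble(sample = as.character(sample), chrom = as.character(chrom),
               start_bin = as.integer(start_bin), end_bin = as.integer(end_bin),
               integer_cn = as.integer(integer_cn),
               cell_fraction = as.numeric(cell_fraction),
               kind = as.character(kind))
  if (nrow(ev) > 0) {
    if (any(ev$cell_fraction <= 0 | ev$cell_fraction > 1))
      stop("cell_fraction must be in (0, 1]", call. = FALSE)
    bad <- (ev$kind == "cnloh" & ev$integer_cn != 2L) |
      (ev$kind == "del" & ev$integer_cn >= 2L) |
      (ev$kind == "dup" & ev$integer_cn <= 2L)
    if (any(bad))
      stop("event kind inconsistent with integer_cn (cnloh=2, del<2, dup>2)",
           call. = FALSE)
    if (any(ev$end_bin <= ev$start_bin))
      stop("end_bin must exceed start_bin (half-open bin ranges)", call. = FALSE)
  }
  ev
}

check_pedigree_acyclic <- function(ped) {
  # topological check: repeatedly peel children whose parents are resolved
  ids <- unique(c(ped$child, ped$parent1, ped$parent2))
  done <- setdiff(ids, ped$child) # founders
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- remaining$parent1 %in% done & remaining$parent2 %in% done
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    done <- c(done, remaining$child[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  invisible(TRUE)
}

sim_sample_ids <- function(n) sprintf("S%03d", seq_len(n))

# expected fragments per bin given the config
bin_lambda <- function(cfg) cfg$mean_depth * cfg$bin_size / cfg$read_length

# draw read counts under the configured noise model
draw_counts <- function(n, lambda, cfg) {
  if (cfg$noise_model == "poisson") rpois(n, lambda)
  else stats::rnbinom(n, size = cfg$dispersion, mu = lambda)
}

bin_table <- function(cfg) {
  purrr::map_dfr(names(cfg$n_bins), function(ch) {
    nb <- cfg$n_bins[[ch]]
    tibble(chrom = ch,
           start = as.numeric(seq_len(nb) - 1) * cfg$bin_size,
           end = as.numeric(seq_len(nb)) * cfg$bin_size)
  })
}
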