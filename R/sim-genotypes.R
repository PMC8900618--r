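#' Simulate pedigree genotypes by gene drop
#'
#' Founder allele frequencies are drawn uniformly on `[maf_floor, 0.5]`; each
#' founder receives two independently drawn haplotypes carrying unique founder
#' labels, and offspring inherit one haplotype from each parent with an
#' independent Mendelian coin flip per site (no linkage, matching the
#' independence assumption of method-of-moments IBD estimation). Realized IBD
#' sharing per pair is computed directly from the transmitted founder labels,
#' giving an exact ground truth against which the estimator is judged.
#'
#' With `cfg$ld_block = k`, consecutive blocks of `k` sites are exact copies of
#' the block's first site, producing perfect within-block LD for exercising
#' the LD pruner.
#'
#' @param cfg a [sim_config()] with a `pedigree` (may be `NULL` for founders
#'   only, in which case `n_samples` unrelated founders are generated).
#' @return list with `genotypes` (wide tibble: `chrom`, `pos`, `id`, then one
#'   dosage column per sample), `allele_freq`, `relationships` (tibble of all
#'   pairs with the true relationship), and `ibd_truth` (realized IBD0/1/2
#'   site fractions per pair, from founder labels).
#' @export
sim_pedigree_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- cfg$pedigree
  if (is.null(ped)) {
    ids <- sim_sample_ids(cfg$n_samples)
    founders <- ids
    ped <- tibble(child = character(), parent1 = character(),
                  parent2 = character())
  } else {
    ids <- unique(c(ped$parent1, ped$parent2, ped$child))
    founders <- setdiff(ids, ped$child)
  }
  m <- cfg$n_snps

  with_seed(cfg$seed + 202L, {
    p <- runif(m, cfg$maf_floor, 0.5)
    # haplotype allele matrices and founder-label matrices, sites x ids
    hapA <- hapB <- labA <- labB <- list()
    for (fo in founders) {
      hapA[[fo]] <- rbinom(m, 1, p)
      hapB[[fo]] <- rbinom(m, 1, p)
      labA[[fo]] <- rep(paste0(fo, ".A"), m)
      labB[[fo]] <- rep(paste0(fo, ".B"), m)
    }
    remaining <- ped
    while (nrow(remaining) > 0) {
      ready <- remaining$parent1 %in% names(hapA) &
        remaining$parent2 %in% names(hapA)
      for (i in which(ready)) {
        ch <- remaining$child[i]
        p1 <- remaining$parent1[i]; p2 <- remaining$parent2[i]
        pick1 <- rbinom(m, 1, 0.5) == 1
        pick2 <- rbinom(m, 1, 0.5) == 1
        hapA[[ch]] <- ifelse(pick1, hapA[[p1]], hapB[[p1]])
        labA[[ch]] <- ifelse(pick1, labA[[p1]], labB[[p1]])
        hapB[[ch]] <- ifelse(pick2, hapA[[p2]], hapB[[p2]])
        labB[[ch]] <- ifelse(pick2, labA[[p2]], labB[[p2]])
      }
      remaining <- remaining[!ready, , drop = FALSE]
    }
    dos <- vapply(ids, function(s) hapA[[s]] + hapB[[s]], numeric(m))
    lab1 <- vapply(ids, function(s) labA[[s]], character(m))
    lab2 <- vapply(ids, function(s) labB[[s]], character(m))

    if (!is.null(cfg$ld_block) && cfg$ld_block > 1) {
      block <- (seq_len(m) - 1) %/% cfg$ld_block
      first <- match(block, block)
      dos <- dos[first, , drop = FALSE]
      lab1 <- lab1[first, , drop = FALSE]
      lab2 <- lab2[first, , drop = FALSE]
      p <- p[first]
    }

    geno <- bind_cols(
      tibble(chrom = "chr1", pos = seq_len(nrow(dos)) * 1000,
             id = sprintf("snp%06d", seq_len(nrow(dos)))),
      as_tibble(dos)
    )

    pairs <- utils::combn(ids, 2)
    rel <- tibble(id1 = pairs[1, ], id2 = pairs[2, ]) |>
      mutate(relationship = purrr::map2_chr(.data$id1, .data$id2,
                                            ~ true_relationship(.x, .y, ped)))
    ibd_truth <- rel |>
      mutate(purrr::map2_dfr(.data$id1, .data$id2, function(a, b) {
        shared <- (lab1[, a] == lab1[, b] | lab1[, a] == lab2[, b]) +
          (lab2[, a] == lab1[, b] | lab2[, a] == lab2[, b])
        # count matched haplotypes without double-using one haplotype of b
        both <- (lab1[, a] == lab1[, b] & lab2[, a] == lab2[, b]) |
          (lab1[, a] == lab2[, b] & lab2[, a] == lab1[, b])
        n_ibd <- ifelse(both, 2L, pmin(shared, 1L))
        tibble(ibd0 = mean(n_ibd == 0), ibd1 = mean(n_ibd == 1),
               ibd2 = mean(n_ibd == 2))
      }))

    list(genotypes = geno, allele_freq = p, relationships = rel,
         ibd_truth = ibd_truth)
  })
}

true_relationship <- function(a, b, ped) {
  pa <- ped[ped$child == a, ]; pb <- ped[ped$child == b, ]
  parents_a <- if (nrow(pa)) sort(c(pa$parent1, pa$parent2)) else character()
  parents_b <- if (nrow(pb)) sort(c(pb$parent1, pb$parent2)) else character()
  if (b %in% parents_a || a %in% parents_b) return("parent_child")
  if (length(parents_a) && identical(parents_a, parents_b))
    return("full_siblings")
  if (length(parents_a) && length(parents_b) &&
      length(intersect(parents_a, parents_b)) == 1)
    return("half_siblings")
  "unrelated"
}

#' Simulate genotypes for divergent populations and admixed samples
#'
#' Generates a labelled reference panel (and optional query samples) under a
#' Balding-Nichols model: ancestral allele frequencies uniform on
#' `[0.1, 0.9]`, population frequencies Beta-distributed around them with the
#' requested fixation index. Admixed individuals draw each allele copy from a
#' mixture of population frequencies according to their ancestry fractions.
#'
#' @param n_per_pop named vector, samples per population (names are ancestry
#'   labels, e.g. `c(European = 50, African = 50, Asian = 50)`).
#' @param n_sites number of biallelic sites.
#' @param fst fixation index controlling population divergence.
#' @param admixed optional tibble with column `sample` plus one fraction
#'   column per population, describing extra samples to generate.
#' @param seed integer seed.
#' @return list with `genotypes` (wide tibble), `labels` (tibble of true
#'   ancestry fractions per sample) and `pop_freq` (sites x populations).
#' @export
sim_population_genotypes <- function(n_per_pop, n_sites = 5000, fst = 0.1,
                                     admixed = NULL, seed = 1L) {
  pops <- names(n_per_pop)
  stopifnot(!is.null(pops), all(nzchar(pops)))
  with_seed(seed + 303L, {
    p0 <- runif(n_sites, 0.1, 0.9)
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    pf <- vapply(pops, function(k) rbeta(n_sites, a, b), numeric(n_sites))

    ids <- character(); fracs <- list(); dos <- list()
    for (k in pops) {
      for (i in seq_len(n_per_pop[[k]])) {
        sid <- sprintf("%s%03d", k, i)
        ids <- c(ids, sid)
        fr <- setNames(as.numeric(pops == k), pops)
        fracs[[sid]] <- fr
        dos[[sid]] <- rbinom(n_sites, 2, pf %*% fr)
      }
    }
    if (!is.null(admixed)) {
      for (i in seq_len(nrow(admixed))) {
        sid <- admixed$sample[i]
        fr <- setNames(as.numeric(admixed[i, pops]), pops)
        ids <- c(ids, sid)
        fracs[[sid]] <- fr
        dos[[sid]] <- rbinom(n_sites, 2, pf %*% fr)
      }
    }
    geno <- bind_cols(
      tibble(chrom = "chr1", pos = seq_len(n_sites) * 1000,
             id = sprintf("snp%06d", seq_len(n_sites))),
      as_tibble(setNames(dos, ids))
    )
    labels <- bind_rows(purrr::imap(fracs, ~ tibble(sample = .y, !!!.x)))
    list(genotypes = geno, labels = labels, pop_freq = pf)
  })
}
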