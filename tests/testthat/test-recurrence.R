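test_that("minimal region matches pairwise and nested expectations", {
  iv <- tibble::tibble(line = c("a", "b"), chrom = "chr1",
                       start = c(100, 300), end = c(500, 900))
  got <- minimal_region(iv)
  expect_equal(got$start, 300)
  expect_equal(got$end, 500)
  expect_equal(got$depth, 2)
  # nested intervals: the inner one is the minimal region
  nested <- tibble::tibble(line = c("a", "b"), chrom = "chr1",
                           start = c(100, 300), end = c(900, 500))
  gn <- minimal_region(nested)
  expect_equal(c(gn$start, gn$end, gn$depth), c(300, 500, 2))
  # disjoint intervals flagged
  dj <- tibble::tibble(line = c("a", "b"), chrom = "chr1",
                       start = c(0, 600), end = c(100, 700))
  expect_true(all(minimal_region(dj)$disjoint))
})

test_that("minimal region agrees with per-base depth maximization", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 50
    start <- sample(0:9000, n)
    iv <- tibble::tibble(line = sprintf("L%02d", 1:n), chrom = "chr1",
                         start = start,
                         end = start + sample(100:1000, n, TRUE))
    iv$end <- pmin(iv$end, 10000)
    got <- minimal_region(iv)
    want <- oracle_minimal_region(iv, space = 10000)
    expect_equal(got$depth[1], want$max_depth)
    got_pos <- unlist(purrr::map2(got$start, got$end, ~ (.x + 1):.y))
    expect_setequal(got_pos, want$positions)
  }
})

test_that("motif scan finds tandem runs across rotations and strands", {
  expect_equal(motif_scan(c(w = "GGAATGGAATGGAAT"))$n_units, 3)
  # cyclic rotation of the unit
  hit_rot <- motif_scan(c(w = "AATGGAATGGAATGG"))
  expect_equal(nrow(hit_rot), 1)
  expect_equal(hit_rot$n_units, 3)
  # reverse complement strand
  expect_equal(nrow(motif_scan(c(w = "ATTCCATTCCATTCC"))), 1)
  # two units only: below min_units
  expect_equal(nrow(motif_scan(c(w = "GGAATGGAATCCCCC"))), 0)
  # reverse complementing the window preserves the hit count
  w <- "TTTGGAATGGAATGGAATGGAATCCC"
  expect_equal(nrow(motif_scan(c(a = w))),
               nrow(motif_scan(c(a = pluriscan:::revcomp(w)))))
  # random sequence essentially never carries a 3-unit run
  set.seed(72)
  rand <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  }, character(1))
  names(rand) <- sprintf("r%02d", 1:50)
  expect_lte(nrow(motif_scan(rand)), 1)
})

test_that("GC fractions match direct base counting", {
  expect_equal(gc_profile(tibble::tibble(chrom = "c", start = 0, end = 8),
                          c(c = "GCGCGCGC"))$per_interval$gc, 1)
  expect_equal(gc_profile(tibble::tibble(chrom = "c", start = 0, end = 8),
                          c(c = "ATGCATGC"))$per_interval$gc, 0.5)
  set.seed(73)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T", "N"), 5000, TRUE,
                                prob = c(.3, .2, .2, .29, .01)),
                         collapse = ""))
  st <- sample(0:4000, 100)
  iv <- tibble::tibble(chrom = "chr1", start = st,
                       end = st + sample(50:500, 100, TRUE))
  iv$end <- pmin(iv$end, 5000)
  got <- gc_profile(iv, seqs)
  oracle <- vapply(seq_len(nrow(iv)), function(i) {
    b <- strsplit(substr(seqs[["chr1"]], iv$start[i] + 1, iv$end[i]),
                  "")[[1]]
    sum(b %in% c("G", "C")) / sum(b %in% c("A", "C", "G", "T"))
  }, numeric(1))
  expect_equal(got$per_interval$gc, oracle[!is.na(oracle)])
  # N-only interval is excluded and counted
  ivn <- tibble::tibble(chrom = "c", start = 0, end = 3)
  gn <- gc_profile(ivn, c(c = "NNN"))
  expect_equal(nrow(gn$per_interval), 0)
  expect_equal(gn$n_excluded, 1)
})

test_that("burden regression recovers a planted passage effect", {
  set.seed(74)
  n <- 100
  tb <- tibble::tibble(
    passage = sample(5:60, n, TRUE),
    sex = sample(c(0, 1), n, TRUE),
    euro_frac = runif(n))
  tb$n_large_cnv <- rpois(n, pmax(0.1 * tb$passage, 0.01))
  fit <- burden_regression(tb, "n_large_cnv",
                           c("passage", "sex", "euro_frac"))
  td <- tidy(fit)
  est <- td$estimate[td$term == "passage"]
  expect_lt(abs(est - 0.1), 0.05)
  expect_lt(td$p.value[td$term == "passage"], 0.01)
  expect_s3_class(glance(fit), "tbl_df")
  # constant burden: zero slopes
  tb0 <- dplyr::mutate(tb, n_large_cnv = 3)
  # a constant response triggers lm's perfect-fit warning; slopes matter here
  td0 <- suppressWarnings(tidy(burden_regression(tb0, "n_large_cnv",
                                                 c("passage", "sex"))))
  expect_true(all(abs(td0$estimate[td0$term != "(Intercept)"]) < 1e-10))
  expect_error(burden_regression(tb[1:4, ], "n_large_cnv",
                                 c("passage", "sex", "euro_frac")),
               "more lines")
})

test_that("null burden p-values are uniform across replicates", {
  set.seed(75)
  pvals <- replicate(100, {
    tb <- tibble::tibble(passage = sample(5:60, 40, TRUE),
                         burden = rpois(40, 3))
    td <- tidy(burden_regression(tb, "burden", "passage"))
    td$p.value[td$term == "passage"]
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
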