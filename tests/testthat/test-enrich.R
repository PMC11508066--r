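# The binomial tail statistic, the fold-change filter, the four
# unit-construction modes, and the region-density operations.

test_that("binomial tail equals explicit pmf summation and obeys bounds", {
  # spot grid here; the full n <= 12 sweep lives in the acceptance suite
  for (p in c(0.1, 0.5)) {
    for (n in c(1, 7, 10)) {
      for (k in 0:n) {
        expect_equal(binomial_tail(p, n, k), brute_binomial_tail(p, n, k),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(binomial_tail(0.3, 9, 0), 1)
  expect_equal(binomial_tail(0.5, 1, 1), 0.5)
  expect_equal(binomial_tail(0.1, 10, 3), brute_binomial_tail(0.1, 10, 3),
               tolerance = 1e-12)
  expect_equal(round(binomial_tail(0.1, 10, 3), 4), 0.0702)
  expect_error(binomial_tail(1.2, 5, 1), "p must")
  expect_error(binomial_tail(0.5, 5, 6), "k must")
})

test_that("the tail is monotone in k and p and sums with the lower tail", {
  for (n in c(5, 11)) {
    for (p in c(0.05, 0.4, 0.9)) {
      tails <- vapply(0:n, function(k) binomial_tail(p, n, k), numeric(1))
      expect_true(all(diff(tails) <= 1e-15))
      for (k in 0:n) {
        lower <- if (k == 0) 0 else sum(stats::dbinom(0:(k - 1), n, p))
        expect_equal(binomial_tail(p, n, k) + lower, 1, tolerance = 1e-9)
      }
    }
    ks <- 3
    by_p <- vapply(c(0.1, 0.3, 0.5, 0.7), function(p) binomial_tail(p, n, ks),
                   numeric(1))
    expect_true(all(diff(by_p) >= 0))
  }
})

test_that("fold change is the ratio of unit and universe proportions", {
  expect_equal(fold_change(2, 10, 100 / 1000), 2)
  expect_equal(fold_change(5, 50, 0.1), 1)
  expect_error(fold_change(1, 0, 0.1), "n must")
  expect_error(fold_change(1, 10, 0), "degenerate")
})

test_that("unit testing applies both thresholds", {
  r <- test_unit(n = 50, k = 0, p = 0.05)
  expect_equal(r$p_value, 1)
  expect_false(r$passes)
  r2 <- test_unit(n = 50, k = 12, p = 0.05)
  expect_true(r2$fold > 2 && r2$p_value < 1e-3)
  expect_true(r2$passes)
  # fold filter alone can block a pass
  r3 <- test_unit(n = 5000, k = 320, p = 0.05)
  expect_lt(r3$p_value, 1e-3)
  expect_lt(r3$fold, 2)
  expect_false(r3$passes)
  expect_error(test_unit(n = 5, k = 6, p = 0.1), "exceed")
})

# A compact annotation table: 3 genes x hand-chosen missense counts.
toy_annotations <- function() {
  mk <- function(gene, n, k, base) {
    tibble::tibble(chrom = "c1", pos = base + seq_len(n),
                   gene_id = gene, effect_class = "NONSYNONYMOUS_SNV",
                   is_focal_specific = seq_len(n) <= k)
  }
  dplyr::bind_rows(mk("gA", 40, 10, 0), mk("gB", 40, 2, 1000),
                   mk("gC", 20, 2, 2000))
}

test_that("gene-mode enrichment reproduces hand-computed unit tests", {
  ann <- toy_annotations()
  e <- run_enrichment(ann, "GENE_MISSENSE")
  expect_s3_class(e, "focalvar_enrichment")
  expect_equal(e$S_size, 100L)
  expect_equal(e$U_size, 14L)
  res <- tidy(e)
  gA <- res[res$unit_id == "gA", ]
  expect_equal(gA$n, 40L); expect_equal(gA$k, 10L)
  expect_equal(gA$fold, (10 / 40) / 0.14)
  expect_equal(gA$p_value, brute_binomial_tail(0.14, 40, 10), tolerance = 1e-12)
  expect_identical(res$p_value, sort(res$p_value))
  g <- glance(e)
  expect_equal(g$n_units, 3L)
})

test_that("GO modes restrict the universe to annotated genes", {
  ann <- toy_annotations()
  go <- tibble::tibble(gene_id = c("gA", "gB"), go_id = c("GO:1", "GO:1"),
                       go_name = "cat one")
  e <- run_enrichment(ann, "GO_MISSENSE", go_table = go)
  # gC carries no GO term: excluded from the universe entirely
  expect_equal(e$S_size, 80L)
  expect_equal(e$U_size, 12L)
  expect_identical(tidy(e)$unit_id, "GO:1")
  expect_equal(tidy(e)$n, 80L)
  expect_error(run_enrichment(ann, "GO_MISSENSE",
                              go_table = go[0, ]), "non-empty")
  expect_error(run_enrichment(ann, "NOT_A_MODE"), "unknown mode")
})

test_that("window modes count a position once per universe, per unit per gene", {
  gm <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
    start = c(20000L, 22000L), end = c(21000L, 23000L), exon_rank = 1L)
  # one site in the overlap of both windows, one in g1's window only
  ann <- tibble::tibble(chrom = "c1", pos = c(20500L, 11000L),
                        gene_id = NA_character_,
                        effect_class = "INTERGENIC",
                        is_focal_specific = c(TRUE, FALSE))
  e <- run_enrichment(ann, "GENE_FLANK10K", gene_models = gm)
  expect_equal(e$S_size, 2L)      # overlap position counted once
  res <- tidy(e)
  expect_equal(res$n[res$unit_id == "g1"], 2L)
  expect_equal(res$n[res$unit_id == "g2"], 1L)
  expect_equal(res$k[res$unit_id == "g2"], 1L)
})

test_that("region density fold matches direct arithmetic and a random null", {
  regions <- tibble::tibble(chrom = "c1", start = 1L, end = 1000L)
  U <- tibble::tibble(chrom = "c1", pos = c(10L, 20L, 600L, 999L,
                                            2000L, 3000L, 4000L, 5000L,
                                            6000L, 7000L))
  # 10 kb genome, 10 specific positions; 4 inside the 1 kb region -> fold 4
  out <- region_density_fold(regions, U, 10000)
  expect_equal(out$n_specific, 4L)
  expect_equal(out$density_fold, 4)
  empty <- region_density_fold(tibble::tibble(chrom = "c1", start = 8000L,
                                              end = 8999L), U, 10000)
  expect_equal(empty$density_fold, 0)
  expect_error(region_density_fold(tibble::tibble(chrom = "c1", start = 5L,
                                                  end = 4L), U, 10000),
               "length")

  # Monte-Carlo null: mean fold over random regions is ~1
  withr::with_seed(99, {
    upos <- tibble::tibble(chrom = "c1", pos = sample.int(100000, 2000))
    rnd <- tibble::tibble(chrom = "c1",
                          start = sample.int(95000, 400), end = 0L)
    rnd$end <- rnd$start + 4999L
    folds <- region_density_fold(rnd, upos, 100000)$density_fold
    expect_lt(abs(mean(folds) - 1), 0.1)
  })
})

test_that("region intersection counts match a brute double loop", {
  regions <- tibble::tibble(chrom = c("c1", "c1", "c2"),
                            start = c(10L, 50L, 5L), end = c(30L, 80L, 15L),
                            region_id = c("r1", "r2", "r3"))
  U <- tibble::tibble(chrom = c("c1", "c1", "c1", "c2", "c2"),
                      pos = c(10L, 30L, 40L, 15L, 16L))
  ov <- intersect_regions(U, regions)
  brute <- sapply(seq_len(nrow(regions)), function(i) {
    sum(U$chrom == regions$chrom[i] & U$pos >= regions$start[i] &
          U$pos <= regions$end[i])
  })
  expect_equal(ov$counts$n_specific, as.integer(brute))
  # boundary positions are counted (inclusive semantics)
  expect_equal(ov$counts$n_specific[1], 2L)
  empty <- intersect_regions(U, regions[0, ])
  expect_equal(nrow(empty$assignments), 0L)
})
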