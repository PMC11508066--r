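# The synthetic panel generator: construction invariants, determinism, and
# calibration of the planted rates.

test_that("genome generation honours composition, preconditions and seed", {
  expect_error(generate_genome(c(chr1 = 0L), 0.5, 1), "length")
  expect_error(generate_genome(setNames(100L, ""), 0.5, 1), "named")
  expect_error(generate_genome(c(chr1 = 100L), 1.5, 1), "gc_content")

  g <- generate_genome(c(chr1 = 200L), gc_content = 1, seed = 5)
  expect_true(all(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C")))

  g1 <- generate_genome(c(chr1 = 5000L, chr2 = 2000L), 0.42, seed = 7)
  g2 <- generate_genome(c(chr1 = 5000L, chr2 = 2000L), 0.42, seed = 7)
  expect_identical(g1, g2)
  # written FASTA is byte-identical too
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # GC fraction close to target at this length
  gc <- mean(strsplit(g1[["chr1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.42), 0.03)
})

test_that("planted genes are valid coding genes on both strands", {
  cfg <- panel_config(chrom_lengths = c(chr1 = 60000L), n_genes = 12L,
                      cds_length_range = c(300L, 900L), seed = 21)
  genome0 <- generate_genome(cfg$chrom_lengths, cfg$gc_content, cfg$seed)
  pg <- plant_genes(genome0, cfg, cfg$seed)
  gm <- pg$gene_models
  expect_length(unique(gm$gene_id), 12L)
  expect_true(all(c("+", "-") %in% gm$strand))

  for (g in unique(gm$gene_id)) {
    cds <- spliced_cds(pg$genome, gm, g)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(nchar(cds) %% 3, 0)
    # no internal stop
    expect_no_warning(prot <- translate_cds(pg$genome, gm, g))
    expect_false(grepl("*", prot, fixed = TRUE))
    # exons non-overlapping and ordered
    ex <- gm[gm$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) {
      expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    }
  }
})

test_that("gene placement fails loudly when the genome is too crowded", {
  cfg <- panel_config(chrom_lengths = c(chr1 = 5000L), n_genes = 20L,
                      cds_length_range = c(900L, 1500L), seed = 2)
  genome0 <- generate_genome(cfg$chrom_lengths, cfg$gc_content, 2)
  expect_error(plant_genes(genome0, cfg, 2), "could not place")
})

test_that("difference tables are calibrated and consistent with truth", {
  panel <- small_panel(seed = 31, chrom_len = 50000L, n_genes = 8L)
  tr <- panel$truth$sites

  # every truth site appears in the emitted difference tables
  expect_true(all(paste(tr$chrom, tr$pos) %in%
                    paste(panel$diffs$chrom, panel$diffs$pos)))
  # and vice versa: no orphan difference positions
  expect_true(all(paste(panel$diffs$chrom, panel$diffs$pos) %in%
                    paste(tr$chrom, tr$pos)))

  # realized pairwise difference fraction within 3 binomial sd of the target
  L <- sum(nchar(panel$genome))
  d <- panel$config$background_diff_rate
  sd3 <- 3 * sqrt(L * d * (1 - d))
  for (b in unique(panel$diffs$breed)) {
    n_rec <- sum(panel$diffs$breed == b)
    expect_lt(abs(n_rec - L * d), sd3 + 1)
  }

  # focal genome carries the focal allele at every truth site
  got <- vapply(seq_len(nrow(tr)), function(i) {
    substr(panel$genome[[tr$chrom[i]]], tr$pos[i], tr$pos[i])
  }, character(1))
  expect_identical(got, tr$focal_allele)
  # the ancestral allele always differs from the focal one
  expect_true(all(tr$ancestral_allele != tr$focal_allele))
})

test_that("a planted multiplier is realized in the focal-private fraction", {
  # Pool planted counts across seeds and compare the realized inside/outside
  # rate ratio to the configured multiplier via a binomial interval.
  m <- 8
  k_in <- 0; n_in <- 0; k_out <- 0; n_out <- 0
  for (seed in 1:4) {
    cfg <- panel_config(chrom_lengths = c(chr1 = 300000L), n_genes = 60L,
                        n_breeds = 10L, n_private_regions = 0L,
                        cds_length_range = c(900L, 1800L),
                        enriched_units = tibble::tibble(
                          unit_id = "gene0001", multiplier = m, scope = "cds"),
                        seed = seed)
    panel <- simulate_panel(cfg)
    tr <- panel$truth$sites
    inside <- tr$multiplier > 1
    k_in <- k_in + sum(tr$class[inside] == "focal_private")
    n_in <- n_in + sum(inside)
    k_out <- k_out + sum(tr$class[!inside] == "focal_private")
    n_out <- n_out + sum(!inside)
  }
  expect_gt(n_in, 20)
  ratio <- (k_in / n_in) / (k_out / n_out)
  ci <- stats::binom.test(k_in, n_in)$conf.int / (k_out / n_out)
  expect_gt(ratio, 2)          # clearly elevated
  expect_true(ci[1] <= m && m <= ci[2] * 1.2)  # consistent with the target
})

test_that("planted focal-only regions hit composition targets and masks", {
  panel <- small_panel(seed = 41, chrom_len = 30000L, n_genes = 3L,
                       n_private_regions = 2L)
  regs <- panel$truth$regions
  expect_equal(nrow(regs), 2L)
  tgt_t <- panel$config$private_region_tandem
  tgt_g <- panel$config$private_region_g4
  expect_true(all(abs(regs$tandem_fraction_built - tgt_t) <= 0.05))
  expect_true(all(abs(regs$g4_fraction_built - tgt_g) <= 0.05))

  # every breed's mask excludes the planted interval entirely
  for (i in seq_len(nrow(regs))) {
    hit <- panel$masks$chrom == regs$chrom[i] &
      panel$masks$start <= regs$end[i] & panel$masks$end >= regs$start[i]
    expect_equal(sum(hit), 0L)
  }

  # no difference site inside a planted region
  for (i in seq_len(nrow(regs))) {
    expect_equal(sum(panel$diffs$chrom == regs$chrom[i] &
                       panel$diffs$pos >= regs$start[i] &
                       panel$diffs$pos <= regs$end[i]), 0L)
  }
})

test_that("a pure tandem composition gives a perfect array", {
  cfg <- panel_config(chrom_lengths = c(chr1 = 20000L), n_genes = 2L,
                      n_private_regions = 1L,
                      private_region_length_range = c(1000L, 1200L),
                      private_region_tandem = 1, private_region_g4 = 0,
                      seed = 9)
  panel <- simulate_panel(cfg)
  regs <- panel$truth$regions
  expect_equal(regs$tandem_fraction_built, 1)
  expect_error(panel_config(private_region_tandem = 0.9,
                            private_region_g4 = 0.2), "sum")
})

test_that("the generator is deterministic for a fixed config and seed", {
  p1 <- small_panel(seed = 13, n_private_regions = 1L)
  p2 <- small_panel(seed = 13, n_private_regions = 1L)
  expect_identical(p1$genome, p2$genome)
  expect_identical(p1$diffs, p2$diffs)
  expect_identical(p1$masks, p2$masks)
  expect_identical(p1$truth$sites, p2$truth$sites)
  p3 <- small_panel(seed = 14, n_private_regions = 1L)
  expect_false(identical(p1$genome, p3$genome))
})
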