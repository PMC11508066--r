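# Codon-level effect annotation: published-format change strings, strand
# handling, splice windows, window assignment, and the whole-protein
# re-translation oracle.

# One single-exon gene embedded in random flanks; returns genome + exon table.
make_single_gene_genome <- function(cds, strand = "+", flank = 30L,
                                    chrom = "chrT") {
  left <- random_dna(flank); right <- random_dna(flank)
  segment <- if (strand == "-") {
    chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]), collapse = ""))
  } else cds
  genome <- setNames(paste0(left, segment, right), chrom)
  gm <- tibble::tibble(gene_id = "geneX", chrom = chrom, strand = strand,
                       start = flank + 1L, end = flank + nchar(cds),
                       exon_rank = 1L)
  list(genome = genome, gene_models = gm)
}

# CDS of n_codons sense codons (ALA fill) + stop, with substitutions applied.
ala_cds <- function(n_codons, replace = list()) {
  codons <- c("ATG", rep("GCA", n_codons - 1), "TAA")
  for (nm in names(replace)) codons[as.integer(nm)] <- replace[[nm]]
  paste(codons, collapse = "")
}

test_that("codon and amino-acid change strings follow the published format", {
  # focal codon 643 = CTT, panel allele G at its second base -> cgt > ctt
  cds <- ala_cds(1500, replace = list(`643` = "CTT", `1494` = "CGC"))
  fx <- make_single_gene_genome(cds, strand = "+")
  pos643 <- fx$gene_models$start + (643 - 1) * 3 + 1   # codon base 2
  pos1494 <- fx$gene_models$start + (1494 - 1) * 3     # codon base 1
  sites <- tibble::tibble(chrom = "chrT", pos = c(pos643, pos1494),
                          focal_allele = c("T", "C"),
                          ref_allele = c("G", "T"))
  ann <- annotate_effects(sites, fx$gene_models, fx$genome)
  expect_identical(ann$effect_class, rep("NONSYNONYMOUS_SNV", 2))
  expect_identical(ann$codon_change, c("cgt > ctt", "tgc > cgc"))
  expect_identical(ann$aa_change, c("r > l at 643", "c > r at 1494"))
})

test_that("effect classes cover the genetic-code cases", {
  cds <- ala_cds(20, replace = list(`5` = "CGC", `7` = "TGA", `9` = "TAT",
                                    `11` = "TAT"))
  fx <- make_single_gene_genome(cds, strand = "+")
  st <- fx$gene_models$start
  # genomic position of base b of codon i: st + (i-1)*3 + (b-1)
  sites <- tibble::tibble(
    chrom = "chrT",
    pos = st + c((5 - 1) * 3 + 2,   # codon 5 base 3: cgt > cgc synonymous
                 (7 - 1) * 3 + 2,   # codon 7 base 3: tgc > tga stop gained
                 (9 - 1) * 3 + 0,   # codon 9 base 1: cat > tat missense
                 (11 - 1) * 3 + 2), # codon 11 base 3: tag > tat stop lost
    focal_allele = c("C", "A", "T", "T"),
    ref_allele = c("T", "C", "C", "G"))
  ann <- annotate_effects(sites, fx$gene_models, fx$genome)
  expect_identical(ann$effect_class,
                   c("SYNONYMOUS_SNV", "STOPGAIN", "NONSYNONYMOUS_SNV",
                     "STOPLOSS"))
  expect_identical(ann$codon_change[1:2], c("cgt > cgc", "tgc > tga"))
  expect_identical(ann$codon_change[3:4], c("cat > tat", "tag > tat"))
  # merged mode folds stop classes into missense
  ann2 <- annotate_effects(sites, fx$gene_models, fx$genome,
                           merge_stop_classes = TRUE)
  expect_identical(ann2$effect_class[c(2, 4)], rep("NONSYNONYMOUS_SNV", 2))
})

test_that("annotation is invariant under strand placement", {
  cds <- ala_cds(100, replace = list(`43` = "CTT"))
  pos_in_cds <- (43 - 1) * 3 + 2
  for (strand in c("+", "-")) {
    fx <- make_single_gene_genome(cds, strand = strand)
    gpos <- if (strand == "+") {
      fx$gene_models$start + pos_in_cds - 1L
    } else {
      fx$gene_models$end - pos_in_cds + 1L
    }
    focal <- if (strand == "+") "T" else "A"
    ref <- if (strand == "+") "G" else "C"
    ann <- annotate_effects(
      tibble::tibble(chrom = "chrT", pos = gpos, focal_allele = focal,
                     ref_allele = ref),
      fx$gene_models, fx$genome)
    expect_identical(ann$effect_class, "NONSYNONYMOUS_SNV")
    expect_identical(ann$aa_change, "r > l at 43")
  }
})

test_that("translate_cds handles both strands and flags internal stops", {
  fx <- make_single_gene_genome("ATGCGTTAA", strand = "+")
  expect_identical(translate_cds(fx$genome, fx$gene_models, "geneX"), "MR")
  fxm <- make_single_gene_genome("ATGCGTTAA", strand = "-")
  expect_identical(translate_cds(fxm$genome, fxm$gene_models, "geneX"), "MR")
  fxs <- make_single_gene_genome("ATGTAACGTTAA", strand = "+")
  expect_warning(translate_cds(fxs$genome, fxs$gene_models, "geneX"),
                 "internal stop")
})

test_that("gene windows use inclusive boundaries and allow multiplicity", {
  gm <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
    start = c(20000L, 32000L), end = c(25000L, 36000L), exon_rank = 1L)
  # 5,000 bp upstream of g1 -> inside its window
  w <- assign_gene_windows(tibble::tibble(chrom = "c1", pos = 15000L), gm)
  expect_identical(w$gene_id, "g1")
  # 10,001 bp upstream -> outside
  w2 <- assign_gene_windows(tibble::tibble(chrom = "c1", pos = 9999L), gm)
  expect_equal(nrow(w2), 0L)
  # exactly 10,000 bp upstream -> inside (inclusive)
  w3 <- assign_gene_windows(tibble::tibble(chrom = "c1", pos = 10000L), gm)
  expect_identical(w3$gene_id, "g1")
  # a position in two overlapping windows reports both genes
  w4 <- assign_gene_windows(tibble::tibble(chrom = "c1", pos = 28000L), gm)
  expect_setequal(w4$gene_id, c("g1", "g2"))
})

test_that("splice-site and intronic classes respect the 2 bp window", {
  # two-exon gene: exon1 31..60, intron 61..160, exon2 161..220
  genome <- setNames(random_dna(260), "c1")
  cds <- ala_cds(29)  # 90 bp
  seg <- paste0(substr(cds, 1, 30),
                paste0("GT", random_dna(96), "AG"),
                substr(cds, 31, 90))
  genome["c1"] <- paste0(substr(genome["c1"], 1, 30), seg,
                         substr(genome["c1"], 221, 260))
  gm <- tibble::tibble(gene_id = "gS", chrom = "c1", strand = "+",
                       start = c(31L, 161L), end = c(60L, 220L),
                       exon_rank = c(1L, 2L))
  probe <- function(pos) {
    fa <- substr(genome[["c1"]], pos, pos)
    ref <- setdiff(c("A", "C", "G", "T"), fa)[1]
    annotate_effects(tibble::tibble(chrom = "c1", pos = pos,
                                    focal_allele = fa, ref_allele = ref),
                     gm, genome)$effect_class
  }
  expect_identical(probe(61L), "SPLICE_SITE_VARIANT")   # donor +1
  expect_identical(probe(62L), "SPLICE_SITE_VARIANT")   # donor +2
  expect_identical(probe(63L), "INTRONIC")
  expect_identical(probe(159L), "SPLICE_SITE_VARIANT")  # acceptor -2
  expect_identical(probe(158L), "INTRONIC")
  expect_identical(probe(10L), "FLANK_10KB")
  expect_true(probe(45L) %in% c("SYNONYMOUS_SNV", "NONSYNONYMOUS_SNV",
                                "STOPGAIN", "STOPLOSS"))
})

test_that("every site gets exactly one class per gene and mismatches drop", {
  panel <- small_panel(seed = 51, chrom_len = 40000L, n_genes = 6L)
  calls <- classify_focal_specific(panel$diffs, panel$masks)
  s <- calls[calls$reason != "INSUFFICIENT_PRESENCE",
             c("chrom", "pos", "focal_allele")]
  ann <- annotate_effects(s, panel$gene_models, panel$genome,
                          diffs = panel$diffs)
  # partition: one row per (site, gene) incl. the NA-gene intergenic rows
  expect_equal(nrow(dplyr::distinct(ann, chrom, pos, gene_id)), nrow(ann))
  expect_true(all(table(paste(ann$chrom, ann$pos)) >= 1))
  expect_true(all(ann$effect_class %in%
                    c("NONSYNONYMOUS_SNV", "SYNONYMOUS_SNV", "STOPGAIN",
                      "STOPLOSS", "SPLICE_SITE_VARIANT", "INTRONIC",
                      "FLANK_10KB", "INTERGENIC")))
  coding <- ann[!is.na(ann$aa_pos), ]
  expect_true(all(!is.na(coding$codon_change) & !is.na(coding$aa_change)))

  # a corrupted focal allele is dropped with a warning
  s_bad <- s
  s_bad$focal_allele[1] <- setdiff(c("A", "C", "G", "T"),
                                   s$focal_allele[1])[1]
  expect_warning(
    ann_bad <- annotate_effects(s_bad, panel$gene_models, panel$genome,
                                diffs = panel$diffs),
    "dropped")
  expect_equal(attr(ann_bad, "n_dropped_ref_mismatch"), 1L)
})

test_that("codon annotation agrees with whole-protein re-translation", {
  # The generator's truth effects are produced by translating the entire
  # mutant CDS and diffing proteins -- an independent route from the
  # single-codon reconstruction in annotate_effects().
  panel <- small_panel(seed = 61, chrom_len = 50000L, n_genes = 8L)
  tr_eff <- panel$truth$coding_effects
  expect_gt(nrow(tr_eff), 5)
  sites <- panel$truth$sites[, c("chrom", "pos", "focal_allele",
                                 "ancestral_allele")]
  names(sites)[4] <- "ref_allele"
  ann <- annotate_effects(sites, panel$gene_models, panel$genome)
  merged <- dplyr::inner_join(
    ann[!is.na(ann$gene_id) & !is.na(ann$aa_pos), ],
    tr_eff, by = c("chrom", "pos", "gene_id"), suffix = c("", ".truth"))
  expect_equal(nrow(merged), nrow(tr_eff))
  expect_identical(merged$effect_class, merged$effect_class.truth)
  expect_identical(merged$aa_pos, merged$aa_pos.truth)
  # amino-acid letters match the diffed proteins
  nonsyn <- merged[merged$effect_class == "NONSYNONYMOUS_SNV", ]
  expect_identical(nonsyn$aa_change,
                   paste(tolower(nonsyn$ref_aa), ">", tolower(nonsyn$alt_aa),
                         "at", nonsyn$aa_pos))
})
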