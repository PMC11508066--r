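# Codon-level effect annotation of difference sites against gene models.
# The annotated genome is the focal assembly, so the genome codon is the ALT
# (focal) codon; the REF codon substitutes the comparison-panel allele. Codon
# and amino-acid change strings are lowercase, e.g. "cgt > ctt" and
# "r > l at 643".

EFFECT_CLASSES <- c("NONSYNONYMOUS_SNV", "SYNONYMOUS_SNV", "STOPGAIN",
                    "STOPLOSS", "SPLICE_SITE_VARIANT", "INTRONIC",
                    "FLANK_10KB", "INTERGENIC")

# Panel consensus allele at each site: the majority allele among covered
# differing breeds, alphabetical tie-break.
panel_ref_alleles <- function(diffs) {
  diffs |>
    count(.data$chrom, .data$pos, .data$breed_allele) |>
    arrange(.data$chrom, .data$pos, dplyr::desc(.data$n), .data$breed_allele) |>
    group_by(.data$chrom, .data$pos) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("chrom", "pos", ref_allele = "breed_allele")
}

#' Assign sites to gene +/- flank windows
#'
#' Returns every (site, gene) pair where the position lies within the gene
#' span extended by `flank` on both sides; a site may match zero, one or
#' several genes.
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param gene_models Exon tibble (see [plant_genes()]).
#' @param flank Flank size in bp (default 10000).
#' @return Tibble `chrom`, `pos`, `gene_id`.
#' @export
assign_gene_windows <- function(sites, gene_models, flank = 10000L) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  spans <- gene_spans(gene_models) |>
    mutate(start = pmax(1L, .data$start - as.integer(flank)),
           end = .data$end + as.integer(flank))
  hits <- GenomicRanges::findOverlaps(positions_to_gr(sites),
                                      intervals_to_gr(spans))
  tibble(chrom = sites$chrom[S4Vectors::queryHits(hits)],
         pos = sites$pos[S4Vectors::queryHits(hits)],
         gene_id = spans$gene_id[S4Vectors::subjectHits(hits)]) |>
    arrange(.data$chrom, .data$pos, .data$gene_id)
}

#' Annotate the coding effect of difference sites
#'
#' For each site inside a CDS exon, reconstructs the containing codon in
#' transcript orientation (reverse complement on the minus strand),
#' substitutes the panel reference allele to obtain the REF codon, and
#' translates both codons with the standard genetic code. Sites within
#' `splice_window` intronic bases of an exon/intron junction are splice-site
#' variants; remaining sites are intronic, within a gene +/- `flank` window,
#' or intergenic. A site overlapping the CDS of two genes is annotated once
#' per gene.
#'
#' @param sites Tibble with `chrom`, `pos`, `focal_allele` and either a
#'   `ref_allele` column or the long difference table's `breed_allele`
#'   records from which the panel consensus is taken (see `diffs`).
#' @param gene_models Exon tibble (see [plant_genes()]).
#' @param genome Named character vector of focal chromosome sequences.
#' @param diffs Optional difference tibble used to derive the panel reference
#'   allele when `sites` has no `ref_allele` column.
#' @param flank Window size for the FLANK_10KB class (default 10000).
#' @param splice_window Intronic bases adjacent to each exon boundary called
#'   as splice-site variants (default 2, the canonical donor/acceptor).
#' @param merge_stop_classes When `TRUE`, STOPGAIN/STOPLOSS are relabelled
#'   NONSYNONYMOUS_SNV (off by default: enrichment counts missense only).
#' @return Tibble with one row per (site, gene) pair — sites outside every
#'   gene get a single row with `gene_id` NA — and columns `chrom`, `pos`,
#'   `focal_allele`, `ref_allele`, `gene_id`, `effect_class`, `codon_change`,
#'   `aa_change`, `aa_pos`. Sites whose focal allele disagrees with the
#'   genome sequence are dropped with a warning (count in attribute
#'   `n_dropped_ref_mismatch`).
#' @export
annotate_effects <- function(sites, gene_models, genome, diffs = NULL,
                             flank = 10000L, splice_window = 2L,
                             merge_stop_classes = FALSE) {
  assert_genome(genome)
  sites <- as_tibble(sites)
  if (!"ref_allele" %in% names(sites)) {
    if (is.null(diffs)) {
      stop("provide `ref_allele` in `sites` or pass `diffs` to derive it",
           call. = FALSE)
    }
    sites <- sites |>
      left_join(panel_ref_alleles(diffs), by = c("chrom", "pos"))
  }
  bad_chrom <- setdiff(unique(sites$chrom), names(genome))
  if (length(bad_chrom) > 0) {
    stop("unknown chromosome(s): ", paste(bad_chrom, collapse = ", "),
         call. = FALSE)
  }

  # Consistency: the focal genome must carry the focal allele.
  genome_base <- character(nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    raw_chr <- charToRaw(genome[[chr]])
    genome_base[idx] <- strsplit(rawToChar(raw_chr[sites$pos[idx]]), "",
                                 fixed = TRUE)[[1]]
  }
  mism <- genome_base != sites$focal_allele
  if (any(mism)) {
    warning(sum(mism), " site(s) dropped: focal allele disagrees with the ",
            "genome sequence", call. = FALSE)
  }
  sites <- sites[!mism, ]
  n_mismatch <- sum(mism)
  if (nrow(sites) == 0) {
    out <- tibble(chrom = character(), pos = integer(),
                  focal_allele = character(), ref_allele = character(),
                  gene_id = character(), effect_class = character(),
                  codon_change = character(), aa_change = character(),
                  aa_pos = integer())
    attr(out, "n_dropped_ref_mismatch") <- n_mismatch
    return(out)
  }

  exmap <- gene_models |>
    arrange(.data$gene_id, .data$exon_rank) |>
    group_by(.data$gene_id) |>
    mutate(w = .data$end - .data$start + 1L,
           toff = cumsum(.data$w) - .data$w,
           cds_len = sum(.data$w)) |>
    ungroup()
  if (any(exmap$cds_len %% 3 != 0)) {
    bad <- unique(exmap$gene_id[exmap$cds_len %% 3 != 0])
    stop("CDS length not divisible by 3 for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  spans <- gene_spans(gene_models)
  site_gr <- positions_to_gr(sites)

  # --- coding sites ----------------------------------------------------
  cds_hits <- GenomicRanges::findOverlaps(site_gr, intervals_to_gr(exmap))
  si <- S4Vectors::queryHits(cds_hits)
  ei <- S4Vectors::subjectHits(cds_hits)
  coding <- NULL
  if (length(si) > 0) {
    cds_cache <- spliced_cds_all(genome, gene_models,
                                 unique(exmap$gene_id[ei]))
    strand <- exmap$strand[ei]
    tpos <- ifelse(strand == "+",
                   exmap$toff[ei] + sites$pos[si] - exmap$start[ei] + 1L,
                   exmap$toff[ei] + exmap$end[ei] - sites$pos[si] + 1L)
    ci <- (tpos - 1L) %/% 3L + 1L
    within <- (tpos - 1L) %% 3L + 1L
    alt_codon <- substr(cds_cache[exmap$gene_id[ei]], 3 * ci - 2, 3 * ci)
    ref_t <- ifelse(strand == "+", sites$ref_allele[si],
                    unname(COMPLEMENT[sites$ref_allele[si]]))
    ref_codon <- vapply(seq_along(si), function(r) {
      replace_bases(alt_codon[r], within[r], ref_t[r])
    }, character(1))
    ref_aa <- translate_codons(ref_codon)
    alt_aa <- translate_codons(alt_codon)
    effect <- dplyr::case_when(
      ref_aa == alt_aa ~ "SYNONYMOUS_SNV",
      alt_aa == "*" ~ "STOPGAIN",
      ref_aa == "*" ~ "STOPLOSS",
      TRUE ~ "NONSYNONYMOUS_SNV"
    )
    if (merge_stop_classes) {
      effect[effect %in% c("STOPGAIN", "STOPLOSS")] <- "NONSYNONYMOUS_SNV"
    }
    coding <- tibble(
      chrom = sites$chrom[si], pos = sites$pos[si],
      focal_allele = sites$focal_allele[si], ref_allele = sites$ref_allele[si],
      gene_id = exmap$gene_id[ei],
      effect_class = effect,
      codon_change = paste(tolower(ref_codon), ">", tolower(alt_codon)),
      aa_change = paste(tolower(ref_aa), ">", tolower(alt_aa), "at", ci),
      aa_pos = as.integer(ci)
    )
  }

  # --- splice-site / intronic sites ------------------------------------
  # Splice windows: `splice_window` intronic bases beyond each internal exon
  # boundary (terminal gene bounds excluded).
  sp_rows <- exmap |>
    group_by(.data$gene_id) |>
    mutate(gstart = min(.data$start), gend = max(.data$end)) |>
    ungroup()
  splice_iv <- bind_rows(
    sp_rows |> filter(.data$start > .data$gstart) |>
      mutate(s = .data$start - as.integer(splice_window), e = .data$start - 1L) |>
      select("gene_id", "chrom", start = "s", end = "e"),
    sp_rows |> filter(.data$end < .data$gend) |>
      mutate(s = .data$end + 1L, e = .data$end + as.integer(splice_window)) |>
      select("gene_id", "chrom", start = "s", end = "e")
  )
  in_cds_pair <- paste(sites$chrom[si], sites$pos[si], exmap$gene_id[ei])

  gene_hits <- GenomicRanges::findOverlaps(site_gr, intervals_to_gr(spans))
  gi <- S4Vectors::queryHits(gene_hits)
  gg <- S4Vectors::subjectHits(gene_hits)
  noncoding <- NULL
  if (length(gi) > 0) {
    pair_id <- paste(sites$chrom[gi], sites$pos[gi], spans$gene_id[gg])
    keep <- !(pair_id %in% in_cds_pair)
    gi <- gi[keep]; gg <- gg[keep]
  }
  if (length(gi) > 0) {
    in_splice <- rep(FALSE, length(gi))
    if (nrow(splice_iv) > 0) {
      sp_gr <- intervals_to_gr(splice_iv)
      h <- GenomicRanges::findOverlaps(positions_to_gr(sites[gi, ]), sp_gr)
      # Splice assignment is per gene: the window must belong to the same gene.
      same_gene <- spans$gene_id[gg][S4Vectors::queryHits(h)] ==
        splice_iv$gene_id[S4Vectors::subjectHits(h)]
      in_splice[unique(S4Vectors::queryHits(h)[same_gene])] <- TRUE
    }
    noncoding <- tibble(
      chrom = sites$chrom[gi], pos = sites$pos[gi],
      focal_allele = sites$focal_allele[gi], ref_allele = sites$ref_allele[gi],
      gene_id = spans$gene_id[gg],
      effect_class = ifelse(in_splice, "SPLICE_SITE_VARIANT", "INTRONIC"),
      codon_change = NA_character_, aa_change = NA_character_,
      aa_pos = NA_integer_
    )
  }

  # --- flank / intergenic ----------------------------------------------
  in_gene_idx <- unique(c(si, gi))
  rest_idx <- setdiff(seq_len(nrow(sites)), in_gene_idx)
  rest <- NULL
  if (length(rest_idx) > 0) {
    win <- assign_gene_windows(sites[rest_idx, ], gene_models, flank = flank)
    in_flank <- paste(sites$chrom[rest_idx], sites$pos[rest_idx]) %in%
      paste(win$chrom, win$pos)
    rest <- tibble(
      chrom = sites$chrom[rest_idx], pos = sites$pos[rest_idx],
      focal_allele = sites$focal_allele[rest_idx],
      ref_allele = sites$ref_allele[rest_idx],
      gene_id = NA_character_,
      effect_class = ifelse(in_flank, "FLANK_10KB", "INTERGENIC"),
      codon_change = NA_character_, aa_change = NA_character_,
      aa_pos = NA_integer_
    )
  }

  out <- bind_rows(coding, noncoding, rest) |>
    arrange(.data$chrom, .data$pos, .data$gene_id)
  attr(out, "n_dropped_ref_mismatch") <- n_mismatch
  out
}
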