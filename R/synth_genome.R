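#' Generate a random ancestral genome
#'
#' Draws i.i.d. bases with the requested GC content, split evenly between G
#' and C (and between A and T). Deterministic for a fixed seed.
#'
#' @param chrom_lengths Named integer vector, chromosome name -> length (bp).
#' @param gc_content GC fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @examples
#' g <- generate_genome(c(chr1 = 100), gc_content = 1, seed = 7)
#' unique(strsplit(g[["chr1"]], "")[[1]])
#' @export
generate_genome <- function(chrom_lengths, gc_content, seed) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1", call. = FALSE)
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  }
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  withr::with_seed(child_seed(seed, "genome"), {
    vapply(names(chrom_lengths), function(chr) {
      paste(sample(names(probs), chrom_lengths[[chr]], replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- {
  all_codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all_codons, STOP_CODONS)
}

# Build one random CDS: ATG + sense codons + stop. Length must be a multiple
# of 3 and >= 9 so there is at least one internal codon.
random_cds <- function(cds_len) {
  stopifnot(cds_len %% 3 == 0, cds_len >= 9)
  n_internal <- cds_len / 3 - 2
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_internal, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

# Random intron with canonical GT...AG dinucleotides.
random_intron <- function(len) {
  stopifnot(len >= 10)
  body <- paste(sample(BASES, len - 4, replace = TRUE), collapse = "")
  paste0("GT", body, "AG")
}

#' Plant multi-exon protein-coding genes into a genome
#'
#' Writes non-overlapping, randomly placed gene loci into the genome. Each
#' gene has an ATG start, a single terminal stop, no in-frame internal stop,
#' canonical GT/AG intron boundaries, and ordered non-overlapping CDS exons;
#' about half of the genes land on the minus strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param config A [panel_config()].
#' @param seed Integer seed.
#' @param forbidden Optional tibble (`chrom`, `start`, `end`, 1-based
#'   inclusive) of intervals genes must not touch.
#' @return List with elements `genome` (edited sequences) and `gene_models`,
#'   a tibble of CDS exons with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank` (rank 1 is the 5'-most exon in transcript
#'   orientation).
#' @export
plant_genes <- function(genome, config, seed, forbidden = NULL) {
  assert_genome(genome)
  lens <- genome_lengths(genome)
  chars <- lapply(genome, seq_chars)
  placed <- lapply(names(genome), function(x) cbind(start = numeric(0), end = numeric(0)))
  names(placed) <- names(genome)
  if (!is.null(forbidden) && nrow(forbidden) > 0) {
    for (i in seq_len(nrow(forbidden))) {
      chr <- forbidden$chrom[i]
      placed[[chr]] <- rbind(placed[[chr]],
                             c(forbidden$start[i], forbidden$end[i]))
    }
  }
  exon_rows <- vector("list", config$n_genes)
  withr::with_seed(child_seed(seed, "genes"), {
    for (g in seq_len(config$n_genes)) {
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      len_choices <- seq(max(config$cds_length_range[1], 3 * n_ex + 9),
                         config$cds_length_range[2], by = 3)
      cds_len <- sample(len_choices, 1)
      # Split the CDS into n_ex exon pieces of >= 3 bp each.
      extra <- if (cds_len - 3 * n_ex > 0) {
        as.vector(stats::rmultinom(1, cds_len - 3 * n_ex, rep(1, n_ex)))
      } else rep(0L, n_ex)
      exon_lens <- 3L + extra
      intron_lens <- if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE) else integer(0)
      span <- cds_len + sum(intron_lens)
      strand <- sample(c("+", "-"), 1)

      cds <- random_cds(cds_len)
      pieces <- character(2 * n_ex - 1)
      off <- 0L
      t_starts <- integer(n_ex); t_ends <- integer(n_ex)
      tpos <- 0L
      for (e in seq_len(n_ex)) {
        piece <- substr(cds, off + 1, off + exon_lens[e])
        off <- off + exon_lens[e]
        pieces[2 * e - 1] <- piece
        t_starts[e] <- tpos + 1L
        tpos <- tpos + exon_lens[e]
        t_ends[e] <- tpos
        if (e < n_ex) {
          pieces[2 * e] <- random_intron(intron_lens[e])
          tpos <- tpos + intron_lens[e]
        }
      }
      segment <- paste(pieces, collapse = "")
      if (strand == "-") segment <- revcomp(segment)

      # Place: bounded rejection sampling against occupied intervals.
      ok <- FALSE
      for (try in seq_len(500)) {
        chr <- sample(names(genome), 1, prob = lens)
        if (lens[[chr]] < span + 2) next
        gstart <- sample.int(lens[[chr]] - span - 1, 1) + 1L
        gend <- gstart + span - 1L
        occ <- placed[[chr]]
        if (nrow(occ) == 0 || !any(occ[, "start"] <= gend + 1 & occ[, "end"] >= gstart - 1)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place gene ", g, " without overlap; ",
             "reduce n_genes or enlarge the genome", call. = FALSE)
      }
      placed[[chr]] <- rbind(placed[[chr]], c(gstart, gend))
      chars[[chr]][gstart:gend] <- seq_chars(segment)

      # Map transcript-orientation exon offsets to genomic coordinates.
      if (strand == "+") {
        e_start <- gstart + t_starts - 1L
        e_end <- gstart + t_ends - 1L
      } else {
        e_start <- gstart + span - t_ends
        e_end <- gstart + span - t_starts
      }
      exon_rows[[g]] <- tibble(
        gene_id = sprintf("gene%04d", g),
        chrom = chr, strand = strand,
        start = as.integer(e_start), end = as.integer(e_end),
        exon_rank = seq_len(n_ex)
      )
    }
  })
  genome_out <- vapply(chars, paste, character(1), collapse = "")
  names(genome_out) <- names(genome)
  list(genome = genome_out, gene_models = bind_rows(exon_rows))
}

# Gene-level spans derived from the exon table.
gene_spans <- function(gene_models) {
  gene_models |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

# Spliced, strand-corrected CDS of every requested gene in one pass.
spliced_cds_all <- function(genome, gene_models, gene_ids = NULL) {
  gm <- gene_models |> arrange(.data$gene_id, .data$exon_rank)
  if (!is.null(gene_ids)) gm <- gm |> filter(.data$gene_id %in% gene_ids)
  pieces <- substring(unname(genome[gm$chrom]), gm$start, gm$end)
  minus <- gm$strand == "-"
  pieces[minus] <- revcomp(pieces[minus])
  vapply(split(pieces, gm$gene_id), paste, character(1), collapse = "")
}

#' Extract the spliced, strand-corrected CDS of a gene
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gene_models Exon tibble as produced by [plant_genes()].
#' @param gene_id Gene identifier.
#' @return The CDS sequence 5'->3' as a character scalar.
#' @export
spliced_cds <- function(genome, gene_models, gene_id) {
  ex <- gene_models |> filter(.data$gene_id == .env$gene_id)
  if (nrow(ex) == 0) stop("unknown gene: ", gene_id, call. = FALSE)
  ex <- ex |> arrange(.data$exon_rank)
  chrom_seq <- genome[[ex$chrom[1]]]
  pieces <- substring(chrom_seq, ex$start, ex$end)
  if (ex$strand[1] == "-") {
    paste(revcomp(pieces), collapse = "")
  } else {
    paste(pieces, collapse = "")
  }
}

#' Translate the CDS of a gene model
#'
#' Standard-code translation of the spliced, strand-corrected CDS; the
#' terminal stop is stripped. An internal stop raises a warning (it can arise
#' legitimately once focal-branch substitutions are applied to a genome).
#'
#' @inheritParams spliced_cds
#' @return Protein string (single-letter, uppercase).
#' @export
translate_cds <- function(genome, gene_models, gene_id) {
  cds <- spliced_cds(genome, gene_models, gene_id)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length of ", gene_id, " is not a multiple of 3", call. = FALSE)
  }
  codons <- substring(cds, seq(1, nchar(cds), by = 3), seq(3, nchar(cds), by = 3))
  aa <- translate_codons(codons)
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    warning("internal stop codon in ", gene_id, call. = FALSE)
  }
  paste(aa, collapse = "")
}
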