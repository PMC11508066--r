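# File-format boundaries. External conventions: FASTA wrapped at 80 columns;
# GFF3 1-based inclusive with phase; BED 0-based half-open; TSV dialects with
# header lines. Internally everything is 1-based inclusive tibbles.

#' Write / read a genome FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly (writer); named character vector (reader).
#' @export
write_genome_fasta <- function(genome, path) {
  assert_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 80L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / CDS records (one transcript per gene) with correct CDS
#' phase; 1-based inclusive per the GFF3 specification.
#'
#' @param gene_models Exon tibble (see [plant_genes()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  spans <- gene_spans(gene_models)
  for (i in seq_len(nrow(spans))) {
    g <- spans$gene_id[i]
    writeLines(sprintf("%s\tfocalvar\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       spans$chrom[i], spans$start[i], spans$end[i],
                       spans$strand[i], g), con)
    writeLines(sprintf("%s\tfocalvar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       spans$chrom[i], spans$start[i], spans$end[i],
                       spans$strand[i], g, g), con)
    ex <- gene_models |> filter(.data$gene_id == g) |> arrange(.data$exon_rank)
    cum <- cumsum(c(0L, ex$end - ex$start + 1L))[seq_len(nrow(ex))]
    phase <- (3L - cum %% 3L) %% 3L
    for (e in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tfocalvar\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
                         ex$chrom[e], ex$start[e], ex$end[e], ex$strand[e],
                         phase[e], g, g), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports CDS features (via rtracklayer) and reconstructs the exon tibble;
#' exon rank follows transcript orientation (reverse coordinate order on the
#' minus strand). The stored phase column is checked against the
#' by-construction phase implied by the exon order.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @return Exon tibble (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exon_rank`).
#' @export
read_gene_models_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", path, call. = FALSE)
  parent <- vapply(as.list(cds$Parent), function(p) p[1], character(1))
  df <- tibble(
    gene_id = sub("\\.t1$", "", parent),
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    phase = as.integer(as.character(cds$phase))
  )
  out <- df |>
    group_by(.data$gene_id) |>
    arrange(ifelse(.data$strand == "+", .data$start, -.data$start),
            .by_group = TRUE) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup()
  # Phase check: first CDS base must open a codon.
  chk <- out |>
    group_by(.data$gene_id) |>
    arrange(.data$exon_rank, .by_group = TRUE) |>
    mutate(cum = cumsum(c(0L, (.data$end - .data$start + 1L)[-dplyr::n()])),
           expect = (3L - .data$cum %% 3L) %% 3L) |>
    ungroup()
  if (any(!is.na(chk$phase) & chk$phase != chk$expect)) {
    warning("GFF3 phase column disagrees with exon order for some CDS",
            call. = FALSE)
  }
  out |>
    select("gene_id", "chrom", "strand", "start", "end", "exon_rank") |>
    arrange(.data$gene_id, .data$exon_rank)
}

#' Write / read coverage masks as per-breed BED files
#'
#' BED is 0-based half-open; the internal tibbles are 1-based inclusive.
#'
#' @param masks Mask tibble (`breed`, `chrom`, `start`, `end`).
#' @param dir Directory for `mask_<breed>.bed` files.
#' @return File paths, invisibly (writer); mask tibble (reader).
#' @export
write_masks_bed <- function(masks, dir) {
  paths <- vapply(sort(unique(masks$breed)), function(b) {
    p <- file.path(dir, paste0("mask_", b, ".bed"))
    df <- masks |> filter(.data$breed == b) |>
      arrange(.data$chrom, .data$start) |>
      mutate(start0 = .data$start - 1L) |>
      select("chrom", "start0", "end")
    readr::write_tsv(df, p, col_names = FALSE, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_masks_bed
#' @export
read_masks_bed <- function(dir) {
  files <- sort(list.files(dir, pattern = "^mask_.*\\.bed$", full.names = TRUE))
  if (length(files) == 0) stop("no mask_*.bed files in ", dir, call. = FALSE)
  bind_rows(lapply(files, function(f) {
    breed <- sub("^mask_(.*)\\.bed$", "\\1", basename(f))
    read_bed(f) |> mutate(breed = breed) |>
      select("breed", "chrom", "start", "end")
  }))
}

#' Read a BED file of intervals
#'
#' @param path BED file (0-based half-open); converted to 1-based inclusive.
#' @return Tibble `chrom`, `start`, `end` (plus `region_id` if a name column
#'   is present).
#' @export
read_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) {
      stop("malformed BED file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  out <- gr_to_intervals(gr)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$region_id <- nm
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble `chrom`, `start`, `end` (1-based inclusive),
#'   optional `region_id` written as the name column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals |> mutate(start0 = .data$start - 1L)
  cols <- c("chrom", "start0", "end")
  if ("region_id" %in% names(intervals)) cols <- c(cols, "region_id")
  readr::write_tsv(df[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write / read per-breed difference tables
#'
#' One TSV per breed (`diff_<breed>.tsv`) with header
#' `chrom pos focal_allele breed_allele`; a record means the breed differs
#' from the focal genome at that (covered) position, and absence of a record
#' at a covered position means the breed matches the focal allele.
#'
#' @param diffs Difference tibble (`chrom`, `pos`, `focal_allele`, `breed`,
#'   `breed_allele`).
#' @param dir Directory for the per-breed files.
#' @return File paths, invisibly (writer); combined tibble (reader).
#' @export
write_diff_tables <- function(diffs, dir) {
  paths <- vapply(sort(unique(diffs$breed)), function(b) {
    p <- file.path(dir, paste0("diff_", b, ".tsv"))
    df <- diffs |> filter(.data$breed == b) |>
      arrange(.data$chrom, .data$pos) |>
      select("chrom", "pos", "focal_allele", "breed_allele")
    readr::write_tsv(df, p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_diff_tables
#' @export
read_diff_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "^diff_.*\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no diff_*.tsv files in ", dir, call. = FALSE)
  bind_rows(lapply(files, function(f) {
    breed <- sub("^diff_(.*)\\.tsv$", "\\1", basename(f))
    readr::read_tsv(f, col_types = "cicc", progress = FALSE) |>
      mutate(breed = breed) |>
      select("chrom", "pos", "focal_allele", "breed", "breed_allele")
  }))
}

#' Write / read the gene -> GO table
#'
#' @param go_table Tibble `gene_id`, `go_id`, `go_name`.
#' @param path TSV file.
#' @return `path`, invisibly (writer); tibble (reader).
#' @export
write_go_table <- function(go_table, path) {
  readr::write_tsv(go_table |> arrange(.data$gene_id, .data$go_id), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_go_table
#' @export
read_go_table <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Export focal-specific variants as a minimal VCF
#'
#' Interoperability export of the set U: the panel consensus allele is the
#' REF column and the focal allele the ALT.
#'
#' @param calls Specificity calls (see [classify_focal_specific()]).
#' @param diffs Difference tibble (for the panel reference allele).
#' @param path Output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_specific_vcf <- function(calls, diffs, path) {
  u <- calls |> filter(.data$is_focal_specific) |>
    left_join(panel_ref_alleles(diffs), by = c("chrom", "pos"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=NCOV,Number=1,Type=Integer,Description=\"Covering comparison breeds\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(u) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNCOV=%d",
                       u$chrom, u$pos, u$ref_allele, u$focal_allele,
                       u$n_covering), con)
  }
  invisible(path)
}
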