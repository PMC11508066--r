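# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Derive a child RNG seed from a master seed and a stream label; keeps every
# source of randomness traceable to one user-supplied seed without touching
# the global RNG state outside withr::with_seed().
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587L)
}

# Reverse complement of a plain character scalar (ACGTN alphabet).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Replace single bases at 1-based positions in a sequence string.
replace_bases <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  ch <- seq_chars(seq)
  ch[pos] <- base
  paste(ch, collapse = "")
}

# Convert a tibble of 1-based inclusive intervals into a GRanges.
intervals_to_gr <- function(df, chrom = "chrom", start = "start", end = "end") {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]], end = df[[end]])
  )
}

# Convert positions (chrom, pos) to a width-1 GRanges.
positions_to_gr <- function(df) {
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1)
  )
}

gr_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

# Genome container: named character vector (chromosome name -> sequence).
genome_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

assert_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    stop("`genome` must be a named character vector of chromosome sequences",
         call. = FALSE)
  }
  invisible(genome)
}

# The standard genetic code keyed by uppercase codon; "*" marks stop.
GENETIC_CODE_1 <- {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_codons <- function(codons) {
  aa <- GENETIC_CODE_1[toupper(codons)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}
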