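# Long focal-only genomic regions and their sequence content. Regions are
# defined purely from coverage masks (maximal intervals covered by zero
# comparison breeds); sequence content (perfect tandem arrays, G-quadruplex
# motifs) is profiled afterwards. Both content fractions use union-of-match
# coverage, so they are bounded by 1 and a base may count in both.

#' Find maximal focal-only regions from coverage masks
#'
#' Reports every maximal interval covered by zero comparison breeds whose
#' length reaches `min_length`. Maximality: no reported interval can be
#' extended in either direction without touching some breed's mask.
#'
#' @param masks Coverage-mask tibble (`breed`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param min_length Minimum region length in bp (default 1000).
#' @param breeds Full comparison panel; defaults to the breeds in `masks`. A
#'   declared breed with no mask rows is an error (its coverage is unknown,
#'   not empty).
#' @return Tibble `chrom`, `start`, `end`, `length`, sorted, pairwise
#'   disjoint.
#' @export
find_specific_regions <- function(masks, chrom_lengths, min_length = 1000L,
                                  breeds = NULL) {
  if (min_length < 1) stop("min_length must be >= 1", call. = FALSE)
  breeds <- breeds %||% sort(unique(masks$breed))
  missing <- setdiff(breeds, unique(masks$breed))
  if (length(missing) > 0) {
    stop("no coverage mask for breed(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(names(chrom_lengths), function(chr) {
    mk <- masks |> filter(.data$chrom == chr, .data$breed %in% breeds)
    covered <- if (nrow(mk) == 0) {
      IRanges::IRanges()
    } else {
      IRanges::reduce(IRanges::IRanges(start = mk$start, end = mk$end))
    }
    holes <- IRanges::setdiff(IRanges::IRanges(1L, chrom_lengths[[chr]]),
                              covered)
    holes <- holes[IRanges::width(holes) >= min_length]
    tibble(chrom = chr, start = IRanges::start(holes),
           end = IRanges::end(holes), length = IRanges::width(holes))
  })
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

# Per-position G-run lengths: grun[i] = number of consecutive G starting at i.
g_run_lengths <- function(is_g) {
  r <- rle(is_g)
  unlist(lapply(seq_along(r$lengths), function(i) {
    if (r$values[i]) rev(seq_len(r$lengths[i])) else integer(r$lengths[i])
  }), use.names = FALSE)
}

# All bases covered by some match of G{3,}N{1,7}G{3,}N{1,7}G{3,}N{1,7}G{3,}
# on ONE strand, as an IRanges. Dynamic programme over (start, runs left):
# for each possible match start the maximal match end is computed exactly, so
# the union over starts equals the union over all matches. Loop bases may be
# any unambiguous base (including G); literal N never matches anywhere.
g4_cover_one_strand <- function(chars) {
  n <- length(chars)
  is_g <- chars == "G"
  is_n <- !(chars %in% BASES)
  grun <- g_run_lengths(is_g)
  cand <- which(grun >= 3L)
  if (length(cand) == 0) return(IRanges::IRanges())
  cum_n <- cumsum(is_n)
  # Stage 1 (last G-run): maximal end takes the whole run.
  f_prev <- rep(NA_integer_, n)
  f_prev[cand] <- as.integer(cand + grun[cand] - 1L)
  for (stage in 2:4) {
    f_new <- rep(NA_integer_, n)
    for (i in cand) {
      jmin <- i + 4L
      jmax <- min(i + grun[i] + 7L, n)
      if (jmin > jmax) next
      js <- jmin:jmax
      js <- js[!is.na(f_prev[js])]
      if (length(js) == 0) next
      # Run + loop bases between this run's start and the next run must be
      # N-free (the run is all G; the loop may be any base but N).
      js <- js[cum_n[js - 1L] - cum_n[i + 2L] == 0]
      if (length(js) == 0) next
      f_new[i] <- max(f_prev[js])
    }
    f_prev <- f_new
  }
  ok <- cand[!is.na(f_prev[cand])]
  if (length(ok) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = ok, end = f_prev[ok]))
}

#' Fraction of a sequence covered by G-quadruplex motifs
#'
#' Quadparser-style canonical motif `G{3,}N{1,7}G{3,}N{1,7}G{3,}N{1,7}G{3,}`
#' scanned on both strands (the minus strand contributes the C-run analog);
#' the fraction is the union of all match footprints divided by the sequence
#' length. A literal N never matches.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param min_run Minimum G-run length (default 3).
#' @param max_loop Maximum loop length (default 7). Only the defaults are
#'   currently implemented for `min_run`.
#' @return Fraction in \[0, 1\].
#' @examples
#' g4_fraction("GGGTGGGTGGGTGGG")
#' @export
g4_fraction <- function(sequence, min_run = 3L, max_loop = 7L) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  if (min_run != 3L || max_loop != 7L) {
    stop("only min_run = 3 and max_loop = 7 are implemented", call. = FALSE)
  }
  chars <- seq_chars(toupper(sequence))
  n <- length(chars)
  plus <- g4_cover_one_strand(chars)
  rc <- seq_chars(revcomp(paste(chars, collapse = "")))
  minus_rc <- g4_cover_one_strand(rc)
  # Map minus-strand coordinates back to the plus frame.
  minus <- if (length(minus_rc) == 0) IRanges::IRanges() else {
    IRanges::IRanges(start = n - IRanges::end(minus_rc) + 1L,
                     end = n - IRanges::start(minus_rc) + 1L)
  }
  covered <- IRanges::reduce(c(plus, minus))
  sum(IRanges::width(covered)) / n
}

# Union coverage of maximal perfect tandem arrays, as an IRanges.
tandem_cover <- function(chars, max_unit = 50L, min_array = 10L) {
  n <- length(chars)
  is_n <- !(chars %in% BASES)
  pieces <- list()
  for (u in seq_len(min(max_unit, n %/% 2))) {
    eq <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    eq[is_n[seq_len(n - u)] | is_n[(u + 1L):n]] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # Array length = match-run length + u; require >= max(2u, min_array)
    # (at least two full unit copies, partial trailing copy allowed).
    need <- max(u, min_array - u)
    sel <- r$values & r$lengths >= need
    if (any(sel)) {
      pieces[[length(pieces) + 1L]] <-
        IRanges::IRanges(start = starts[sel], end = ends[sel] + u)
    }
  }
  if (length(pieces) == 0) return(IRanges::IRanges())
  IRanges::reduce(do.call(c, pieces))
}

#' Fraction of a sequence covered by perfect tandem repeat arrays
#'
#' Detects maximal perfect (exact-copy) tandem arrays with unit length 1 to
#' `max_unit` and total array length at least `max(2 * unit, min_array)` bp
#' by periodicity scan, and reports the union footprint divided by the
#' sequence length. Approximate (mutation-tolerant) repeats are out of scope.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param max_unit Largest repeat unit considered (default 50).
#' @param min_array Minimum array length floor in bp (default 10).
#' @return Fraction in \[0, 1\].
#' @examples
#' tandem_fraction("ACACACACAC")
#' @export
tandem_fraction <- function(sequence, max_unit = 50L, min_array = 10L) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- seq_chars(toupper(sequence))
  covered <- tandem_cover(chars, max_unit = max_unit, min_array = min_array)
  sum(IRanges::width(covered)) / length(chars)
}

#' Profile the sequence content of regions
#'
#' Computes the tandem-repeat and G-quadruplex fractions of each region plus
#' a genome-wide baseline row (coverage pooled over all chromosomes).
#'
#' @param regions Tibble `chrom`, `start`, `end` (1-based inclusive),
#'   optionally `region_id`.
#' @param genome Named character vector of chromosome sequences.
#' @param max_unit,min_array Tandem detector parameters (see
#'   [tandem_fraction()]).
#' @return Object of class `focalvar_region_profile`: a tibble `region_id`,
#'   `chrom`, `start`, `end`, `length`, `tandem_fraction`, `g4_fraction`,
#'   with the baseline row labelled `region_id = "genome_baseline"`.
#' @export
profile_regions <- function(regions, genome, max_unit = 50L, min_array = 10L) {
  assert_genome(genome)
  lens <- genome_lengths(genome)
  if (!"region_id" %in% names(regions)) {
    regions <- regions |>
      mutate(region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
  }
  bad <- regions$end > lens[regions$chrom] | regions$start < 1
  if (any(bad, na.rm = TRUE) || any(is.na(lens[regions$chrom]))) {
    stop("region outside chromosome bounds", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- substr(genome[[regions$chrom[i]]], regions$start[i], regions$end[i])
    tibble(region_id = regions$region_id[i], chrom = regions$chrom[i],
           start = regions$start[i], end = regions$end[i],
           length = nchar(s),
           tandem_fraction = tandem_fraction(s, max_unit, min_array),
           g4_fraction = g4_fraction(s))
  })
  # Genome-wide baseline: covered bases pooled over chromosomes.
  base_t <- 0; base_g <- 0
  for (chr in names(genome)) {
    chars <- seq_chars(toupper(genome[[chr]]))
    base_t <- base_t + sum(IRanges::width(tandem_cover(chars, max_unit, min_array)))
    n <- length(chars)
    plus <- g4_cover_one_strand(chars)
    rc <- seq_chars(revcomp(paste(chars, collapse = "")))
    minus_rc <- g4_cover_one_strand(rc)
    minus <- if (length(minus_rc) == 0) IRanges::IRanges() else {
      IRanges::IRanges(start = n - IRanges::end(minus_rc) + 1L,
                       end = n - IRanges::start(minus_rc) + 1L)
    }
    base_g <- base_g + sum(IRanges::width(IRanges::reduce(c(plus, minus))))
  }
  total <- sum(lens)
  baseline <- tibble(region_id = "genome_baseline", chrom = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     length = as.integer(total),
                     tandem_fraction = base_t / total,
                     g4_fraction = base_g / total)
  out <- bind_rows(bind_rows(rows), baseline)
  class(out) <- c("focalvar_region_profile", class(out))
  out
}

#' Scatter plot of region content fractions
#'
#' G4 fraction against tandem-repeat fraction, one point per region; the
#' genome-wide baseline is marked with a cross.
#'
#' @param object A `focalvar_region_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot focalvar_region_profile
#' @export
autoplot.focalvar_region_profile <- function(object, ...) {
  df <- as_tibble(object)
  regions <- df |> filter(.data$region_id != "genome_baseline")
  base <- df |> filter(.data$region_id == "genome_baseline")
  ggplot2::ggplot(regions, ggplot2::aes(x = .data$g4_fraction,
                                        y = .data$tandem_fraction)) +
    ggplot2::geom_point(colour = "darkgreen", alpha = 0.8) +
    ggplot2::geom_point(data = base, shape = 4, size = 3, colour = "black") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "fraction of G4 motifs", y = "fraction of tandem repeats",
                  title = "Content of focal-only regions (x = genome baseline)")
}
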