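# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the paths they verify.

# Upper binomial tail by explicit pmf summation with choose().
brute_binomial_tail <- function(p, n, k) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Per-position specificity by looping over every breed, mask row and record.
brute_specificity <- function(diffs, masks, min_breeds, breeds) {
  positions <- unique(diffs[, c("chrom", "pos")])
  out <- vector("list", nrow(positions))
  for (r in seq_len(nrow(positions))) {
    chrom <- positions$chrom[r]; pos <- positions$pos[r]
    covered <- character(0)
    for (b in breeds) {
      mk <- masks[masks$breed == b & masks$chrom == chrom, ]
      hit <- FALSE
      for (j in seq_len(nrow(mk))) {
        if (mk$start[j] <= pos && pos <= mk$end[j]) hit <- TRUE
      }
      if (hit) covered <- c(covered, b)
    }
    rec <- diffs[diffs$chrom == chrom & diffs$pos == pos, ]
    rec <- rec[rec$breed %in% covered, ]
    focal <- unique(rec$focal_allele)
    # Covered breeds without a record match the focal allele (dialect).
    shares <- length(setdiff(covered, rec$breed)) > 0 ||
      any(rec$breed_allele == focal)
    reason <- if (length(covered) < min_breeds) {
      "INSUFFICIENT_PRESENCE"
    } else if (shares) {
      "ALLELE_SHARED"
    } else {
      "SPECIFIC"
    }
    out[[r]] <- tibble::tibble(chrom = chrom, pos = pos,
                               n_covering = length(covered), reason = reason)
  }
  dplyr::bind_rows(out)
}

# All G4 motif matches by naive recursion over every decomposition
# (G-run >= 3, loop 1-7 of non-N bases, four runs); returns covered fraction.
naive_g4_fraction <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  covered <- rep(FALSE, n)
  mark_one <- function(i, runs_left) {
    # at i a G-run must start
    ends <- integer(0)
    g <- 0
    while (i + g <= n && ch[i + g] == "G") g <- g + 1
    if (g < 3) return(ends)
    if (runs_left == 1) {
      for (a in 3:g) ends <- c(ends, i + a - 1)
      return(ends)
    }
    for (a in 3:g) {
      for (b in 1:7) {
        j <- i + a + b
        if (j > n) next
        loop <- ch[(i + a):(j - 1)]
        if (any(!loop %in% c("A", "C", "G", "T"))) next
        ends <- c(ends, mark_one(j, runs_left - 1))
      }
    }
    ends
  }
  for (i in seq_len(n)) {
    ends <- mark_one(i, 4)
    if (length(ends) > 0) covered[i:max(ends)] <- TRUE
  }
  rc <- chartr("ACGTN", "TGCAN", paste(rev(ch), collapse = ""))
  ch2 <- strsplit(rc, "")[[1]]
  covered2 <- rep(FALSE, n)
  mark_one2 <- function(i, runs_left) {
    ends <- integer(0)
    g <- 0
    while (i + g <= n && ch2[i + g] == "G") g <- g + 1
    if (g < 3) return(ends)
    if (runs_left == 1) {
      for (a in 3:g) ends <- c(ends, i + a - 1)
      return(ends)
    }
    for (a in 3:g) {
      for (b in 1:7) {
        j <- i + a + b
        if (j > n) next
        loop <- ch2[(i + a):(j - 1)]
        if (any(!loop %in% c("A", "C", "G", "T"))) next
        ends <- c(ends, mark_one2(j, runs_left - 1))
      }
    }
    ends
  }
  for (i in seq_len(n)) {
    ends <- mark_one2(i, 4)
    if (length(ends) > 0) covered2[i:max(ends)] <- TRUE
  }
  # map reverse-complement coordinates back
  covered_minus <- rev(covered2)
  mean(covered | covered_minus)
}

# Perfect tandem arrays by double loop over unit length and start position.
brute_tandem_fraction <- function(seq, max_unit = 50, min_array = 10) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  covered <- rep(FALSE, n)
  for (u in seq_len(min(max_unit, n %/% 2))) {
    i <- 1
    while (i + u <= n) {
      # extend the periodic run starting at i
      j <- i
      while (j + u <= n && ch[j] == ch[j + u] &&
             ch[j] %in% c("A", "C", "G", "T") &&
             ch[j + u] %in% c("A", "C", "G", "T")) {
        j <- j + 1
      }
      run <- j - i
      if (run >= 1) {
        arr_len <- run + u
        if (arr_len >= max(2 * u, min_array)) {
          covered[i:(i + arr_len - 1)] <- TRUE
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  mean(covered)
}

# Random DNA string.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Small panel used across tests.
small_panel <- function(seed, n_breeds = 8L, chrom_len = 10000L,
                        n_genes = 4L, n_private_regions = 0L,
                        private_region_length_range = c(1000L, 2000L), ...) {
  cfg <- panel_config(
    n_breeds = n_breeds,
    chrom_lengths = c(chrA = chrom_len),
    n_genes = n_genes,
    cds_length_range = c(300L, 900L),
    n_private_regions = n_private_regions,
    private_region_length_range = private_region_length_range,
    seed = seed, ...)
  simulate_panel(cfg)
}
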