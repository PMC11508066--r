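# Classification of focal-breed-specific variants from pairwise difference
# tables. Dialect: a difference table lists, per comparison breed, only the
# positions where that breed differs from the focal genome; absence of a
# record at a position covered by the breed's mask means the breed matches
# the focal allele (pairwise-difference semantics). Coordinates are 1-based
# inclusive throughout the user-facing tables.

#' Count covering breeds at difference-site positions
#'
#' For each distinct position, counts the comparison breeds whose coverage
#' mask contains it. A site is testable only if enough breeds cover it.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based).
#' @param masks Coverage-mask tibble (`breed`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param breeds Character vector naming the full comparison panel; defaults
#'   to the breeds present in `masks`.
#' @return `sites` with an added integer column `n_covering`.
#' @export
compute_presence <- function(sites, masks, breeds = NULL) {
  breeds <- breeds %||% sort(unique(masks$breed))
  missing <- setdiff(breeds, unique(masks$breed))
  if (length(missing) > 0) {
    stop("no coverage mask for breed(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gr <- positions_to_gr(sites)
  n_cov <- integer(nrow(sites))
  for (b in breeds) {
    mk <- masks |> filter(.data$breed == b)
    if (nrow(mk) == 0) next
    n_cov <- n_cov + IRanges::overlapsAny(gr, intervals_to_gr(mk))
  }
  sites |> mutate(n_covering = as.integer(n_cov))
}

#' Classify difference sites as focal-specific
#'
#' Applies the presence and uniqueness rules: a site is focal-specific iff at
#' least `min_breeds` comparison breeds cover the position and none of the
#' covered breeds carries the focal allele. Under the pairwise-difference
#' dialect a covered breed with no record carries the focal allele, so a site
#' is specific exactly when every covered breed has a (differing) record.
#'
#' @param diffs Difference tibble (`chrom`, `pos`, `focal_allele`, `breed`,
#'   `breed_allele`), one record per breed that differs from the focal genome
#'   at a covered position.
#' @param masks Coverage-mask tibble (`breed`, `chrom`, `start`, `end`).
#' @param min_breeds Minimum number of covering breeds for a position to be
#'   testable. Default mirrors a "panel size minus 3" rule.
#' @param breeds Full comparison panel; defaults to breeds present in `masks`.
#' @return Tibble of specificity calls, one row per position: `chrom`, `pos`,
#'   `focal_allele`, `n_covering`, `n_differing`, `is_focal_specific`,
#'   `reason` (`SPECIFIC`, `ALLELE_SHARED` or `INSUFFICIENT_PRESENCE`). The
#'   number of records dropped for ambiguous (non-ACGT) alleles or for
#'   falling outside the recording breed's own mask is attached as attributes
#'   `n_dropped_ambiguous` and `n_dropped_uncovered_record`.
#' @export
classify_focal_specific <- function(diffs, masks,
                                    min_breeds = NULL, breeds = NULL) {
  breeds <- breeds %||% sort(unique(masks$breed))
  min_breeds <- min_breeds %||% max(1L, length(breeds) - 3L)
  if (min_breeds < 1) stop("min_breeds must be >= 1", call. = FALSE)

  ok_allele <- diffs$focal_allele %in% BASES & diffs$breed_allele %in% BASES
  n_ambiguous <- sum(!ok_allele)
  diffs <- diffs[ok_allele, ]

  # Consistency: one focal allele per position.
  chk <- diffs |> distinct(.data$chrom, .data$pos, .data$focal_allele) |>
    count(.data$chrom, .data$pos)
  if (any(chk$n > 1)) {
    bad <- chk |> filter(.data$n > 1)
    stop("conflicting focal alleles at ", nrow(bad), " position(s), e.g. ",
         bad$chrom[1], ":", bad$pos[1], call. = FALSE)
  }

  # Drop records from breeds whose own mask does not cover the position:
  # they carry no presence information under the dialect.
  rec_cov <- logical(nrow(diffs))
  for (b in breeds) {
    idx <- which(diffs$breed == b)
    if (length(idx) == 0) next
    mk <- masks |> filter(.data$breed == b)
    rec_cov[idx] <- IRanges::overlapsAny(positions_to_gr(diffs[idx, ]),
                                         intervals_to_gr(mk))
  }
  n_uncovered_record <- sum(!rec_cov)
  diffs <- diffs[rec_cov, ]

  sites <- diffs |>
    group_by(.data$chrom, .data$pos) |>
    summarise(focal_allele = .data$focal_allele[1],
              n_differing = dplyr::n_distinct(.data$breed),
              any_shares = any(.data$breed_allele == .data$focal_allele),
              .groups = "drop")
  sites <- compute_presence(sites, masks, breeds = breeds)

  calls <- sites |>
    mutate(
      reason = dplyr::case_when(
        .data$n_covering < .env$min_breeds ~ "INSUFFICIENT_PRESENCE",
        .data$any_shares | .data$n_differing < .data$n_covering ~ "ALLELE_SHARED",
        TRUE ~ "SPECIFIC"
      ),
      is_focal_specific = .data$reason == "SPECIFIC"
    ) |>
    select("chrom", "pos", "focal_allele", "n_covering", "n_differing",
           "is_focal_specific", "reason") |>
    arrange(.data$chrom, .data$pos)
  attr(calls, "n_dropped_ambiguous") <- n_ambiguous
  attr(calls, "n_dropped_uncovered_record") <- n_uncovered_record
  attr(calls, "min_breeds") <- min_breeds
  calls
}

#' Build the difference and focal-specific position sets S and U
#'
#' S is the set of positions passing the presence rule (each genomic position
#' counted once regardless of how many breeds differ there); U is the
#' focal-specific subset, so U is always contained in S.
#'
#' @param calls Specificity-call tibble from [classify_focal_specific()].
#' @return List with tibbles `S` and `U` (columns `chrom`, `pos`,
#'   `focal_allele`) and the scalar proportion `p` = |U|/|S| (NA when S is
#'   empty).
#' @export
build_variant_sets <- function(calls) {
  S <- calls |> filter(.data$reason != "INSUFFICIENT_PRESENCE") |>
    select("chrom", "pos", "focal_allele")
  U <- calls |> filter(.data$is_focal_specific) |>
    select("chrom", "pos", "focal_allele")
  list(S = S, U = U, p = if (nrow(S) > 0) nrow(U) / nrow(S) else NA_real_)
}

#' Call differences between two equal-length toy genomes
#'
#' Plumbing stand-in for a whole-genome aligner on toy data: compares two
#' sequences position by position in the same coordinate frame. Positions
#' with N in either sequence are skipped and excluded from the comparison
#' breed's mask.
#'
#' @param focal_seq,other_seq Character scalars of equal length.
#' @param chrom Chromosome name used in the output.
#' @param breed Comparison breed name used in the output.
#' @return List with `diffs` (tibble `chrom`, `pos`, `focal_allele`, `breed`,
#'   `breed_allele`) and `mask` (tibble `breed`, `chrom`, `start`, `end` of
#'   N-free intervals).
#' @export
call_differences_toy <- function(focal_seq, other_seq, chrom = "chr1",
                                 breed = "other") {
  if (nchar(focal_seq) != nchar(other_seq)) {
    stop("sequences must have equal length for toy difference calling",
         call. = FALSE)
  }
  a <- seq_chars(toupper(focal_seq))
  b <- seq_chars(toupper(other_seq))
  usable <- a != "N" & b != "N"
  d <- which(a != b & usable)
  diffs <- tibble(chrom = chrom, pos = d, focal_allele = a[d],
                  breed = breed, breed_allele = b[d])
  ir <- IRanges::reduce(IRanges::IRanges(start = which(usable), width = 1))
  mask <- tibble(breed = breed, chrom = chrom,
                 start = IRanges::start(ir), end = IRanges::end(ir))
  list(diffs = diffs, mask = mask)
}
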