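# The length-bias-free binomial enrichment test. Null hypothesis: the
# proportion of focal-private mutations in a unit's sites S' equals the
# genome-wide proportion p = |U|/|S|. The unit statistic is the exact upper
# binomial tail P(X >= k), X ~ Binomial(n = |S'|, p), with a fold-change
# filter (|U'|/|S'|) / (|U|/|S|). Because every unit is judged against its
# own site count n, longer genes gain no systematic advantage.

#' Exact upper binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p); returns 1 when k = 0 (the whole sample
#' space).
#'
#' @param p Success probability in \[0, 1\].
#' @param n Number of trials.
#' @param k Threshold count, 0 <= k <= n.
#' @return The exact tail probability.
#' @examples
#' binomial_tail(0.1, 10, 3)
#' @export
binomial_tail <- function(p, n, k) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  ifelse(k == 0, 1, pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Fold change of a unit's focal-private proportion
#'
#' (k/n) divided by the genome-wide proportion `p`.
#'
#' @param k Focal-private sites in the unit (|U'|).
#' @param n All sites in the unit (|S'|).
#' @param p Genome-wide focal-private proportion |U|/|S|, > 0.
#' @return The fold change.
#' @export
fold_change <- function(k, n, p) {
  if (any(n <= 0)) stop("n must be > 0 to compute a fold change", call. = FALSE)
  if (length(p) != 1 || is.na(p) || p <= 0) {
    stop("degenerate universe: |U|/|S| must be > 0", call. = FALSE)
  }
  (k / n) / p
}

#' Test one unit for an excess of focal-private mutations
#'
#' @param n Number of unit sites |S'| (> 0; units with n = 0 are skipped by
#'   [run_enrichment()], not tested).
#' @param k Number of focal-private unit sites |U'| (<= n).
#' @param p Genome-wide proportion |U|/|S|.
#' @param fold_min,p_max Pass thresholds (defaults 2 and 1e-3).
#' @return One-row tibble `n`, `k`, `fold`, `p_value`, `passes`.
#' @export
test_unit <- function(n, k, p, fold_min = 2, p_max = 1e-3) {
  if (any(k > n)) {
    stop("unit focal-private sites exceed unit sites (U' must be within S')",
         call. = FALSE)
  }
  fold <- fold_change(k, n, p)
  p_value <- binomial_tail(p, n, k)
  tibble(n = as.integer(n), k = as.integer(k), fold = fold,
         p_value = p_value,
         passes = fold >= fold_min & p_value < p_max)
}

ENRICH_MODES <- c("GENE_MISSENSE", "GENE_FLANK10K", "GO_MISSENSE",
                  "GO_FLANK10K")

#' Run the enrichment test in one of the four unit-construction modes
#'
#' Builds the mode's universe and per-unit site sets from effect annotations,
#' then applies the binomial tail test with the fold-change filter to every
#' unit with at least one site:
#' \describe{
#'   \item{GENE_MISSENSE}{S = all missense sites of all genes; S' = missense
#'     sites of one gene.}
#'   \item{GENE_FLANK10K}{S = all sites within any gene +/- `flank` window;
#'     S' = sites within one gene's window.}
#'   \item{GO_MISSENSE}{S = missense sites of genes carrying at least one GO
#'     category; S' = missense sites of one category's genes.}
#'   \item{GO_FLANK10K}{S = window sites of genes carrying at least one GO
#'     category; S' = window sites of one category's genes.}
#' }
#' A position inside two genes contributes to both genes' S' but is counted
#' once in the mode universe S. The universe proportion p = |U|/|S| is
#' computed over distinct positions.
#'
#' @param annotations Effect annotations from [annotate_effects()] joined
#'   with a logical column `is_focal_specific` (see
#'   [classify_focal_specific()]).
#' @param mode One of `"GENE_MISSENSE"`, `"GENE_FLANK10K"`, `"GO_MISSENSE"`,
#'   `"GO_FLANK10K"`.
#' @param gene_models Exon tibble; required for the window modes.
#' @param go_table Gene -> GO tibble; required for the GO modes.
#' @param flank Window flank in bp for the window modes (default 10000).
#' @param fold_min,p_max Pass thresholds (defaults 2 and 1e-3).
#' @param n_min Units with fewer than `n_min` sites are reported but never
#'   flagged (default 1).
#' @return An object of class `focalvar_enrichment`: list with `results`
#'   (tibble `unit_id`, `n`, `k`, `fold`, `p_value`, `p_adjust` (BH, extra
#'   information only; the pass flag ignores it), `passes`, sorted by
#'   p-value), `mode`, `S_size`, `U_size`, `p` and the thresholds.
#' @export
run_enrichment <- function(annotations, mode, gene_models = NULL,
                           go_table = NULL, flank = 10000L,
                           fold_min = 2, p_max = 1e-3, n_min = 1L) {
  if (!mode %in% ENRICH_MODES) {
    stop("unknown mode: ", mode, " (expected one of ",
         paste(ENRICH_MODES, collapse = ", "), ")", call. = FALSE)
  }
  if (!"is_focal_specific" %in% names(annotations)) {
    stop("annotations need an `is_focal_specific` column", call. = FALSE)
  }
  go_mode <- mode %in% c("GO_MISSENSE", "GO_FLANK10K")
  if (go_mode && (is.null(go_table) || nrow(go_table) == 0)) {
    stop("GO modes require a non-empty go_table", call. = FALSE)
  }

  if (mode %in% c("GENE_MISSENSE", "GO_MISSENSE")) {
    unit_sites <- annotations |>
      filter(.data$effect_class == "NONSYNONYMOUS_SNV", !is.na(.data$gene_id)) |>
      select("chrom", "pos", "gene_id", "is_focal_specific")
  } else {
    if (is.null(gene_models)) {
      stop("window modes require gene_models", call. = FALSE)
    }
    pos_tbl <- annotations |>
      distinct(.data$chrom, .data$pos, .data$is_focal_specific)
    unit_sites <- assign_gene_windows(pos_tbl, gene_models, flank = flank) |>
      left_join(pos_tbl, by = c("chrom", "pos"))
  }

  if (go_mode) {
    unit_sites <- unit_sites |>
      inner_join(go_table |> distinct(.data$gene_id, .data$go_id),
                 by = "gene_id", relationship = "many-to-many") |>
      mutate(unit_id = .data$go_id) |>
      # One category counts a position once even when several member genes
      # contain it.
      distinct(.data$unit_id, .data$chrom, .data$pos, .data$is_focal_specific)
  } else {
    unit_sites <- unit_sites |> mutate(unit_id = .data$gene_id)
  }

  universe <- unit_sites |> distinct(.data$chrom, .data$pos, .data$is_focal_specific)
  S_size <- nrow(universe)
  U_size <- sum(universe$is_focal_specific)
  if (S_size == 0) {
    res <- tibble(unit_id = character(), n = integer(), k = integer(),
                  fold = numeric(), p_value = numeric(), p_adjust = numeric(),
                  passes = logical())
    return(new_focalvar_enrichment(res, mode, S_size, U_size, NA_real_,
                                   fold_min, p_max, n_min))
  }
  p <- U_size / S_size

  per_unit <- unit_sites |>
    group_by(.data$unit_id) |>
    summarise(n = dplyr::n_distinct(paste(.data$chrom, .data$pos)),
              k = dplyr::n_distinct(paste(.data$chrom, .data$pos)[.data$is_focal_specific]),
              .groups = "drop") |>
    filter(.data$n > 0)

  if (p == 0) {
    # Degenerate universe: no focal-private site anywhere; no unit can be
    # enriched and the fold change is undefined.
    res <- per_unit |>
      mutate(fold = NA_real_, p_value = 1, p_adjust = 1, passes = FALSE) |>
      arrange(.data$p_value, .data$unit_id)
    return(new_focalvar_enrichment(res, mode, S_size, U_size, p,
                                   fold_min, p_max, n_min))
  }

  res <- per_unit |>
    mutate(fold = (.data$k / .data$n) / p,
           p_value = binomial_tail(p, .data$n, .data$k),
           p_adjust = p.adjust(.data$p_value, method = "BH"),
           passes = .data$fold >= fold_min & .data$p_value < p_max &
             .data$n >= n_min) |>
    arrange(.data$p_value, .data$unit_id)
  new_focalvar_enrichment(res, mode, S_size, U_size, p, fold_min, p_max, n_min)
}

new_focalvar_enrichment <- function(results, mode, S_size, U_size, p,
                                    fold_min, p_max, n_min) {
  structure(list(results = results, mode = mode, S_size = S_size,
                 U_size = U_size, p = p, fold_min = fold_min, p_max = p_max,
                 n_min = n_min),
            class = "focalvar_enrichment")
}

#' @export
print.focalvar_enrichment <- function(x, ...) {
  cat("<focalvar_enrichment> mode:", x$mode, "\n")
  cat(sprintf("  universe: |S| = %d, |U| = %d, p = %.4g\n",
              x$S_size, x$U_size, x$p))
  cat(sprintf("  units tested: %d, passing (fold >= %g, p < %g): %d\n",
              nrow(x$results), x$fold_min, x$p_max, sum(x$results$passes)))
  print(utils::head(x$results, 10))
  invisible(x)
}

#' Tidy an enrichment result
#'
#' @param x A `focalvar_enrichment` object.
#' @param ... Unused.
#' @return The per-unit results tibble, sorted by p-value.
#' @method tidy focalvar_enrichment
#' @export
tidy.focalvar_enrichment <- function(x, ...) x$results

#' One-row summary of an enrichment run
#'
#' @param x A `focalvar_enrichment` object.
#' @param ... Unused.
#' @return Tibble with the mode, universe sizes, the null proportion and the
#'   number of tested and passing units.
#' @method glance focalvar_enrichment
#' @export
glance.focalvar_enrichment <- function(x, ...) {
  tibble(mode = x$mode, S_size = x$S_size, U_size = x$U_size, p = x$p,
         n_units = nrow(x$results), n_pass = sum(x$results$passes),
         fold_min = x$fold_min, p_max = x$p_max)
}

#' Volcano-style plot of an enrichment run
#'
#' @param object A `focalvar_enrichment` object.
#' @param ... Unused.
#' @return A ggplot: fold change (log2) against -log10 p-value, passing units
#'   highlighted.
#' @method autoplot focalvar_enrichment
#' @export
autoplot.focalvar_enrichment <- function(object, ...) {
  df <- object$results |> filter(.data$fold > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold),
                                   y = -log10(.data$p_value),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$p_max), linetype = 2) +
    ggplot2::geom_vline(xintercept = log2(object$fold_min), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  colour = "passes",
                  title = paste("Focal-private mutation excess:", object$mode))
}

#' Density fold change of focal-specific variants in regions
#'
#' Per-region density of focal-specific positions divided by the genome-wide
#' average density.
#'
#' @param regions Tibble `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `region_id`.
#' @param specific_positions Tibble `chrom`, `pos` of focal-specific variants
#'   (the set U).
#' @param genome_size_considered Total bp over which U was ascertained.
#' @return `regions` with added columns `n_specific`, `density_fold`.
#' @export
region_density_fold <- function(regions, specific_positions,
                                genome_size_considered) {
  if (genome_size_considered <= 0) {
    stop("genome_size_considered must be > 0", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("zero- or negative-length region", call. = FALSE)
  }
  global_density <- nrow(specific_positions) / genome_size_considered
  counts <- GenomicRanges::countOverlaps(
    intervals_to_gr(regions), positions_to_gr(specific_positions))
  regions |>
    mutate(n_specific = as.integer(counts),
           length = .data$end - .data$start + 1L,
           density_fold = if (global_density > 0) {
             (.data$n_specific / .data$length) / global_density
           } else NA_real_)
}

#' Assign focal-specific variants to query regions
#'
#' Every variant is assigned to each region that contains it (inclusive
#' 1-based semantics); per-region counts are reported.
#'
#' @param specific_positions Tibble `chrom`, `pos`.
#' @param regions Tibble `chrom`, `start`, `end` and optionally `region_id`.
#' @return List with `assignments` (tibble region columns + `chrom`, `pos`)
#'   and `counts` (regions with `n_specific`).
#' @export
intersect_regions <- function(specific_positions, regions) {
  if (!"region_id" %in% names(regions)) {
    regions <- regions |>
      mutate(region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
  }
  hits <- GenomicRanges::findOverlaps(positions_to_gr(specific_positions),
                                      intervals_to_gr(regions))
  assignments <- tibble(
    region_id = regions$region_id[S4Vectors::subjectHits(hits)],
    chrom = specific_positions$chrom[S4Vectors::queryHits(hits)],
    pos = specific_positions$pos[S4Vectors::queryHits(hits)]
  )
  counts <- regions |>
    left_join(assignments |> count(.data$region_id, name = "n_specific"),
              by = "region_id") |>
    mutate(n_specific = dplyr::coalesce(.data$n_specific, 0L))
  list(assignments = assignments, counts = counts)
}
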