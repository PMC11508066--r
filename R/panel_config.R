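#' Configuration for the synthetic breed panel
#'
#' Bundles every tunable of the synthetic panel generator. The defaults
#' emulate a realistic multi-breed chicken panel at desk scale: 33 comparison
#' breeds radiating from a common ancestor (star topology), a pairwise
#' per-base difference rate of 0.5%, a focal-private proportion of 2% among
#' difference sites, multi-exon protein-coding genes, and a handful of
#' focal-only regions of 1000-4857 bp rich in tandem repeats and G-quadruplex
#' motifs.
#'
#' @param n_breeds Number of comparison breeds (>= 2).
#' @param chrom_lengths Named integer vector, chromosome name -> length (bp).
#' @param gc_content GC fraction of the ancestral genome, in \[0, 1\].
#' @param n_genes Number of protein-coding genes to plant.
#' @param exons_per_gene Integer range (length-2 vector) of CDS exons per gene.
#' @param cds_length_range Range (bp) of spliced CDS lengths; bounds are
#'   rounded to multiples of 3.
#' @param background_diff_rate Expected per-base pairwise difference fraction
#'   between the focal genome and one comparison breed.
#' @param focal_unique_fraction Expected fraction of difference sites that are
#'   focal-private (carried by no comparison breed).
#' @param enriched_units Tibble/data frame with columns `unit_id`,
#'   `multiplier` (>= 1) and `scope` (`"cds"` or `"window"`); the
#'   focal-private rate inside the unit is multiplied by `multiplier`.
#'   `unit_id` may be a gene id or a GO id (all member genes are scaled).
#' @param n_private_regions Number of focal-only regions to plant.
#' @param private_region_length_range Length range (bp) of planted regions.
#' @param private_region_tandem Target tandem-repeat fraction of planted
#'   regions.
#' @param private_region_g4 Target G-quadruplex fraction of planted regions.
#'   `private_region_tandem + private_region_g4` must be <= 1 (blocks are
#'   disjoint by construction).
#' @param uncovered_breed_fraction Probability that a given breed's coverage
#'   mask drops a given 1 kb window.
#' @param n_go_terms Number of GO categories in the synthetic gene->GO table.
#' @param go_terms_per_gene Integer range of GO terms per gene (0 allowed:
#'   such genes are excluded from GO-mode universes).
#' @param seed Master integer seed; the generator derives all of its RNG
#'   streams from it and is byte-deterministic given the same configuration.
#'
#' @return An object of class `panel_config` (a validated list).
#' @examples
#' cfg <- panel_config(chrom_lengths = c(chr1 = 50000), n_genes = 10,
#'                     n_private_regions = 1, seed = 1)
#' cfg$n_breeds
#' @export
panel_config <- function(n_breeds = 33L,
                         chrom_lengths = c(chr1 = 600000L, chr2 = 400000L),
                         gc_content = 0.42,
                         n_genes = 200L,
                         exons_per_gene = c(2L, 6L),
                         cds_length_range = c(300L, 3000L),
                         background_diff_rate = 0.005,
                         focal_unique_fraction = 0.02,
                         enriched_units = NULL,
                         n_private_regions = 8L,
                         private_region_length_range = c(1000L, 4857L),
                         private_region_tandem = 0.72,
                         private_region_g4 = 0.23,
                         uncovered_breed_fraction = 0.03,
                         n_go_terms = 20L,
                         go_terms_per_gene = c(0L, 3L),
                         seed = 1L) {
  if (is.null(enriched_units)) {
    enriched_units <- tibble(unit_id = character(), multiplier = numeric(),
                             scope = character())
  }
  enriched_units <- as_tibble(enriched_units)
  if (!all(c("unit_id", "multiplier") %in% names(enriched_units))) {
    stop("`enriched_units` needs columns unit_id and multiplier", call. = FALSE)
  }
  if (!"scope" %in% names(enriched_units)) {
    enriched_units$scope <- "cds"
  }
  cfg <- list(
    n_breeds = as.integer(n_breeds),
    chrom_lengths = chrom_lengths,
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    cds_length_range = as.integer(cds_length_range),
    background_diff_rate = background_diff_rate,
    focal_unique_fraction = focal_unique_fraction,
    enriched_units = enriched_units,
    n_private_regions = as.integer(n_private_regions),
    private_region_length_range = as.integer(private_region_length_range),
    private_region_tandem = private_region_tandem,
    private_region_g4 = private_region_g4,
    uncovered_breed_fraction = uncovered_breed_fraction,
    n_go_terms = as.integer(n_go_terms),
    go_terms_per_gene = as.integer(go_terms_per_gene),
    seed = as.integer(seed)
  )
  validate_panel_config(cfg)
}

validate_panel_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_breeds < 2) stop("n_breeds must be >= 2", call. = FALSE)
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  if (any(cfg$chrom_lengths < 1)) {
    stop("chromosome lengths must be >= 1", call. = FALSE)
  }
  frac <- c(cfg$gc_content, cfg$background_diff_rate, cfg$focal_unique_fraction,
            cfg$uncovered_breed_fraction, cfg$private_region_tandem,
            cfg$private_region_g4)
  if (any(frac < 0 | frac > 1)) {
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$private_region_tandem + cfg$private_region_g4 > 1) {
    stop("private region composition targets must sum to <= 1", call. = FALSE)
  }
  if (nrow(cfg$enriched_units) > 0 && any(cfg$enriched_units$multiplier < 1)) {
    stop("enrichment multipliers must be >= 1", call. = FALSE)
  }
  if (length(cfg$exons_per_gene) != 2 || any(cfg$exons_per_gene < 1)) {
    stop("exons_per_gene must be a positive length-2 range", call. = FALSE)
  }
  if (length(cfg$cds_length_range) != 2 || cfg$cds_length_range[1] < 6) {
    stop("cds_length_range must be a length-2 range with minimum >= 6",
         call. = FALSE)
  }
  # CDS lengths are drawn as multiples of 3; snap the bounds.
  cfg$cds_length_range <- cfg$cds_length_range - cfg$cds_length_range %% 3L
  structure(cfg, class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  cat("  breeds:", x$n_breeds,
      " genome:", sum(x$chrom_lengths), "bp over",
      length(x$chrom_lengths), "chromosome(s)\n")
  cat("  genes:", x$n_genes, " GO terms:", x$n_go_terms, "\n")
  cat("  pairwise diff rate:", x$background_diff_rate,
      " focal-private fraction:", x$focal_unique_fraction, "\n")
  cat("  private regions:", x$n_private_regions, "of",
      paste(x$private_region_length_range, collapse = "-"), "bp\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
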