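# End-to-end orchestration: analyze a panel in memory, or round-trip a
# simulated panel bundle through standard file formats and write the result
# tables. Stage counts (records in / kept / dropped with reasons) are
# collected in a structured log so filter conservation can be asserted.

#' Analyze a breed panel
#'
#' Runs the full pipeline on in-memory panel data: specificity
#' classification, the S/U sets, effect annotation, the four enrichment
#' modes, focal-only region detection and content profiling, and (optionally)
#' overlap and density-fold statistics for externally supplied query regions.
#'
#' @param panel A `breed_panel` from [simulate_panel()], or any list with
#'   elements `genome`, `gene_models`, `go_table`, `diffs`, `masks`.
#' @param min_breeds Presence threshold; default panel size minus 3.
#' @param flank Gene window flank in bp (default 10000).
#' @param fold_min,p_max Enrichment pass thresholds (defaults 2 and 1e-3).
#' @param min_region_length Minimum focal-only region length (default 1000).
#' @param query_regions Optional named list of region tibbles (`chrom`,
#'   `start`, `end`) to intersect with the focal-specific set.
#' @return Object of class `focalvar_analysis`: list with `calls`, `sets`
#'   (S, U, p), `annotations`, `enrichment` (one `focalvar_enrichment` per
#'   mode), `regions`, `region_profile`, `query_overlaps`, `log` and the
#'   parameters used.
#' @export
analyze_panel <- function(panel, min_breeds = NULL, flank = 10000L,
                          fold_min = 2, p_max = 1e-3,
                          min_region_length = 1000L, query_regions = NULL) {
  genome <- panel$genome
  breeds <- sort(unique(panel$masks$breed))
  min_breeds <- min_breeds %||% max(1L, length(breeds) - 3L)

  calls <- classify_focal_specific(panel$diffs, panel$masks,
                                   min_breeds = min_breeds, breeds = breeds)
  sets <- build_variant_sets(calls)

  log <- list(
    tibble(stage = "classify_records", n_in = nrow(panel$diffs),
           n_kept = nrow(panel$diffs) -
             attr(calls, "n_dropped_ambiguous") -
             attr(calls, "n_dropped_uncovered_record"),
           n_dropped = attr(calls, "n_dropped_ambiguous") +
             attr(calls, "n_dropped_uncovered_record"),
           reason = "ambiguous allele or record outside own mask"),
    tibble(stage = "presence_filter", n_in = nrow(calls),
           n_kept = nrow(sets$S), n_dropped = nrow(calls) - nrow(sets$S),
           reason = "fewer covering breeds than min_breeds")
  )

  s_sites <- calls |>
    filter(.data$reason != "INSUFFICIENT_PRESENCE") |>
    select("chrom", "pos", "focal_allele", "is_focal_specific")
  ann <- annotate_effects(s_sites |> select(-"is_focal_specific"),
                          panel$gene_models, genome, diffs = panel$diffs,
                          flank = flank)
  ann <- ann |> left_join(s_sites |> select("chrom", "pos", "is_focal_specific"),
                          by = c("chrom", "pos"))
  log <- c(log, list(
    tibble(stage = "effect_annotation", n_in = nrow(s_sites),
           n_kept = nrow(s_sites) - attr(ann, "n_dropped_ref_mismatch"),
           n_dropped = attr(ann, "n_dropped_ref_mismatch"),
           reason = "focal allele disagrees with genome sequence")))

  enrichment <- lapply(setNames(ENRICH_MODES, ENRICH_MODES), function(m) {
    run_enrichment(ann, m, gene_models = panel$gene_models,
                   go_table = panel$go_table, flank = flank,
                   fold_min = fold_min, p_max = p_max)
  })

  chrom_lengths <- genome_lengths(genome)
  regions <- find_specific_regions(panel$masks, chrom_lengths,
                                   min_length = min_region_length,
                                   breeds = breeds)
  region_profile <- profile_regions(regions, genome)

  query_overlaps <- NULL
  if (!is.null(query_regions)) {
    query_overlaps <- lapply(query_regions, function(qr) {
      ov <- intersect_regions(sets$U, qr)
      dens <- region_density_fold(ov$counts, sets$U, sum(chrom_lengths))
      list(counts = dens, assignments = ov$assignments)
    })
  }

  structure(list(
    calls = calls, sets = sets, annotations = ann, enrichment = enrichment,
    regions = regions, region_profile = region_profile,
    query_overlaps = query_overlaps,
    log = bind_rows(log),
    params = list(min_breeds = min_breeds, flank = flank, fold_min = fold_min,
                  p_max = p_max, min_region_length = min_region_length,
                  breeds = breeds)
  ), class = "focalvar_analysis")
}

#' @export
print.focalvar_analysis <- function(x, ...) {
  cat("<focalvar_analysis>\n")
  cat(sprintf("  |S| = %d, |U| = %d, p = %.4g (min_breeds = %d)\n",
              nrow(x$sets$S), nrow(x$sets$U), x$sets$p, x$params$min_breeds))
  for (m in names(x$enrichment)) {
    cat(sprintf("  %s: %d units, %d pass\n", m,
                nrow(x$enrichment[[m]]$results),
                sum(x$enrichment[[m]]$results$passes)))
  }
  cat("  focal-only regions:", nrow(x$regions), "\n")
  invisible(x)
}

#' One-row summary of a panel analysis
#'
#' @param x A `focalvar_analysis`.
#' @param ... Unused.
#' @return Tibble with set sizes, the focal-specific proportion, passing-unit
#'   counts per mode and the region count.
#' @method glance focalvar_analysis
#' @export
glance.focalvar_analysis <- function(x, ...) {
  pass <- vapply(x$enrichment, function(e) sum(e$results$passes), integer(1))
  tibble(S_size = nrow(x$sets$S), U_size = nrow(x$sets$U), p = x$sets$p,
         pass_gene_missense = pass[["GENE_MISSENSE"]],
         pass_gene_flank = pass[["GENE_FLANK10K"]],
         pass_go_missense = pass[["GO_MISSENSE"]],
         pass_go_flank = pass[["GO_FLANK10K"]],
         n_regions = nrow(x$regions))
}

#' Simulate a panel and write the bundle to disk
#'
#' Writes the focal FASTA, GFF3 gene models, gene -> GO TSV, per-breed
#' difference TSVs and mask BEDs, the ground-truth JSON and a manifest with
#' the seed, parameter echo and per-file MD5 checksums.
#'
#' @param config A [panel_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `breed_panel`, invisibly.
#' @export
simulate_panel_files <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(config)
  write_genome_fasta(panel$genome, file.path(out_dir, "focal_genome.fa"))
  write_gene_models_gff3(panel$gene_models, file.path(out_dir, "genes.gff3"))
  write_go_table(panel$go_table, file.path(out_dir, "gene_go.tsv"))
  write_diff_tables(panel$diffs, out_dir)
  write_masks_bed(panel$masks, out_dir)
  truth <- list(
    sites = panel$truth$sites,
    coding_effects = panel$truth$coding_effects,
    regions = panel$truth$regions,
    enriched_units = panel$truth$enriched_units
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    n_breeds = config$n_breeds,
    chrom_lengths = as.list(config$chrom_lengths),
    background_diff_rate = config$background_diff_rate,
    focal_unique_fraction = config$focal_unique_fraction,
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(panel)
}

#' Read a panel bundle written by [simulate_panel_files()]
#'
#' @param dir Bundle directory.
#' @return List with `genome`, `gene_models`, `go_table`, `diffs`, `masks`
#'   and (when `truth.json` is present) `truth`.
#' @export
read_panel_files <- function(dir) {
  panel <- list(
    genome = read_genome_fasta(file.path(dir, "focal_genome.fa")),
    gene_models = read_gene_models_gff3(file.path(dir, "genes.gff3")),
    go_table = read_go_table(file.path(dir, "gene_go.tsv")),
    diffs = read_diff_tables(dir),
    masks = read_masks_bed(dir)
  )
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    panel$truth <- lapply(tr, as_tibble)
  }
  panel
}

#' Analyze a panel bundle on disk and write result tables
#'
#' Reads a bundle (see [simulate_panel_files()]), runs [analyze_panel()] and
#' writes: specificity calls TSV, a VCF of the focal-specific set, effect
#' annotations TSV, one enrichment TSV per mode, focal-only regions BED plus
#' content-profile TSV, per-query-BED overlap TSVs, and a JSON run report
#' with the stage log. Outputs are deterministic given identical inputs.
#'
#' @param in_dir Bundle directory.
#' @param out_dir Output directory (created if needed).
#' @param query_region_beds Optional character vector of BED paths with query
#'   region sets (e.g. published selection-signature intervals).
#' @inheritParams analyze_panel
#' @return The `focalvar_analysis`, invisibly.
#' @export
analyze_panel_files <- function(in_dir, out_dir, min_breeds = NULL,
                                flank = 10000L, fold_min = 2, p_max = 1e-3,
                                min_region_length = 1000L,
                                query_region_beds = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_panel_files(in_dir)
  query_regions <- NULL
  if (!is.null(query_region_beds)) {
    query_regions <- lapply(query_region_beds, read_bed)
    names(query_regions) <- tools::file_path_sans_ext(basename(query_region_beds))
  }
  res <- tryCatch(
    analyze_panel(panel, min_breeds = min_breeds, flank = flank,
                  fold_min = fold_min, p_max = p_max,
                  min_region_length = min_region_length,
                  query_regions = query_regions),
    error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop("analysis failed: ", conditionMessage(e), call. = FALSE)
    })

  readr::write_tsv(res$calls, file.path(out_dir, "specificity_calls.tsv"),
                   progress = FALSE)
  write_specific_vcf(res$calls, panel$diffs,
                     file.path(out_dir, "focal_specific.vcf"))
  readr::write_tsv(res$annotations, file.path(out_dir, "effects.tsv"),
                   progress = FALSE)
  for (m in names(res$enrichment)) {
    readr::write_tsv(tidy(res$enrichment[[m]]),
                     file.path(out_dir, paste0("enrichment_", tolower(m), ".tsv")),
                     progress = FALSE)
  }
  write_bed(res$regions, file.path(out_dir, "focal_only_regions.bed"))
  readr::write_tsv(as_tibble(res$region_profile),
                   file.path(out_dir, "region_profile.tsv"), progress = FALSE)
  if (!is.null(res$query_overlaps)) {
    for (q in names(res$query_overlaps)) {
      readr::write_tsv(res$query_overlaps[[q]]$counts,
                       file.path(out_dir, paste0("query_overlap_", q, ".tsv")),
                       progress = FALSE)
    }
  }
  report <- list(
    params = res$params[c("min_breeds", "flank", "fold_min", "p_max",
                          "min_region_length")],
    sets = list(S = nrow(res$sets$S), U = nrow(res$sets$U), p = res$sets$p),
    enrichment = lapply(res$enrichment, function(e) as.list(glance(e))),
    n_regions = nrow(res$regions),
    log = res$log
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(res)
}
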