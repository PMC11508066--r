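# Synthetic breed panel: a star phylogeny around a common ancestor. Every
# difference site is a substitution on the focal branch; "shared" sites also
# hand the focal allele to a random non-empty proper subset of comparison
# breeds, which guarantees non-specificity by construction, while
# "focal-private" sites are carried by the focal genome alone.

MASK_WINDOW <- 1000L

#' Generate a synthetic gene -> GO table
#'
#' Assigns each gene a random number of GO categories (possibly zero; such
#' genes are excluded from GO-mode enrichment universes downstream).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param config A [panel_config()].
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `go_id`, `go_name`.
#' @export
make_go_table <- function(gene_ids, config, seed) {
  go_ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  withr::with_seed(child_seed(seed, "go"), {
    rows <- lapply(gene_ids, function(g) {
      k <- sample(config$go_terms_per_gene[1]:config$go_terms_per_gene[2], 1)
      k <- min(k, length(go_ids))
      if (k == 0) return(NULL)
      tibble(gene_id = g, go_id = sort(sample(go_ids, k)))
    })
    out <- bind_rows(rows)
    if (nrow(out) == 0) {
      return(tibble(gene_id = character(), go_id = character(),
                    go_name = character()))
    }
    out |>
      mutate(go_name = paste("synthetic category",
                             as.integer(sub("GO:", "", .data$go_id))))
  })
}

# Resolve enriched unit ids (gene or GO) to genomic scope intervals carrying
# their multipliers. scope "cds" -> the gene's CDS exons; "window" -> the gene
# span +/- flank.
resolve_enriched_scopes <- function(config, gene_models, go_table,
                                    flank = 10000L) {
  eu <- config$enriched_units
  if (nrow(eu) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  multiplier = numeric()))
  }
  spans <- gene_spans(gene_models)
  rows <- lapply(seq_len(nrow(eu)), function(i) {
    uid <- eu$unit_id[i]
    genes <- if (uid %in% gene_models$gene_id) {
      uid
    } else if (uid %in% go_table$go_id) {
      unique(go_table$gene_id[go_table$go_id == uid])
    } else {
      stop("enriched unit id not found in gene or GO inputs: ", uid,
           call. = FALSE)
    }
    if (eu$scope[i] == "cds") {
      gene_models |>
        filter(.data$gene_id %in% genes) |>
        select("chrom", "start", "end") |>
        mutate(multiplier = eu$multiplier[i])
    } else {
      spans |>
        filter(.data$gene_id %in% genes) |>
        mutate(start = pmax(1L, .data$start - flank),
               end = .data$end + flank) |>
        select("chrom", "start", "end") |>
        mutate(multiplier = eu$multiplier[i])
    }
  })
  bind_rows(rows)
}

# Per-breed coverage masks in fixed 1 kb windows: each breed independently
# drops a window with probability uncovered_breed_fraction. Returned as a
# merged 1-based inclusive interval tibble.
make_coverage_masks <- function(chrom_lengths, n_breeds, uncovered_fraction,
                                seed) {
  breeds <- sprintf("breed%02d", seq_len(n_breeds))
  withr::with_seed(child_seed(seed, "masks"), {
    rows <- lapply(breeds, function(b) {
      per_chrom <- lapply(names(chrom_lengths), function(chr) {
        L <- chrom_lengths[[chr]]
        n_win <- ceiling(L / MASK_WINDOW)
        keep <- stats::runif(n_win) >= uncovered_fraction
        if (!any(keep)) return(NULL)
        w <- which(keep)
        ir <- IRanges::reduce(IRanges::IRanges(
          start = (w - 1L) * MASK_WINDOW + 1L,
          end = pmin(w * MASK_WINDOW, L)
        ))
        tibble(breed = b, chrom = chr,
               start = IRanges::start(ir), end = IRanges::end(ir))
      })
      bind_rows(per_chrom)
    })
    bind_rows(rows)
  })
}

# Coverage lookup: logical matrix sites x breeds from the window masks.
site_coverage_matrix <- function(sites, masks, breeds) {
  gr <- positions_to_gr(sites)
  cov <- matrix(FALSE, nrow = nrow(sites), ncol = length(breeds),
                dimnames = list(NULL, breeds))
  for (b in breeds) {
    mk <- masks |> filter(.data$breed == b)
    if (nrow(mk) == 0) next
    cov[, b] <- IRanges::overlapsAny(gr, intervals_to_gr(mk))
  }
  cov
}

#' Simulate per-breed difference tables, coverage masks and ground truth
#'
#' Plants two classes of substitution sites on the focal branch of a star
#' phylogeny: shared-variation sites, whose focal allele is also carried by a
#' random non-empty proper subset of comparison breeds, and focal-private
#' sites, carried by no comparison breed. Inside each configured enriched
#' unit the focal-private rate is `multiplier` times the base rate. The
#' focal genome sequence is edited to carry the focal allele at every site.
#'
#' @param genome Named character vector (ancestral genome with genes planted).
#' @param gene_models Exon tibble from [plant_genes()].
#' @param go_table Gene -> GO tibble from [make_go_table()].
#' @param config A [panel_config()].
#' @param seed Integer seed.
#' @param forbidden Optional interval tibble where no site may be planted
#'   (used for reserved focal-only region intervals).
#' @return List with `genome` (focal sequence), `diffs` (tibble `chrom`,
#'   `pos`, `focal_allele`, `breed`, `breed_allele`), `masks` (tibble
#'   `breed`, `chrom`, `start`, `end`) and `truth` (list with `sites` and
#'   `coding_effects` tibbles).
#' @export
simulate_breed_differences <- function(genome, gene_models, go_table, config,
                                       seed, forbidden = NULL) {
  assert_genome(genome)
  lens <- genome_lengths(genome)
  breeds <- sprintf("breed%02d", seq_len(config$n_breeds))
  f <- config$focal_unique_fraction
  # Calibrate the per-base site rate so that the realized pairwise difference
  # fraction against one breed matches background_diff_rate: a covered breed
  # differs at a site with probability f + (1 - f) * P(not in sharing subset),
  # and sharing subsets of size Uniform{1..n-1} include a given breed with
  # probability 1/2.
  site_rate <- min(1, config$background_diff_rate / (f + (1 - f) / 2))

  masks <- make_coverage_masks(lens, config$n_breeds,
                               config$uncovered_breed_fraction, seed)
  scopes <- resolve_enriched_scopes(config, gene_models, go_table)

  withr::with_seed(child_seed(seed, "sites"), {
    # Positions available for planting: everything outside `forbidden`.
    site_list <- lapply(names(genome), function(chr) {
      avail <- IRanges::IRanges(start = 1L, end = lens[[chr]])
      if (!is.null(forbidden)) {
        fb <- forbidden |> filter(.data$chrom == chr)
        if (nrow(fb) > 0) {
          avail <- IRanges::setdiff(
            avail, IRanges::IRanges(start = fb$start, end = fb$end))
        }
      }
      pool <- unlist(lapply(seq_along(avail), function(i) {
        seq(IRanges::start(avail)[i], IRanges::end(avail)[i])
      }))
      n_sites <- stats::rbinom(1, length(pool), site_rate)
      tibble(chrom = chr, pos = sort(sample(pool, n_sites)))
    })
    sites <- bind_rows(site_list)

    # Per-site focal-private probability, scaled inside enriched scopes.
    mult <- rep(1, nrow(sites))
    if (nrow(scopes) > 0) {
      hits <- GenomicRanges::findOverlaps(positions_to_gr(sites),
                                          intervals_to_gr(scopes))
      if (length(hits) > 0) {
        hit_df <- tibble(site = S4Vectors::queryHits(hits),
                         m = scopes$multiplier[S4Vectors::subjectHits(hits)]) |>
          group_by(.data$site) |> summarise(m = max(.data$m), .groups = "drop")
        mult[hit_df$site] <- hit_df$m
      }
    }
    p_private <- pmin(1, f * mult)
    is_private <- stats::runif(nrow(sites)) < p_private

    # Alleles: ancestral base from the genome, focal allele one of the 3
    # alternatives, uniform.
    anc <- character(nrow(sites))
    for (chr in names(genome)) {
      idx <- which(sites$chrom == chr)
      if (length(idx) > 0) {
        raw_chr <- charToRaw(genome[[chr]])
        anc[idx] <- strsplit(rawToChar(raw_chr[sites$pos[idx]]), "",
                             fixed = TRUE)[[1]]
      }
    }
    alt <- vapply(anc, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)

    cov <- site_coverage_matrix(sites, masks, breeds)

    # Sharing subsets for shared sites: size Uniform{1 .. n_breeds - 1},
    # anchored at one breed that covers the site so a shared site can never
    # look focal-specific (non-specificity by construction). Sites no breed
    # covers are unobservable and dropped below either way.
    shares <- matrix(FALSE, nrow = nrow(sites), ncol = length(breeds),
                     dimnames = list(NULL, breeds))
    shared_idx <- which(!is_private)
    for (i in shared_idx) {
      s <- sample.int(config$n_breeds - 1L, 1)
      covered_j <- which(cov[i, ])
      if (length(covered_j) == 0) {
        shares[i, sample.int(config$n_breeds, s)] <- TRUE
        next
      }
      anchor <- covered_j[sample.int(length(covered_j), 1)]
      pool <- setdiff(seq_len(config$n_breeds), anchor)
      extra <- if (s > 1) pool[sample.int(length(pool), s - 1L)] else integer(0)
      shares[i, c(anchor, extra)] <- TRUE
    }

    # Emit one record per (site, breed) where the breed is covered and does
    # not carry the focal allele.
    differs <- cov & !shares
    rec_list <- lapply(seq_along(breeds), function(j) {
      idx <- which(differs[, j])
      if (length(idx) == 0) return(NULL)
      tibble(chrom = sites$chrom[idx], pos = sites$pos[idx],
             focal_allele = alt[idx], breed = breeds[j],
             breed_allele = anc[idx])
    })
    diffs <- bind_rows(rec_list) |> arrange(.data$chrom, .data$pos, .data$breed)

    truth_sites <- tibble(
      chrom = sites$chrom, pos = sites$pos,
      ancestral_allele = anc, focal_allele = alt,
      class = ifelse(is_private, "focal_private", "shared"),
      multiplier = mult,
      n_covered = rowSums(cov),
      n_records = rowSums(differs)
    )
    # A site emitting no record is unobservable (every covered breed carries
    # the focal allele, or nothing covers it); drop it from truth and leave
    # the genome untouched there.
    keep <- truth_sites$n_records > 0
    truth_sites <- truth_sites[keep, ]
    sites <- sites[keep, ]
    alt_kept <- alt[keep]

    # Apply the focal-branch substitutions to the genome.
    genome_out <- genome
    for (chr in names(genome)) {
      idx <- which(sites$chrom == chr)
      if (length(idx) > 0) {
        genome_out[[chr]] <- replace_bases(genome_out[[chr]], sites$pos[idx],
                                           alt_kept[idx])
      }
    }
  })

  coding <- truth_coding_effects(truth_sites, gene_models, genome_out)
  truth_sites <- truth_sites |>
    left_join(coding |> select("chrom", "pos", "gene_id", "effect_class"),
              by = c("chrom", "pos"), relationship = "many-to-many") |>
    group_by(.data$chrom, .data$pos) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos)

  list(genome = genome_out, diffs = diffs, masks = masks,
       truth = list(sites = truth_sites, coding_effects = coding))
}

# Ground-truth coding effects by whole-CDS re-translation: for each site
# inside a CDS exon, revert the focal base to the ancestral allele in the
# spliced CDS, translate both versions in full, and diff the proteins. This
# is a deliberately different route from the codon-level annotator in the
# effects module, so the two can check each other.
truth_coding_effects <- function(truth_sites, gene_models, genome_focal) {
  empty <- tibble(chrom = character(), pos = integer(), gene_id = character(),
                  effect_class = character(), aa_pos = integer(),
                  ref_aa = character(), alt_aa = character())
  if (nrow(truth_sites) == 0 || nrow(gene_models) == 0) return(empty)
  exmap <- gene_models |>
    arrange(.data$gene_id, .data$exon_rank) |>
    group_by(.data$gene_id) |>
    mutate(w = .data$end - .data$start + 1L,
           toff = cumsum(.data$w) - .data$w) |>
    ungroup()
  hits <- GenomicRanges::findOverlaps(positions_to_gr(truth_sites),
                                      intervals_to_gr(exmap))
  if (length(hits) == 0) return(empty)
  si <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)

  cds_cache <- spliced_cds_all(genome_focal, gene_models,
                               unique(exmap$gene_id[ei]))

  strand <- exmap$strand[ei]
  tpos <- ifelse(strand == "+",
                 exmap$toff[ei] + truth_sites$pos[si] - exmap$start[ei] + 1L,
                 exmap$toff[ei] + exmap$end[ei] - truth_sites$pos[si] + 1L)
  anc_t <- ifelse(strand == "+",
                  truth_sites$ancestral_allele[si],
                  unname(COMPLEMENT[truth_sites$ancestral_allele[si]]))

  focal_cds <- cds_cache[exmap$gene_id[ei]]
  ref_cds <- paste0(substring(focal_cds, 1L, tpos - 1L), anc_t,
                    substring(focal_cds, tpos + 1L, nchar(focal_cds)))

  prot_focal <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(focal_cds), no.init.codon = TRUE))
  prot_ref <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(ref_cds), no.init.codon = TRUE))

  # A single-base revert changes at most the codon containing tpos, so the
  # protein diff (if any) sits at that codon index.
  ci <- (tpos - 1L) %/% 3L + 1L
  ref_aa <- substr(prot_ref, ci, ci)
  alt_aa <- substr(prot_focal, ci, ci)
  cls <- dplyr::case_when(
    ref_aa == alt_aa ~ "SYNONYMOUS_SNV",
    alt_aa == "*" ~ "STOPGAIN",
    ref_aa == "*" ~ "STOPLOSS",
    TRUE ~ "NONSYNONYMOUS_SNV"
  )
  tibble(chrom = truth_sites$chrom[si], pos = truth_sites$pos[si],
         gene_id = exmap$gene_id[ei], effect_class = cls,
         aa_pos = as.integer(ci), ref_aa = ref_aa, alt_aa = alt_aa) |>
    arrange(.data$chrom, .data$pos)
}

# Composite focal-only region sequence: disjoint perfect-tandem blocks,
# G-quadruplex motif blocks and random filler, hitting target fractions.
build_private_sequence <- function(len, tandem_target, g4_target) {
  if (tandem_target + g4_target > 1) {
    stop("private region composition targets must sum to <= 1", call. = FALSE)
  }
  n_t <- round(tandem_target * len)
  n_g <- round(g4_target * len)

  segments <- list()
  # Perfect tandem arrays: units of 2-8 bp with at most one G (so a block can
  # neither form a G4 nor merge with one).
  rem <- n_t
  while (rem >= 10) {
    alen <- if (rem > 900) sample(300:800, 1) else rem
    if (rem - alen < 10) alen <- rem
    repeat {
      u <- sample(2:8, 1)
      unit <- paste(sample(BASES, u, replace = TRUE), collapse = "")
      tiled <- strrep(unit, 3)
      # no G- or C-triplet anywhere in the tiled array (a C-run is a G4 on
      # the minus strand), and no homopolymer unit
      if (!grepl("GGG", tiled, fixed = TRUE) &&
          !grepl("CCC", tiled, fixed = TRUE) &&
          length(unique(seq_chars(unit))) > 1) break
    }
    arr <- substr(strrep(unit, ceiling(alen / u)), 1, alen)
    segments <- c(segments, list(arr))
    rem <- rem - alen
  }
  # One chained G4 block: G-runs of 3 separated by 1-3 bp loops over A/C/T.
  # Overlapping four-run matches tile the whole block, so its G4 coverage is
  # its full length. Loop constraints keep perfect tandem periodicity out of
  # the block: a loop may not be a prefix/suffix of its predecessor (period
  # 3 + loop) nor equal the loop two back (period 6 + both loops). A single
  # long block instead of many short ones avoids junction artifacts where
  # sentinels and thin fillers get swallowed by matches or arrays.
  if (n_g >= 15) {
    parts <- "GGG"
    blk_len <- 3L
    prev1 <- ""; prev2 <- ""
    while (blk_len < n_g) {
      repeat {
        loop <- paste(sample(c("A", "C", "T"), sample(1:3, 1), replace = TRUE),
                      collapse = "")
        ok <- loop != prev2 &&
          (prev1 == "" || (!startsWith(prev1, loop) && !startsWith(loop, prev1) &&
                             !endsWith(prev1, loop) && !endsWith(loop, prev1)))
        if (ok) break
      }
      parts <- c(parts, loop, "GGG")
      blk_len <- blk_len + nchar(loop) + 3L
      prev2 <- prev1; prev1 <- loop
    }
    segments <- c(segments,
                  list(paste0("T", paste(parts, collapse = ""), "T")))
  }

  segments <- segments[sample.int(length(segments))]
  used <- sum(vapply(segments, nchar, integer(1)))
  filler_total <- len - used
  if (filler_total < 0) {
    # Overshoot can only come from the last (indivisible) G4 block wrap;
    # absorb it by trimming the longest tandem array.
    tl <- which.max(vapply(segments, nchar, integer(1)))
    segments[[tl]] <- substr(segments[[tl]], 1,
                             nchar(segments[[tl]]) + filler_total)
    filler_total <- 0
  }
  k <- length(segments)
  chunk_lens <- if (filler_total > 0) {
    as.vector(stats::rmultinom(1, filler_total, rep(1, k + 1)))
  } else rep(0L, k + 1)
  fillers <- vapply(chunk_lens, function(n) {
    if (n == 0) "" else paste(sample(BASES, n, replace = TRUE), collapse = "")
  }, character(1))
  out <- fillers[1]
  for (i in seq_len(k)) out <- paste0(out, segments[[i]], fillers[i + 1])
  stopifnot(nchar(out) == len)
  out
}

# Reserve non-overlapping intervals for focal-only regions, kept away from
# chromosome edges so mask windows behave simply.
reserve_private_intervals <- function(chrom_lengths, config, seed) {
  if (config$n_private_regions == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  withr::with_seed(child_seed(seed, "region-intervals"), {
    placed <- list()
    for (r in seq_len(config$n_private_regions)) {
      L <- sample(config$private_region_length_range[1]:
                    config$private_region_length_range[2], 1)
      ok <- FALSE
      for (try in seq_len(500)) {
        chr <- sample(names(chrom_lengths), 1, prob = chrom_lengths)
        if (chrom_lengths[[chr]] < L + 2 * MASK_WINDOW) next
        start <- sample.int(chrom_lengths[[chr]] - L - 2 * MASK_WINDOW, 1) +
          MASK_WINDOW
        end <- start + L - 1L
        clash <- any(vapply(placed, function(p) {
          p$chrom == chr && p$start <= end + 1 && p$end >= start - 1
        }, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place private region ", r, call. = FALSE)
      placed[[r]] <- list(region_id = sprintf("region%02d", r), chrom = chr,
                          start = as.integer(start), end = as.integer(end))
    }
    bind_rows(lapply(placed, as_tibble))
  })
}

#' Plant focal-only regions and strip them from every coverage mask
#'
#' Fills reserved intervals of the focal genome with composite sequence
#' (perfect tandem arrays + G-quadruplex motif blocks + random filler at the
#' configured composition) and removes the intervals from every comparison
#' breed's coverage mask, making the regions focal-only by construction.
#'
#' @param genome Named character vector (focal genome).
#' @param masks Coverage-mask tibble (`breed`, `chrom`, `start`, `end`).
#' @param config A [panel_config()].
#' @param seed Integer seed.
#' @param intervals Optional reserved interval tibble (`region_id`, `chrom`,
#'   `start`, `end`); chosen fresh when `NULL`.
#' @return List with `genome`, `masks` and `regions`, the truth tibble of
#'   planted regions with their as-built tandem and G4 fractions (measured
#'   with [tandem_fraction()] and [g4_fraction()]).
#' @export
plant_private_regions <- function(genome, masks, config, seed,
                                  intervals = NULL) {
  assert_genome(genome)
  if (is.null(intervals)) {
    intervals <- reserve_private_intervals(genome_lengths(genome), config, seed)
  }
  if (nrow(intervals) == 0) {
    return(list(genome = genome, masks = masks,
                regions = tibble(region_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 length = integer(),
                                 tandem_fraction_built = numeric(),
                                 g4_fraction_built = numeric())))
  }
  built <- withr::with_seed(child_seed(seed, "region-seq"), {
    vapply(seq_len(nrow(intervals)), function(i) {
      build_private_sequence(intervals$end[i] - intervals$start[i] + 1L,
                             config$private_region_tandem,
                             config$private_region_g4)
    }, character(1))
  })
  for (i in seq_len(nrow(intervals))) {
    chr <- intervals$chrom[i]
    genome[[chr]] <- paste0(
      substr(genome[[chr]], 1, intervals$start[i] - 1),
      built[i],
      substr(genome[[chr]], intervals$end[i] + 1, nchar(genome[[chr]])))
  }
  # Remove the intervals from every breed's mask; only chromosomes that
  # carry a planted region need editing.
  cut_chroms <- unique(intervals$chrom)
  untouched <- masks |> filter(!.data$chrom %in% cut_chroms)
  edited <- lapply(unique(masks$breed), function(b) {
    bind_rows(lapply(cut_chroms, function(chr) {
      mk <- masks |> filter(.data$breed == b, .data$chrom == chr)
      if (nrow(mk) == 0) return(NULL)
      cut <- intervals |> filter(.data$chrom == chr)
      ir <- IRanges::setdiff(IRanges::IRanges(mk$start, mk$end),
                             IRanges::IRanges(cut$start, cut$end))
      tibble(breed = b, chrom = chr, start = IRanges::start(ir),
             end = IRanges::end(ir))
    }))
  })
  masks_out <- bind_rows(untouched, bind_rows(edited)) |>
    arrange(.data$breed, .data$chrom, .data$start)

  regions <- intervals |>
    mutate(length = .data$end - .data$start + 1L,
           tandem_fraction_built = vapply(built, tandem_fraction, numeric(1),
                                          USE.NAMES = FALSE),
           g4_fraction_built = vapply(built, g4_fraction, numeric(1),
                                      USE.NAMES = FALSE))
  list(genome = genome, masks = masks_out, regions = regions)
}

#' Simulate a complete synthetic breed panel
#'
#' End-to-end generator: ancestral genome, planted genes, GO table,
#' focal-branch substitutions emitted as per-breed difference tables,
#' per-breed coverage masks, planted focal-only regions, and a ground-truth
#' record of everything planted.
#'
#' @param config A [panel_config()].
#' @return An object of class `breed_panel`: a list with `genome` (focal
#'   assembly), `gene_models`, `go_table`, `diffs`, `masks`, `truth` (lists
#'   `sites`, `coding_effects`, `regions`, `enriched_units`) and `config`.
#' @examples
#' \donttest{
#' cfg <- panel_config(chrom_lengths = c(chr1 = 60000), n_genes = 8,
#'                     n_breeds = 6, n_private_regions = 1, seed = 42)
#' panel <- simulate_panel(cfg)
#' nrow(panel$truth$sites)
#' }
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  seed <- config$seed
  genome0 <- generate_genome(config$chrom_lengths, config$gc_content, seed)
  intervals <- reserve_private_intervals(genome_lengths(genome0), config, seed)
  pg <- plant_genes(genome0, config, seed, forbidden = intervals)
  go_table <- make_go_table(sort(unique(pg$gene_models$gene_id)), config, seed)
  sim <- simulate_breed_differences(pg$genome, pg$gene_models, go_table,
                                    config, seed, forbidden = intervals)
  ppr <- plant_private_regions(sim$genome, sim$masks, config, seed,
                               intervals = intervals)
  structure(list(
    genome = ppr$genome,
    gene_models = pg$gene_models,
    go_table = go_table,
    diffs = sim$diffs,
    masks = ppr$masks,
    truth = list(sites = sim$truth$sites,
                 coding_effects = sim$truth$coding_effects,
                 regions = ppr$regions,
                 enriched_units = config$enriched_units),
    config = config
  ), class = "breed_panel")
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("<breed_panel>\n")
  cat("  genome:", sum(genome_lengths(x$genome)), "bp,",
      length(x$genome), "chromosome(s);",
      length(unique(x$gene_models$gene_id)), "genes\n")
  cat("  breeds:", x$config$n_breeds,
      " difference records:", nrow(x$diffs),
      " sites:", nrow(x$truth$sites),
      sprintf(" (%d focal-private)",
              sum(x$truth$sites$class == "focal_private")), "\n")
  cat("  focal-only regions:", nrow(x$truth$regions), "\n")
  invisible(x)
}
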