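# focalvar

Classification of breed-specific genomic variants from multi-genome panels,
with a length-bias-free binomial enrichment test, codon-level effect
annotation, and detection and content-profiling of long focal-only genomic
regions. A fully synthetic breed-panel simulator with machine-readable ground
truth makes the entire pipeline testable without any external genome
assemblies.

## The scientific problem

Comparing one *focal* genome assembly (for example, a newly sequenced
livestock breed) pairwise against a panel of related assemblies yields, at
each covered position, the focal allele and each comparison breed's allele.
Let **S** be the set of positions where the focal genome differs from at
least one comparison genome, and **U ⊆ S** the *focal-specific* subset —
positions whose focal allele appears in **no** comparison genome that covers
the site (a position is testable only when at least `min_breeds` assemblies
cover it; the default mirrors a 30-of-33 rule). Variants in U are candidate
footprints of the focal lineage's selection history.

To ask which genes or functional categories carry an excess of these private
mutations without favouring long genes, each unit is scored against its own
site count. With p = |U|/|S| and a unit containing n = |S′| sites of which
k = |U′| are focal-specific:

    p-value = P(X ≥ k),  X ~ Binomial(n, p)
    fold    = (|U′|/|S′|) / (|U|/|S|)

A unit passes when fold ≥ 2 and p-value < 10⁻³. Four unit constructions are
provided: per-gene missense, per-GO-category missense, gene ± 10 kb windows,
and GO-category windows; a density-fold statistic serves externally supplied
region lists (e.g. published selection-signature intervals).

Separately, maximal intervals covered by zero comparison breeds (≥ 1000 bp)
are reported as focal-only regions and profiled for perfect-tandem-repeat and
G-quadruplex (G4, motif `G{3,}N{1,7}G{3,}N{1,7}G{3,}N{1,7}G{3,}`, both
strands) content.

## Worked example

```r
library(focalvar)

cfg <- panel_config(
  enriched_units = tibble::tibble(unit_id = "GO:0000010",
                                  multiplier = 8, scope = "cds"),
  seed = 1)
panel <- simulate_panel(cfg)   # 33 breeds, 1 Mb focal genome, ground truth
res <- analyze_panel(panel)
res
#> <focalvar_analysis>
#>   |S| = 9311, |U| = 193, p = 0.02073 (min_breeds = 30)
#>   GENE_MISSENSE: 176 units, 0 pass
#>   GENE_FLANK10K: 200 units, 0 pass
#>   GO_MISSENSE: 20 units, 1 pass
#>   GO_FLANK10K: 20 units, 0 pass
#>   focal-only regions: 8

head(tidy(res$enrichment$GO_MISSENSE), 3)
#> # A tibble: 3 × 7
#>   unit_id        n     k  fold      p_value   p_adjust passes
#>   <chr>      <int> <int> <dbl>        <dbl>      <dbl> <lgl>
#> 1 GO:0000010   116    13  5.38 0.000000145  0.00000291 TRUE
#> 2 GO:0000007   121     6  2.38 0.0156       0.156      FALSE
#> 3 GO:0000016   134     6  2.15 0.0262       0.174      FALSE
```

The panel was built with 9,311 testable difference positions of which 193
(2.1%) are focal-private; the one GO category planted at 8× the private rate
is the only unit flagged (realized fold 5.4 against the mode universe —
the universe proportion itself is inflated by the planted signal — at
p ≈ 1.5 × 10⁻⁷), while the remaining 371 gene- and category-level tests stay
below both thresholds. The eight planted focal-only regions are recovered
with exact boundaries, with mean tandem fraction 0.74 and G4 fraction 0.23
versus genome-wide baselines of 0.031 and 0.006.

`simulate_panel_files()` / `analyze_panel_files()` run the same pipeline over
standard file formats (FASTA, GFF3, per-breed difference TSVs, mask BEDs, GO
TSV, truth JSON); `inst/cli/focalvar` wraps them as `simulate` / `analyze`
subcommands. Objects support `tidy()`, `glance()` and `autoplot()`.

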