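---
title: "Breed-specific variants and length-bias-free enrichment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-specific variants and length-bias-free enrichment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalvar)
```

## The problem

When one genome assembly (the *focal* breed) is compared pairwise against a
panel of assemblies from related breeds, the positions where the focal genome
differs from at least one comparison genome form a set **S**. Some of those
positions carry an allele found in no comparison genome at all; these
*focal-specific* (private) variants form the subset **U** and are the raw
material for asking which genes, functional categories and genomic regions
changed specifically on the focal lineage — for a livestock breed, the
signature of its recent selection history.

Two classification rules define U:

* **Presence**: a position is testable only if at least `min_breeds`
  comparison assemblies cover it (default: panel size minus 3, mirroring a
  30-of-33 rule). Incomplete assemblies otherwise masquerade as carriers of
  "absent" alleles.
* **Uniqueness**: the focal allele must be carried by *no* covered comparison
  breed. Difference tables use pairwise-difference semantics: a breed with no
  record at a covered position matches the focal allele, so a position is
  private exactly when every covered breed has a (differing) record there.

## The enrichment statistic

The naive "gene list" approach — test whether a gene *appears* in the mutated
set — systematically favours long genes, which accumulate more mutations by
chance. The test implemented here conditions on each unit's own site count
instead. With $p = |U|/|S|$ the genome-wide private proportion, a unit (gene,
GO category, gene ±10 kb window, or region) with $n = |S'|$ sites and
$k = |U'|$ private sites is scored by the exact upper binomial tail

$$\text{p-value} = P(X \ge k), \quad X \sim \mathrm{Binomial}(n, p),$$

with the effect-size filter

$$\text{fold} = \frac{|U'|/|S'|}{|U|/|S|} \ge 2, \qquad \text{p-value} < 10^{-3}.$$

Because $n$ scales with gene length under the null, the pass probability does
not: the length-bias control is structural, and the test suite verifies it
empirically (rank correlation between gene length and pass rate under the
null stays below 0.2 in absolute value across 20 simulated panels).

Four unit constructions are provided (`run_enrichment()` modes): per-gene
missense, per-GO-category missense, per-gene ±10 kb windows and per-category
±10 kb windows. In each mode the universe S is rebuilt as the union of that
mode's unit sites, so $p$ is always the proportion the units are judged
against. Where the boundary convention was ambiguous we test fold ≥ 2 (the
threshold is configurable), apply no multiple-testing correction to the pass
flag (a Benjamini–Hochberg column is emitted as side information only), use
the GO table flat without ancestor propagation, and define a gene's window
as gene body plus 10 kb on each side. A position inside two genes counts once
in the universe but contributes to both genes' unit sets, keeping the null
proportion coherent per position.

## Effect annotation

The annotated genome is the focal assembly, so the genome codon is the
*alternate* codon; the *reference* codon substitutes the comparison-panel
consensus allele (majority among covered differing breeds, alphabetical
tie-break). Codons are reconstructed in transcript orientation (reverse
complement on the minus strand) and translated with the standard genetic
code. Change strings are lowercase — `"cgt > ctt"`, `"r > l at 643"` — with
1-based protein positions. Splice-site variants are intronic positions within
2 bp of an exon boundary (the canonical donor/acceptor dinucleotides; the
window is configurable since conventions differ). Stop-gain/loss variants are
reported as their own classes and excluded from the missense sets used by
enrichment, with a `merge_stop_classes` switch to fold them in. One
transcript per gene is assumed; with alternative transcripts a most-severe
rule would be needed and is out of scope.

## Focal-only regions and their content

Long intervals covered by **zero** comparison breeds are detected purely
from the coverage masks (`find_specific_regions()`, default minimum 1000 bp,
maximal by construction) and only then profiled on sequence:

* `g4_fraction()` — Quadparser-style canonical G-quadruplex motif
  `G{3,}N{1,7}G{3,}N{1,7}G{3,}N{1,7}G{3,}`, scanned on both strands; the
  fraction is the union footprint of *all* matches. The scanner is an exact
  dynamic programme over (match start, G-runs remaining): for every start it
  computes the maximal reachable match end, whose union equals the union over
  all decompositions; a greedy regex would not guarantee that. Literal `N`
  never matches. Run length 3 and loop cap 7 are conventional defaults; no
  specific published detector is being reproduced.
* `tandem_fraction()` — maximal *perfect* tandem arrays found by periodicity
  scan, unit length 1–50, array length at least `max(2 × unit, 10)` bp
  (two full copies, partial trailing copy allowed; a homopolymer needs 10 bp).
  Approximate, mutation-tolerant repeats in the TRF sense are a non-goal.

A base may count in both fractions: the two annotations are computed
independently, matching how overlapping content percentages are reported in
practice.

## The synthetic panel generator

Real multi-breed assembly panels are gigabases of external data; the
generator replaces them with a fully synthetic panel whose ground truth is
known exactly, so every downstream rule is testable offline.

* **Phylogeny**: a star — each comparison breed derives independently from a
  common ancestor. Every difference site is a substitution on the focal
  branch. *Shared-variation* sites also hand the focal allele to a random
  non-empty proper subset of breeds (size uniform on 1..n−1, anchored at a
  breed that covers the site), which makes them non-specific by
  construction; *focal-private* sites are carried by the focal genome alone.
  Tree-shaped allele sharing is deliberately out of scope: the star is
  sufficient to exercise the specificity logic.
* **Rates**: the per-base site rate is calibrated so the realized pairwise
  difference fraction against one breed matches `background_diff_rate`
  (default 0.005, the scale of published per-base divergences between
  chicken breeds of 0.44–0.61%). The focal-private fraction among sites
  defaults to 0.02; inside each configured enriched unit it is multiplied by
  the unit's factor. Substitutions are uniform over the three alternative
  bases; indels are not simulated (the specificity analysis is defined on
  single-nucleotide variants).
* **Genes**: multi-exon CDS with ATG start, single terminal stop, no
  in-frame internal stop, canonical GT/AG introns, roughly half on the minus
  strand; spliced lengths 300–3000 bp by default, giving the 10× length
  spread the bias tests need. Per-site truth effects are computed by
  re-translating the entire mutant CDS and diffing proteins — deliberately a
  different route from the codon-level annotator, so each checks the other.
* **Coverage**: each breed's mask drops independent 1 kb windows with
  probability 0.03, emulating alignment-block dropout at a level where a
  33-breed panel usually retains the 30-breed presence floor.
* **Focal-only regions** (default 8 per panel, 1000–4857 bp, the published
  length range) are reserved intervals of the focal genome filled with
  composite sequence — perfect tandem arrays, one long chained G4 block, and
  random filler — and removed from every breed's mask. Replacing a reserved
  interval rather than physically inserting sequence keeps all other
  coordinates stable while producing the same observable: present in the
  focal assembly, uncovered by every comparison breed. Real focal-only
  regions have been reported with *overlapping* content (90.5% tandem and
  23.2% G4 — G4s inside G-rich tandem arrays); the generator builds disjoint
  blocks, so its targets must sum to at most 1. The defaults keep G4 at the
  reported level and tandem as high as the disjoint construction allows
  (tandem 0.72, G4 0.23). Tandem units are constrained to produce no G- or
  C-triplet when tiled, and G4 loops may not repeat back-to-back, so the two
  content classes stay separable to within ±0.05 — the tolerance the
  round-trip tests assert.
* **Determinism**: all randomness flows from one seed through derived
  per-stream seeds; identical configurations produce byte-identical bundles.

What the generator does *not* emulate: linkage and recombination, tree-shaped
breed relatedness, indels and structural variants other than the planted
regions, alignment error, GC-content heterogeneity along the genome, and
approximate repeats. Passing tests therefore demonstrate the correctness of
the classification, annotation, statistic and detectors under their stated
models — not robustness to alignment artifacts in real panels.

## Problem sizes and numerical choices

The simulation studies in the test suite use 1 Mb genomes with 200 genes, 20
GO categories and 33 comparison breeds — the point where all binomial
behaviour of interest (planted 8× categories with ≥ 30 missense sites, ≥ 4000
null unit tests) is observable while a full study of 40 panels completes in
minutes on one core. The acceptance script analyzes one such default panel
end to end. p-values come from the exact tail (`pbinom` upper tail; `k = 0`
returns 1); there are no continuity corrections; units with no sites are
skipped rather than scored; a degenerate universe with no private variants
(`p = 0`) reports fold as `NA` and p-value 1. Ties in the panel-consensus
reference allele break alphabetically. Interval arithmetic is half-open
internally (IRanges) and converted to 1-based inclusive coordinates at every
user-facing boundary; BED output is 0-based half-open; GFF3 is 1-based with
phase checked on read.

## A worked example

```{r example, eval = FALSE}
library(focalvar)

cfg <- panel_config(
  enriched_units = tibble::tibble(unit_id = "GO:0000010",
                                  multiplier = 8, scope = "cds"),
  seed = 1)
panel <- simulate_panel(cfg)
res <- analyze_panel(panel)

glance(res)                      # set sizes, p, passes per mode
tidy(res$enrichment$GO_MISSENSE) # per-category table, sorted by p-value
autoplot(res$enrichment$GO_MISSENSE)
autoplot(res$region_profile)     # G4 vs tandem content per focal-only region
```

## Known limitations

* The star phylogeny makes private variants easier to separate than a real
  breed tree would; shared-by-descent alleles in nested clades are absent.
* Only perfect tandem arrays are detected; diverged repeats lower the
  reported tandem fraction of real sequence.
* The G4 scanner implements one canonical motif; non-canonical quadruplexes
  (two-run bulged, long-loop) are not counted.
* One transcript per gene; overlapping gene models are handled, alternative
  isoforms are not.
* The enrichment test treats sites as independent; clustered mutations
  (e.g. in repeat tracts) can inflate significance on real data.
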