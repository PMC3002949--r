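---
title: "Constructing copy-number variant region maps from two-caller CNV calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing copy-number variant region maps from two-caller CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrmap)
```

## The problem

Copy-number variations (CNVs) — losses and gains of genomic segments
relative to the diploid state — are called from SNP-array intensity data
by segmentation algorithms whose concordance with one another is known to
be poor. A practical remedy is to require *congruent* evidence: a CNV is
trusted only when two independent algorithms report overlapping calls with
the same direction of effect (loss vs. gain) in the same individual.
Across many individuals, the surviving CNVs cluster into copy-number
variant regions (CNVRs): genomic territories where structural variation
recurs in a population. A CNVR map — per population, and a cross-population
map restricted to regions seen in both populations — gives downstream
association studies a frequency-annotated reference of common structural
variation.

`cnvrmap` implements this construction end to end: reading caller output,
the two-caller congruency merge, single-linkage CNVR clustering, map
intersection across populations, gene and catalog annotation, and
population-difference statistics, together with a ground-truthed synthetic
data generator that makes every stage testable without access to raw array
data.

## The procedure and its assumptions

**Congruency merge (per individual).** Calls from caller A and caller B are
compared pairwise on each chromosome. Two calls *overlap* when they share
at least one base (coordinates are 1-based and fully inclusive; intervals
that merely touch end-to-end, `end + 1 == start`, do not overlap). Pairs
with opposite directions are removed; calls never overlapped by the other
caller are discarded — a CNV not even partially detected by the second
algorithm is treated as unsupported. The surviving concordant calls are
merged: connected components of the overlap graph become single CNVs
spanning the union of their supporting calls. Every input call therefore
ends in exactly one of three bins — absorbed into a merge,
discordant-removed, or unsupported-removed — and the per-individual and
total counters must reconcile exactly; the pipeline asserts this
conservation on every run.

Two details of the removal accounting are genuinely underdetermined and are
therefore configuration options rather than fixed behaviour:

* `discordance_policy = "partner_rescue"` (default): a call in a
  discordant pair survives if it retains at least one concordant partner;
  only calls whose every partner disagrees are counted discordant.
  `"remove_both"` removes both members of any discordant pair outright.
* `merge_span = "union"` (default) takes the outer span of a merge
  component; `"intersection"` intersects the two callers' spans.

**CNVR clustering (per population).** Merged CNVs from all individuals of
a population are clustered by single linkage under the same ≥1 bp overlap
rule: connected components of the interval-overlap graph. A component
becomes a CNVR only when it contains CNVs from at least two *distinct
individuals* (`min_individuals = 2`) — frequency counts individuals, not
events, so one individual's fragmented calls can never found a CNVR on
their own. By default gains and losses cluster jointly into one region
with per-direction member counts retained (`direction_mode =
"direction_agnostic"`); a stratified mode building separate gain- and
loss-CNVRs is available, since either reading is defensible. CNVRs within
a map are pairwise non-overlapping by construction and sorted by position.

**Cross-population map.** The CNVRs of the two population maps are pooled
and re-clustered; clusters containing CNVRs from *both* maps become
cross-population CNVRs (union span by default, intersection by
configuration). Because each contributing CNVR already carries ≥2
individuals, every cross-population CNVR rests on at least 2×2 CNV events.

**Annotation and comparison.** Gene screening reports every (gene, CNVR)
pair sharing ≥1 bp, using full gene spans, and partitions affected genes
into shared and population-specific sets. Catalog comparisons count
catalog records overlapping the map, the CNVRs hit, and the novel CNVRs;
map-to-map comparisons report both directional counts because they differ
in general. Per-individual cross-platform concordance requires the overlap
to occur in the *same individual*.

**Population statistics.** Per-individual CNV counts and mean lengths are
compared between populations with two-sided Mann-Whitney U tests;
Shapiro-Wilk normality p-values are recorded per group as justification
metadata rather than as an automatic gate, since CNV count and length
distributions are essentially never normal. Individuals with more than
500 caller-reported CNVs are flagged and excluded from the comparisons:
such counts indicate caller over-fragmentation or misclassification. The
threshold applies to raw per-caller counts — over-fragmentation is a
caller phenomenon — and flagged individuals are retained in the data,
merely excluded from testing.

## Tunable parameters

| Key | Default | Meaning |
|---|---|---|
| `overlap_mode` / `reciprocal` | `any_bp` | ≥1 bp overlap everywhere; a reciprocal-fraction mode exists for sensitivity analyses |
| `merge_span` | `union` | span of a merged CNV |
| `discordance_policy` | `partner_rescue` | removal accounting for direction-discordant pairs |
| `min_individuals` | 2 | distinct individuals required to form a CNVR |
| `direction_mode` | `direction_agnostic` | cluster gains and losses jointly or separately |
| `cp_span` | `union` | span of cross-population CNVRs |
| `exclusion_threshold` | 500 calls | per-individual cap before exclusion from statistics |
| `genome_build` | `hg18` | build tag checked when maps/catalogs are combined |

Internal coordinates are 1-based inclusive (the convention in which CNV
regions are usually printed), with exact, invertible conversion to 0-based
half-open BED at the I/O boundary. Chromosome names are stored without the
`chr` prefix and the analysis is restricted to autosomes throughout; sex
chromosome records are dropped (and counted) at parse time. Copy-neutral
records (`cn = 2`) are rejected at parse time because the procedure only
manipulates gains and losses; multi-state copy numbers are collapsed to
loss/gain, retaining the magnitude in `copy_number`. Genome-fraction
computations default to bundled NCBI36/hg18 autosome lengths and are
overridable for other builds or toy genomes.

## The synthetic-data generator

The generator (`synthetic_truth()` / `generate_synthetic_data()`) emulates
the statistical structure the analysis assumes, not raw array data:

* a toy genome of 4 autosomes × 10 Mb — large enough for dozens of
  non-colliding loci, small enough for instant tests;
* 20 planted CNVR loci (8 shared between populations, 6 specific to
  each), placed ≥100 kb apart, with log-normal lengths (median 100 kb,
  log-sd 0.5, clamped to 20–500 kb) and a fixed direction per locus;
* independent per-individual carrier sampling at per-population
  frequencies drawn from 0.05–0.4 (no linkage or relatedness — the
  simplest structure consistent with frequency-based treatment);
* caller noise: fragmentation probability 0.3 (caller A) vs 0.05
  (caller B), splitting an event into two segments with a 100–500 bp
  interior gap; Gaussian boundary jitter (sd 2 kb); caller-private false
  positives (Poisson, 5 per individual per caller, log-normal lengths,
  median 8 kb); and a direction-flip rate of 0.02 under which one caller
  reports the opposite direction for an event;
* scenario presets: `noise_free` (all noise off — the merge output must
  equal the planted carrier events exactly), `calibration` (40 shared
  loci at frequency 0.35, flip rate 0.10, no other noise, guaranteeing
  >2000 locus-derived call pairs for discordance-rate recovery), and
  `african_shift`, which adds population-specific background CNVs
  (negative-binomial counts, mean 30 vs 60 per individual; log-normal
  lengths, median 100 kb vs 40 kb) reproducing the Sub-Saharan pattern of
  more, shorter CNVs, plus hypervariable individuals that must trip the
  500-call exclusion;
* every emitted call carries exactly one truth label (`locus`,
  `background`, `hypernoise`, `false_positive`), and generation is fully
  deterministic given the seed.

The count and length distributions are modelling choices, not empirical
claims; their defaults were fixed once at values a array-CNV practitioner
would consider realistic for common variation. What passing tests on this
generator demonstrate is that the *procedure* is implemented correctly —
conservation, recovery of planted loci under calibrated noise, rate
recovery — not that real SNP-array data satisfies the generator's
independence assumptions. Real data add marker-grid quantization, waviness
and batch effects, genotyping-intensity artefacts, LD between nearby
variants, and relatedness, none of which are modelled.

```{r, eval = FALSE}
res <- run_synthetic_pipeline("default", seed = 1)
res$score$summary      # recall/precision of SW, RW, CP maps vs planted loci
res$result             # merged-CNV and CNVR counts per map
```

## Scoring recovery

A planted locus is *expected* in a population map only when at least two
distinct individuals of that population carry it — a locus with fewer
carriers cannot form a CNVR under the map's own ≥2 rule — and in the
cross-population map when it is shared and carrier-supported in both
populations. Expected loci are matched to map CNVRs by Jaccard overlap
(intersection over union of the 1-based intervals); the default detection
threshold is 0.5, and noise-free runs are required to reach Jaccard 1.0
exactly.

## Numerical and degenerate-input choices

* Ties: intervals sharing exactly one base overlap; book-ended intervals
  do not. This boundary is exercised explicitly in the tests.
* Within-caller overlapping calls for one individual (possible with
  fragmented caller output) violate the segmentation precondition; they
  are pre-merged per chromosome and direction with a logged warning, and
  the conservation counters are stated in terms of the pre-merged calls.
* Empty inputs are valid everywhere: empty call files parse to empty
  tables with zeroed reports, an empty merged set builds an empty map,
  and an empty map has genome fraction 0.
* The Mann-Whitney implementation uses the exact distribution below 50
  per group without ties and the normal approximation with continuity
  and tie correction otherwise; tests pin the U statistic to the
  exhaustive pair-count definition for all group sizes ≤ 12.
* Clustering is a sorted sweep per chromosome (an interval starting
  beyond the running maximum end opens a new cluster), which is exactly
  single-linkage under the ≥1 bp rule; it is cross-checked against a
  quadratic union-find reference and against `GenomicRanges::reduce`.

## Problem sizes used by the test-suite

The property tests run the quadratic references against the
implementation on more than a thousand randomized instances of up to ~40
calls per caller, and the synthetic studies use 100 individuals per
population with 20 planted loci — sizes chosen so the whole suite
completes in a few minutes while still exercising every code path at
population scale.

## Known limitations

* Two callers only; no three-or-more-caller consensus and no
  confidence-weighted reconciliation.
* No CNVR genotyping (per-individual integer copy numbers within a
  region) and no breakpoint refinement.
* No liftover: maps and catalogs must share a genome build (the tag is
  checked; the check can be overridden deliberately).
* Heterozygosity and similar per-individual metrics arrive precomputed;
  the package does not compute them from genotypes.
* The removed-call accounting for discordant pairs is configurable
  because the choice is not uniquely determined; results reported with
  one policy should state it.
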