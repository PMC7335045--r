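---
title: "Promoter Capture-C variant-to-gene mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter Capture-C variant-to-gene mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcv2g)
```

## The problem

Most GWAS risk variants are non-coding and sit in large linkage
disequilibrium (LD) blocks, so neither the causal variant nor its effector
gene can be read off the association signal. `capcv2g` implements a
physical variant-to-gene (V2G) mapping strategy for this problem: ATAC-seq
open chromatin restricts the candidate variants to those a cell's
regulatory machinery can actually reach, and promoter-focused Capture-C
chromatin contacts assign each accessible variant to the promoter(s) its
chromatin neighbourhood physically touches. The approach treats reported
disease variants as signposts in healthy tissue; it does not estimate
variant effects.

The workflow has five analysis layers, each an independent module with its
own tested surface:

1. **Genome scaffold** — DpnII (`GATC`) restriction fragment maps at
   single-fragment and concatenated 4-fragment resolution, strand-aware
   promoter windows, bait flags.
2. **OCR atlas** — replicate ATAC peak calls are union-merged per cell
   type, peaks seen in fewer than two replicates are discarded, cell types
   are union-merged into non-overlapping reference open chromatin regions
   (OCRs), and per-cell-type openness is called. A counts-per-million
   (CPM) retention rule screens OCRs for downstream quantitative work.
3. **Interaction projection** — significant fragment-level interaction
   calls from the two resolutions are merged (identical coordinate pairs
   keep the maximum score) and projected onto OCR pairs; each end is
   classed `prOCR` (overlaps a promoter window) or `nonprOCR`, and pairs
   with no promoter end are removed.
4. **Variant mapping** — proxy SNPs filtered by LD with their sentinel are
   intersected with open chromatin; accessible variants acquire genes via
   two routes (promoter residency, and chromatin contact to a partner OCR
   overlapping a promoter window) and are categorized against their
   nearest gene.
5. **Enrichment statistics** — an empirical resampling test compares the
   V2G sentinel-gene pairs with eQTL catalogs, and a one-sided Fisher
   statistic serves generic feature-enrichment queries.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| promoter window | −1500/+500 bp of TSS, strand-aware | defines "promoter" everywhere (baits, prOCR, gene assignment) |
| interaction score threshold | 5 (inclusive) | significance cut on the upstream caller's score |
| replicate support | ≥ 2 replicates | reproducibility filter on merged ATAC peaks |
| CPM rule | ≥ 1.5 CPM in ≥ 50% of samples | count-based OCR retention before quantitative analysis |
| LD thresholds | r² ≥ 0.8 (tight), r² ≥ 0.4 (relaxed) | proxy inclusion; both inclusive |
| candidate pool window | ± 5 Mb of each sentinel | null model gene universe for the overlap test |
| resampling repetitions | 100,000 | Monte-Carlo null for the eQTL overlap test |

All of these are arguments (or `sim_config()`/`default_config()` fields),
so sensitivity analyses are one keyword away.

## Design choices where the procedure was genuinely open

* **Coordinates.** All in-memory intervals are `GRanges` (1-based,
  closed) — the Bioconductor idiom — while every file format keeps its
  native convention (BED/rmap 0-based half-open, ibed and SNP positions
  1-based) and is converted at the I/O boundary. Overlap is ≥ 1 bp of
  intersection everywhere.
* **Inclusive thresholds.** The score cut keeps `score >= 5` and the LD cut
  keeps `r2 >= threshold`. Published analyses of this design describe the
  cuts as "greater than" yet retain boundary cases (e.g. an r² = 0.8
  proxy), so the inclusive reading is used and both are configurable.
* **Bookended intervals merge.** Peak merging coalesces touching intervals
  (distance 0), mirroring the default behaviour of the standard
  interval-merging tools the field uses.
* **"Top 50% of samples".** The CPM rule is read as: at least half of the
  samples must individually reach 1.5 CPM. A rank-based reading ("the
  better half of samples") collapses to the same decision whenever the
  threshold count is compared against `ceiling(n/2)`, but the per-sample
  reading matches the stated read-count equivalent and is what
  `cpm_filter()` implements; both the threshold and the fraction are
  arguments.
* **Merge redundancy = exact coordinate identity.** When combining 1- and
  4-fragment calls, only records with identical end coordinates (after
  orienting the lower-coordinate end first) are redundant. A 1-fragment
  call nested inside a 4-fragment span is kept as a separate record:
  projection unions their evidence anyway, so nothing is lost and the
  maximum score per coordinate pair is preserved exactly.
* **Distance between OCRs** is the absolute difference of interval
  midpoints — symmetric in the two ends and anchor-free.
* **Nearest gene** is the gene with the smallest `|TSS − SNP|` over its
  annotated transcripts, computed from the SNP position; ties break to the
  lexicographically smallest gene id. The gene universe defaults to genes
  with captured promoter windows (`gene_universe = "captured"`); `"all"`
  uses the full annotation.
* **Promoter residency is a separate route.** A SNP sitting in a promoter
  OCR does not, by itself, put that gene into the SNP's interaction-derived
  gene set; the two routes are tabulated separately, and only
  interaction-route genes drive the nearest-gene categories
  (`nearest_only` / `nearest_plus_distant` / `skip`).
* **Resampling without replacement.** Each null repetition draws a set of
  distinct sentinel-gene pairs, mimicking the observed (deduplicated) pair
  set; the observed pairs are *not* excluded from the pool. Both choices
  are `empirical_overlap_test()` switches. The empirical p-value uses the
  add-one correction `(1 + #[null ≥ obs]) / (reps + 1)` so a Monte-Carlo p
  is never exactly zero, and "expected overlap" is the null mean.
* **Bait-to-bait interactions** are projected like any other pair —
  promoter-promoter contacts are a substantial fraction of real promoter
  interactomes and must not be dropped.

## What the synthetic generator emulates

`simulate_study()` builds a toy study around isolated locus blocks, one
per planted accessible proxy. A block carries a nearby gene, a distant gene
(60–125 kb away, inside the 1 kb–1.5 Mb cis range of real promoter
interactomes), a non-promoter source OCR holding the SNP, promoter OCRs
over both TSSs, a weak OCR with low counts, and an irreproducible peak
emitted in a single replicate. The planted category of the block — drawn to
an exact largest-remainder realization of the configured 8.5/29/62.5% mix —
decides which promoter(s) the source OCR contacts. Cut sites are placed at
a Poisson density of 4/kb, matching a four-cutter's ~250 bp median
fragment. Interaction records are emitted at one or both resolutions
(4-fragment records span the bins containing their 1-fragment anchors) with
scores above the threshold, alongside sub-threshold decoys; r² values
straddle the 0.8 boundary so threshold sweeps are informative; the eQTL
list contains an exactly known number of realized sentinel-gene pairs plus
decoys whose genes do not exist in the annotation.

Planted pipeline-critical OCRs appear in **every** replicate, so the
two-replicate filter never removes them and the per-SNP category truth is
exact; reproducibility noise is carried by the weak and irreproducible
peaks instead. That is a deliberate trade: it makes recovery tests sharp,
at the cost of not modelling stochastic loss of true signal.

Features of real data the generator does **not** emulate — and which
passing tests therefore say nothing about: distance-decay of contact
frequencies and polymer structure, LD haplotype structure beyond an
assigned r², capture-probe efficiency, trans interactions, overlapping
gene annotations and nested promoters, blacklist artefacts, and read-level
noise (counts are Poisson around fixed open/closed rates).

## Numerical and degenerate-input conventions

* Digestion requires strictly increasing cut sites inside the chromosome;
  a motif hit flush at position 0 adds no boundary. Fragments always tile
  `[0, length)` exactly (asserted at both resolutions).
* Promoter windows are clipped at chromosome edges; a window is at most
  2000 bp.
* Empty inputs flow through: empty interaction tables, empty eQTL sets
  (observed 0, p = 1), and proxies on chromosomes without OCRs or
  annotation are all defined, not errors — except where the result would
  be meaningless (no transcripts on a SNP's chromosome for nearest-gene,
  pool smaller than the draw).
* The odds ratio is the cross-product estimate and is reported as
  undefined (`NA`) when a denominator is zero; the hypergeometric p is
  still computed.
* Outputs are deterministically ordered (chromosome, coordinates,
  identifiers), and every stage is reproducible byte-for-byte given the
  seed.

## Problem sizes used by the shipped checks

The default simulated study uses 200 loci on 4 chromosomes (~32 Mb,
~128,000 fragments), 260 proxies, and 100,000 resampling repetitions —
a single run takes on the order of ten seconds. The test suite
additionally runs a 2000-locus cohort for category recovery, 100
randomized projection instances against an exhaustive oracle, and a
500-dataset × 500-repetition uniformity check of the empirical p-value,
chosen as the smallest sizes at which the statistical assertions have
comfortable error margins.

## Known limitations

* The upstream statistical machinery is out of scope by design: peak
  calling, interaction-score modelling, LD estimation, differential
  accessibility and expression, and colocalization are all consumed as
  inputs, never recomputed.
* The three-way nearest-gene classification assigns exactly one label per
  interaction-connected proxy; variants whose only evidence is promoter
  residency are reported but uncategorized.
* Gene symbol matching in the eQTL comparison is case-folded string
  equality; synonymous symbols must be harmonized upstream (id-based
  matching is available where ids are present on both sides).
* With multi-sentinel proxies the V2G table keeps one row per sentinel;
  enrichment testing deduplicates at sentinel-gene level, so a gene
  reachable from two sentinels counts twice there by construction.
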