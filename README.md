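# capcv2g — variant-to-gene mapping from promoter Capture-C and ATAC-seq

`capcv2g` implements a physical **variant-to-gene (V2G)** mapping workflow
for GWAS loci. Most disease-associated variants are non-coding and tagged
by large LD blocks, so the affected gene cannot be read from the
association signal alone. This package integrates three layers of evidence
to assign candidate effector genes in a disease-relevant cell type:

1. **Open chromatin (ATAC-seq).** Replicate peak calls are union-merged
   per cell type; merged peaks seen in fewer than two biological
   replicates are removed; cell types are merged into a non-overlapping
   reference atlas of open chromatin regions (OCRs), each with
   per-cell-type openness calls. A CPM retention rule
   (≥ 1.5 counts-per-million in at least half the samples) screens OCRs
   for quantitative work.
2. **Promoter contacts (promoter-focused Capture-C).** The genome is cut
   in silico into DpnII (`GATC`) restriction fragments, analysed at
   single-fragment and concatenated four-fragment resolution. Significant
   interaction calls (score ≥ 5) from both resolutions are merged —
   identical coordinate pairs keep the maximum score — and projected onto
   OCR pairs: a pair is reported when the interacting fragments overlap
   two OCRs that are both open in the cell type, and at least one end
   overlaps a promoter window (−1500/+500 bp of a TSS, strand-aware).
3. **GWAS variants.** Proxy SNPs with r² ≥ 0.8 (tight) or ≥ 0.4 (relaxed)
   to a sentinel are intersected with open chromatin. Accessible variants
   gain genes by two routes: *promoter residency* (the SNP sits inside a
   gene's promoter window) and *interaction* (the SNP's OCR contacts a
   partner OCR overlapping a gene's promoter). Each interaction-connected
   variant is categorized against its nearest gene (by TSS distance) as
   `nearest_only`, `nearest_plus_distant`, or `skip`.

The statistical overlap between the resulting sentinel–gene pairs and
eQTL catalogs is tested with an **empirical resampling null**: genes with
a TSS within ±5 Mb of each sentinel form a candidate pool, equally sized
random pair sets are drawn (100,000 repetitions), and the observed overlap
is compared against the null with an add-one Monte-Carlo p-value and a
fold enrichment (observed / null mean).

A first-class, seeded **synthetic-data generator** (`simulate_study()`)
writes a complete toy study — peak BEDs, count matrix, rmap/baitmap and
ibed files, transcript and SNP tables, eQTL lists — with a recorded truth
table, so the entire pipeline is exercised end to end without any external
download.

## Worked example

Run the whole pipeline on a simulated study (200 planted accessible
variants with an 8.5/29/62.5% category mix, two cell types, three ATAC
replicates each):

```r
library(capcv2g)
cfg <- default_config(seed = 1, out_dir = tempfile("v2g_run"))
state <- run_pipeline(cfg)
#> [capcv2g] simulated study: 200 loci, 260 proxies, seed 1
#> [capcv2g] digest: 128261 fragments, 32067 bins, 436 promoter windows
#> [capcv2g] atlas: 743 reference OCRs (tfh open: 700, naive open: 510); 601 pass the CPM filter
#> [capcv2g] project (tfh): 179 + 174 calls -> 353 merged -> 258 OCR interactions
#> [capcv2g] variants: 260 proxies in -> 230 at r2 >= 0.40 -> 200 accessible -> 258 pairs (258 genes) -> 200 categorized
#> [capcv2g] eqtl-test: observed 12, null mean 0.905, fold 13.26, p 1e-05

state$v2g$category_summary
#>               category   n fraction
#> 1         nearest_only  17    0.085
#> 2 nearest_plus_distant  58    0.290
#> 3                 skip 125    0.625

state$eqtl_test
#> Empirical overlap test
#>   observed overlap : 12 (of 258 drawn pairs)
#>   null mean        : 0.905 (100000 reps)
#>   fold enrichment  : 13.26
#>   empirical p      : 1e-05
```

Reading the output: of 260 proxy SNPs, 200 fall in open chromatin after LD
filtering; projection links their OCRs to 258 target genes; only 8.5% of
the variants contact exclusively their nearest gene, while 62.5% *skip*
the nearest gene entirely — the planted mix, recovered exactly. The
12 sentinel–gene pairs shared with the synthetic eQTL list are ~13-fold
more than the 0.9 expected under random pairing (empirical p = 1e-5, the
smallest value 100,000 repetitions can resolve).

The bundled worked comparison against a 41-pair eQTL catalog (14 shared
gene symbols — ANKS1A … FAM219B; all other rows synthetic placeholders):

```r
ex <- eqtl_overlap_example()
overlap_statistic(ex$v2g, ex$eqtl)
#> [1] 14        # 14/41 = 34%
```

Every stage is also available as a plain function (`fragment_map()`,
`merge_replicate_peaks()`, `project_to_ocr()`, `v2g_map()`,
`empirical_overlap_test()`, …) and from the shell via
`inst/scripts/capcv2g.R <stage> --config config.yaml`.

## Layout

```
R/                      genome model, OCR atlas, interaction projection,
                        variant mapping, enrichment stats, synthetic data,
                        pipeline orchestration
inst/extdata/           worked-example pair lists (text, partly synthetic)
inst/scripts/capcv2g.R  command-line wrapper
tests/testthat/         unit, property and acceptance suites
vignettes/              methods vignette (model, parameters, design choices)
scripts/acceptance.R    end-to-end reproduction script
```
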