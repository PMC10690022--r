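# nmdx

Diagnostic genomics toolkit for neuromuscular disease (NMD) cohorts.

Genetic diagnosis transforms care for the ~15 million people with
neuromuscular diseases — it enables counselling, complication screening
and, increasingly, gene-specific therapy — yet most published variant
data come from European-ancestry cohorts, and multinational diagnostic
programmes in under-represented populations keep their patient-level
data under controlled access. `nmdx` is for methodologists and pipeline
developers who need that diagnostic workflow as *tested, reusable
code*: it pairs every analysis stage with a synthetic-cohort generator
that plants known diagnoses, so the whole pipeline can be validated by
exact recovery of the planted truth.

## What it implements

* **Synthetic cohorts with planted truth** — probands (diagnostic
  category, sex, age, HPO terms), variant observations, and per-proband
  ground-truth outcomes, drawn from configurable mixtures whose defaults
  emulate a large multinational NMD cohort (LGMD 18.1%, PN 15.5%,
  CM/CMD 9.4%, DMD/BMD 8.6%; 65% male; median age 26 with 35% ≤ 18;
  29% of causal variants novel).
* **Variant prioritization** — phenotype/panel matching by HPO overlap,
  inheritance-specific minor-allele-frequency filters (max frequency
  across catalogs strictly < 0.01 for AR, < 0.001 for AD/XL genes), and
  zygosity-consistency rules (biallelic for recessive disease:
  homozygous or ≥ 2 heterozygous variants).
* **ACMG classification and outcomes** — an evidence-combining engine
  driven by a packaged, enumerable rule table; outcomes *solved* (all
  causal variants Pathogenic/Likely pathogenic, phenotype fit),
  *possibly solved* (ultra-rare < 0.01% supported VUS candidate) or
  *unsolved*; novelty = absence of the gene + HGVS.c key from every
  reference catalog.
* **Dystrophin (DMD) engine** — the reading-frame rule over a packaged
  79-exon Dp427m coding-length table: a deletion/duplication of exons
  *a..b* is in frame iff `sum(len[a:b]) %% 3 == 0` (inapplicable when
  the interval touches exon 1 or 79); severity prediction
  (out-of-frame → Duchenne-like, in-frame → Becker-like); intron
  breakpoint hotspot summaries; single-exon skipping amenability for
  licensed ASO target exons 45/51/53 and trial exon 44.
* **Cohort statistics** — yield tables, causal-gene frequencies (PMP22
  del/dup/point tracked separately), novel-variant fractions, and an
  exact Fisher test for r×c contingency tables implemented from first
  principles (full margin-conditional enumeration with a log-factorial
  cache; probability-mass two-sided definition; Monte-Carlo fallback
  for large tables).

## Worked example

```r
library(nmdx)
cfg <- cohortConfig(seed = 7)
res <- runPipeline(cfg, n = 300, nDmd = 104)
#> [nmdx] simulate: 300 probands (seed 7)
#> [nmdx] simulate: 2005 variants, 1947 catalog entries
#> [nmdx] classify: 131 solved, 37 possibly solved, 132 unsolved
#> [nmdx] dmd: 104 records, hotspot fraction 0.656, Fisher p 2.37e-06

res$yield[, c("n", "solved", "possibly_solved", "pct_combined_display")]
#>     n solved possibly_solved pct_combined_display
#> 1 300    131              37                   56
```

131 of 300 probands are solved and 37 possibly solved — a combined 56%,
matching the configured expectation — and because the cohort is
synthetic, `res$truth` certifies that every call equals the planted
diagnosis. The causal-gene ranking and novelty fraction behave like the
emulated cohort's:

```r
head(res$geneFreq, 3)
#>    gene  n  percent
#> 1   DMD 24 8.000000
#> 2  GJB1 14 4.666667
#> 3 CAPN3 11 3.666667
round(res$novel$overall, 3)
#> [1] 0.283
```

The dystrophin sub-cohort (104 patients, India/South Africa) shows the
expected country contrast in variant types — no Indian duplications,
frequent South African nonsense variants and duplications — which the
exact Fisher test calls highly significant, and the breakpoint hotspot
at introns 45–48 captures ~0.66 of deletions/duplications:

```r
res$dmd$typeTable
#>              deletion nonsense duplication splice
#> India              51        0           0      2
#> South Africa       35        9           7      0
signif(res$dmd$fisherP, 3)
#> [1] 2.37e-06
```

The canonical skipping example: an exon-52 deletion breaks the frame
and is rescued by skipping either licensed exon 51 or 53 (not 45):

```r
m <- dmdExonModel()
frameStatus(52, 52, m)
#> [1] "out_of_frame"
amenableTherapyExons(52, 52, m)$licensed
#> [1] 51 53
```

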