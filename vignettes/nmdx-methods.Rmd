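---
title: "Methods: simulated diagnostic genomics for neuromuscular disease cohorts"
author: "nmdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated diagnostic genomics for NMD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdx)
```

# Overview

`nmdx` models the genomic-diagnosis workflow used by multinational
neuromuscular-disease (NMD) sequencing programmes: probands are
phenotyped with HPO terms and a clinical diagnostic category, variants
from single-gene tests or exome sequencing are filtered by
inheritance-specific allele-frequency thresholds within
phenotype-matched gene panels, surviving candidates are classified under
ACMG evidence-combining rules, and each proband receives a diagnostic
outcome: *solved*, *possibly solved*, or *unsolved*. A dedicated engine
handles the special case of dystrophinopathies (DMD/BMD), where
exon-level deletions and duplications are interpreted through the
reading-frame rule and screened for antisense-oligonucleotide (ASO)
exon-skipping amenability. Cohort-level statistics (diagnostic-yield
tables, causal-gene frequencies, novel-variant fractions, an exact
Fisher test for r×c tables) complete the pipeline.

Because patient-level data from such programmes are typically under
controlled access, the package ships a synthetic-cohort generator with
*planted ground truth*. Every downstream stage can therefore be tested
end to end: the planted diagnosis is known, and a correct pipeline must
recover it exactly.

# The synthetic cohort model

`cohortConfig()` fixes the study conditions. Defaults encode the
published composition of a large multinational NMD cohort:

* **Category mixture** — LGMD 18.1%, genetic peripheral neuropathies
  (PN) 15.5%, congenital myopathy/congenital muscular dystrophy (CM/CMD)
  9.4%, DMD/BMD 8.6%. The remaining vocabulary (SMA, FSHD, myotonic
  dystrophy, mitochondrial disease, channelopathy, motor-neuron disease,
  neuromuscular-junction disorders, metabolic myopathy, other) is the
  package's own curated tail; the published source states only that each
  remaining category contributes under 7%, which the chosen weights
  respect.
* **Sex ratio** — 65% male.
* **Age model** — a two-component mixture: a paediatric component,
  uniform on [0, 18] years with weight 0.35 (so 35% of the cohort is 18
  or under), and an adult component 18 + Gamma(shape 2, scale 8.8)
  years. The scale solves P(adult ≤ 26) = 0.15/0.65, which places the
  overall cohort median at 26 years. The component forms themselves are
  a design choice; only the median and under-18 mass are constrained by
  the emulated study.
* **Per-category diagnostic yields** — (p_solved, p_possibly_solved) of
  PN (0.46, 0.15), LGMD (0.44, 0.16), CM/CMD (0.53, 0.19) and DMD/BMD
  (0.98, 0) are fixed by the published in-depth reviews. The published
  data constrain the remaining categories only through the overall
  combined exome rate of 56%; the pooled tail default (0.29, 0.135) is
  the solution of the mixture equation
  `sum(w_cat * combined_cat) = 0.56` under the default category
  weights. It was fixed once, analytically, and is not a tuning knob.
* **Causal-gene mixtures** — per-category (gene, inheritance mode,
  weight) lists with the reported lead genes (e.g. GJB1 and the PMP22
  duplication in PN; DYSF/CAPN3/GNE in LGMD; STAC3/RYR1/LAMA2 in
  CM/CMD; DMD for DMD/BMD). Weights approximate the reported ranking;
  they define the simulation conditions rather than estimates of
  population frequencies.
* **Novel fraction** — each planted causal variant is novel with
  probability 0.29.

Per-proband draws use deterministic substreams derived from the master
seed (`seed + 7919·i mod (2^31−1)`), so enlarging a cohort never
reshuffles earlier probands and byte-identical outputs are reproducible
from the config alone.

## Variant planting

Solved probands receive pathogenic/likely-pathogenic-supporting
evidence sets (`PVS1+PS3` or `PS1+PM1`; the frequency code PM2 is added
downstream from the simulated allele frequencies). Possibly-solved
probands receive a single supporting code (`PP3`) so the combined class
is VUS, an allele frequency below 0.01% (often absent from catalogs
altogether), and in-silico support. Zygosity follows the inheritance
mode: homozygous or two heterozygous variants for recessive genes
(60:40), heterozygous for dominant, hemizygous for X-linked males.
Decoy variants (default 6 per proband) draw frequencies log-uniformly
over [1e-6, 0.05] so that both filter thresholds (0.01 AR, 0.001 AD)
are exercised from both sides; decoys carry no in-silico support.

The generator emulates the *statistical structure* of a real cohort —
category, sex, age and yield composition, gene mixtures, frequency
strata — but not real allele-frequency spectra, linkage and
consanguinity structure, phasing, sequencing error, or incomplete
annotation. Passing recovery tests therefore demonstrates that the
filters and classifiers are internally correct under ideal annotations,
not that the pipeline would achieve these yields on real data.

# Prioritization and outcome rules

Panels are matched by HPO-term overlap (descending overlap count, ties
by panel id) with a fallback to the panel mapped from the diagnostic
category; the overlap heuristic is the package's own stated choice, as
the emulated protocol does not specify an alignment algorithm. The
frequency filter uses the *maximum* frequency across catalogs
(conservative), with strict thresholds: < 0.01 for autosomal-recessive
genes, < 0.001 for autosomal-dominant; X-linked genes use the dominant
threshold, another stated choice since published protocols list only
AR/AD. Unobserved frequencies pass. Unphased compound heterozygotes are
assumed in trans and flagged "phase unconfirmed".

Outcomes follow the study definitions. A proband is **solved** when a
zygosity-consistent subset of a candidate group is entirely
Pathogenic/Likely pathogenic and fits the phenotype; **possibly
solved** when a zygosity-consistent subset contains at least one VUS
while every member is ultra-rare (< 0.01% maximum frequency), carries
in-silico support, and fits the phenotype. Judging subsets rather than
whole groups means a common benign passenger in the causal gene cannot
spoil an otherwise clean diagnosis. The ACMG combining algebra is
shipped as a versioned data table (18 rules over strength-category
counts) so tests can enumerate it exhaustively; conflicting
pathogenic-side and benign-side evidence yields VUS, as does an empty
set. Novelty is absence of the gene + whitespace-normalized HGVS.c key
from every catalog.

# The dystrophin engine

The packaged exon model lists the coding lengths of the 79 exons of the
full-length muscle transcript Dp427m (source id NM_004006.2), totalling
11,058 nt. The table was reconstructed from that transcript's HGVS
c.-position exon boundaries and verified self-consistent (total
divisible by 3) and exact in the clinically critical skipping region
(exons 43–55, e.g. exon 51 = 233 nt, exon 52 = 118 nt); the 3′-terminal
exons 77–79 carry the largest reconstruction uncertainty, which does
not affect the shipped analyses (frame calls for terminal-exon
intervals are "inapplicable" anyway).

The frame rule: a deletion or tandem duplication of exons *a..b* is in
frame iff the summed coding lengths of exons *a..b* are divisible by 3.
Intervals touching exon 1 or exon 79 are inapplicable (the rule assumes
an intact translation start and stop). Out-of-frame variants and
truncating point variants predict the severe Duchenne phenotype;
in-frame variants the milder Becker phenotype. A single-exon skip of
exon *e* rescues an out-of-frame deletion iff *e* is immediately
adjacent, the enlarged interval avoids exons 1/79, and the enlarged
interval is in frame; licensed ASO targets are exons 45, 51 and 53,
with exon 44 in trials. Breakpoints of an exon-level variant are
attributed to the immediately flanking introns (MLPA resolution is
exon-level; sub-exonic breakpoints are not modelled), with 5′/3′
sentinels at the gene ends. In hotspot summaries a variant counts once
per intron it touches, and the "fraction within introns 45–48" counts
each variant once even if both its breakpoints fall in the window.

The structural-variant generator draws the left breakpoint intron from
a weight map (defaults: 0.68 total mass on introns 44–50, 0.18 spread
over introns 9–20, remainder uniform) and the exon span from a
geometric distribution (p = 0.35) truncated at 12 exons; country-level
variant-type mixtures default to the published solved counts (India
60:3:0:1 deletion:nonsense:duplication:splice of 64; South Africa
24:8:7:1 of 40; Brazil 1:1 of 2). `dmdHotspotProbability()` computes
the implied hotspot mass by exact enumeration of this finite mixture,
which the empirical fraction must match within sampling error.

# Exact Fisher test

`fisherExactRC()` implements the conditional exact test from first
principles. All tables sharing the observed margins are enumerated by
recursive traversal (last cell of each row, and the last row, are
forced), each table's multivariate hypergeometric probability is
computed from a log-factorial cache, and the two-sided p-value sums the
probabilities not exceeding the observed table's (probability-mass
criterion, the conventional r×c generalization; probabilities are
compared with a 1e-7 relative tolerance to absorb floating-point ties).
Exact enumeration is bounded at a grand total of 200 by default —
comfortably covering the 2×4, n = 104 country-by-type comparison — and
a margin-conditional Monte-Carlo method (Patefield sampling via
`stats::r2dtable`, add-one estimator) covers larger tables. A zero
row/column margin makes every margin-consistent table identical in the
degenerate dimension, so p = 1 with a warning. Tests verify agreement
with `stats::fisher.test` and with a direct hypergeometric-summation
oracle on every 2×2 table up to n = 30, plus super-uniformity of the
exact p-value under the simulated conditional null.

# Numerical and reporting conventions

* Display percentages round half-up to integers ("53.75%" prints as
  54%), matching clinical-report style; all tests and stored values use
  the unrounded quantities, and percentage columns are always recomputed
  from integer counts.
* Validation errors name the offending map or column
  (`category_weights does not sum to 1 ...`), and malformed variant
  records are collected into an error report rather than silently
  dropped.
* Run manifests record the config hash (MD5 of the serialized
  configuration) and per-file checksums; deterministic stages reproduce
  byte-identical artifacts for a fixed seed.

# Problem sizes used in the shipped checks

Composition recovery uses cohorts of 30,000 (module tests, 4 binomial
standard errors) and 100,000 probands (acceptance checks, 3 standard
errors for the LGMD share); end-to-end recovery uses 500 probands, and
the combined-yield check 547 exome probands, mirroring the emulated
study's exome denominator. The frame-rule and skip-closure properties
enumerate all 3,160 exon intervals; the ACMG engine is enumerated over
all evidence sets of size ≤ 3; the Fisher oracle covers all 2×2 tables
to n = 30 and 2,000 simulated null tables. These sizes were chosen so
each property is tested at full combinatorial coverage or tight
binomial tolerance while a complete run stays interactive.

# Known limitations

* The generator's yields are also the quantities the pipeline recovers;
  end-to-end "56% combined" checks are internally consistent recovery
  tests, not independent replications of the published rate.
* Non-frequency ACMG codes (segregation, functional, de novo) arrive as
  inputs; the package does not compute them, and the "phenotype fit"
  judgement — an expert decision in practice — is reduced to a flag.
* The DMD engine assumes tandem, in-cis duplications, judges
  single-exon skips only, and treats "initial or terminal exon" as
  exactly exon 1 or 79.
* HPO handling is literal term-set overlap over a small packaged
  vocabulary; no ontology traversal.
* Epidemiological quantities (incidence, prevalence) are out of scope.
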