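---
title: "The MeDIP+MRE bin test: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MeDIP+MRE bin test: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipmre)
```

## The measurement model

Two sequencing assays observe the same latent quantity — the methylation
level $m \in [0,1]$ of a genomic bin — from opposite directions. MeDIP-seq
enriches methylated fragments, so its read count grows with $m$ and with
the number of CpGs available to be methylated. MRE-seq cuts at
*unmethylated* CpG sites inside restriction motifs, so its count grows
with $1-m$ and with the number of motif sites. For a 500 bp bin $b$ with
CpG count $c_b$ and MRE-site count $r_b$, and samples $i \in \{1,2\}$:

$$X_i \sim \mathrm{Pois}(\kappa\, c_b\, s_i^{\mathrm{medip}}\, m_i),
\qquad
Y_i \sim \mathrm{Pois}(\kappa\, r_b\, s_i^{\mathrm{mre}}\, (1-m_i)).$$

The four counts are assumed mutually independent given the rates. This is
deliberately simple: rate parameters linear in site content, no
overdispersion, no fragment-length or GC bias. The per-sample factors
$s_i$ (total counts over the mean of totals, computed per assay by
`size_factors()`) absorb library-size differences; a per-assay scale
(mean total over summed site content) calibrates MeDIP against MRE rates.
That between-assay calibration is exact when the genome-wide mean
methylation is the reference value implied by the totals; in practice it
cancels from the hypothesis test entirely and only shifts the *absolute*
location of the reported methylation estimates. Estimates are therefore
comparable between groups and across bins, but should be read as
calibrated ratios, not absolute methylation percentages.

## The conditional test

Conditional on the bin total $T = X_1+X_2+Y_1+Y_2$, the count vector is
multinomial with cell probabilities proportional to
$(a_1 m_1,\, a_2 m_2,\, b_1(1-m_1),\, b_2(1-m_2))$, where
$a_i = \kappa c_b s_i^{\mathrm{medip}}$ and
$b_i = \kappa r_b s_i^{\mathrm{mre}}$; $\kappa$ cancels. The statistic is
twice the log-likelihood difference between the two-parameter fit and the
common-$m$ fit.

Two numerical facts shape the implementation:

* **The null MLE is closed-form.** The score equation for the common $m$
  collapses to a linear equation with solution
  $\hat m_0 = (X/A)\,/\,(X/A + Y/B)$ where $X, Y$ are pooled counts and
  $A = a_1+a_2$, $B = b_1+b_2$ — the pooled normalised-read ratio. A unit
  test verifies it against bounded 1-D optimisation.
* **The alternative must be maximised, not plugged in.** The natural
  per-group ratio estimate
  $\hat m_i = (X_i/a_i)/(X_i/a_i + Y_i/b_i)$ maximises each group's own
  conditional binomial likelihood but *not* the joint 4-cell multinomial
  likelihood, whose normaliser couples the groups. Evaluating the
  "alternative" log-likelihood at the ratio estimates can make the
  likelihood-ratio statistic negative (on null simulations this happened
  in roughly a sixth of bins). The statistic therefore evaluates the
  alternative at the true conditional MLE, found by a fixed-point
  iteration: for a given normaliser, each group's stationarity condition
  is a quadratic with a unique root in $[0,1]$; iterating root and
  normaliser to $10^{-13}$ converges in a handful of steps and agrees with
  2-D `optim` on every random case tested. The *reported* estimates and
  the direction label still use the ratio estimates, which are the
  interpretable per-group quantities.

P-values use $\chi^2_1$ when $T$ exceeds `exact_threshold` (default 20)
and exact enumeration of the conditional multinomial otherwise: the exact
p is the total null probability (at $\hat m_0$) of outcomes whose
statistic reaches the observed one, with a $10^{-9}$ tie tolerance.
Enumeration cost grows as $T^3$, which motivates the threshold; on bins
drawn at the default simulation depth the two branches agree closely in
the overlap region, with the residual discrepancy being multinomial
discreteness, largest for bins whose MRE-site content is 1.

Degenerate bins are resolved by convention rather than error: bins with no
CpG and no MRE site are never tested and excluded from the BH denominator
(no information under the model); bins whose content contradicts their
counts (reads in an assay with zero site content) are flagged untested;
tested bins with zero reads get $p = 1$. A bin with sites in only one
assay is still tested — the test degenerates to the correct single-assay
G-test of normalised rates — but its ratio estimates are pinned at the
boundary in both groups, so such a bin can be significant yet carry
direction `none`; the DMR summary counts these separately.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width` (binning) | 500 bp | testing resolution; smaller bins trade power for resolution |
| `mre_motifs` | CCGG, GCGC, CCGC | recognition sites of the enzyme cocktail; counted by leftmost base |
| `exact_threshold` | 20 reads | largest bin total handled by exact enumeration |
| `alpha` | 0.05 | BH FDR level for DMR calls |
| `min_len`, `min_gc`, `min_oe` | 201 bp, 0.5, 0.6 | CpG-island criteria, all strict inequalities |
| `flank` (shores) | 2,000 bp | shore width either side of an island |
| `promoter_flank`, `downstream_flank` | 1,500 bp | strand-aware gene flanks |
| `min_count`, `min_fold` | 2, 1.5 | enrichment reporting filters |
| `kappa_threshold` | 0.5 | Cohen's kappa linkage for term clustering |
| `cons_threshold` | 0.5 | strict mean-conservation cutoff for intergenic DMRs |
| `window` | 1 Mb | TAD search window either side of a DMR |

"Greater than 200 bp" is read strictly (≥ 201), as are the GC, O/E and
conservation cutoffs; boundary cases (a mean conservation of exactly 0.5,
a 200 bp segment) fail. Percentages in summaries are rounded half-up to
one decimal, matching the usual reporting style; note that printed
category counts in publications may sum to slightly more than the DMR
total when single regions span several contexts, which is why
`summarize_contexts()` accepts an explicit denominator.

## Interval conventions

Coordinates are 0-based half-open in every file read or written (BED
convention); in memory the package uses `GRanges`. CpG dinucleotides and
MRE motifs crossing a bin boundary belong to the bin containing their
leftmost base, which makes per-bin content sum exactly to chromosome
totals. Reads are assigned to exactly one bin by their 5′-most base
(midpoint rule available), so assigned + dropped = input. Island-context
labels use any-overlap with precedence island > shore > open, gene-context
labels promoter > intragenic > downstream > intergenic; precedence is
required because the categories are reported as an exclusive partition.
Flanks are strand-aware: "upstream" means 5′ of the TSS on the gene's own
strand. For nested TADs the smallest domain containing the DMR is used; a
DMR spanning a TAD boundary is assigned to none. Cross-assembly transfer
uses a plain block-offset table and demands (by default) that a single
block cover the whole interval — a deliberately transparent stand-in for
chain-based liftover, which depends on external services.

## What the synthetic generator does and does not emulate

`simulate_methylome_study()` produces every input with known truth:

* **Sequence.** Background at GC 40% with CpG depletion (O/E ≈ 0.2),
  mirroring vertebrate genomes; islands planted at GC 60%, O/E 0.75,
  length 300 bp and re-verified against the detector's criteria when
  generated. MRE motifs are planted with ≥ 50 bp spacing (about 5 sites
  per 500 bp); a repair pass thins natural CpGs wherever compositional
  fluctuation would push a background window over the island thresholds,
  so detector tests have an unambiguous truth.
* **Methylation.** A constant baseline (default 0.5) in both groups, with
  a planted fraction of bins (direction Bernoulli(0.5)) shifted by
  ±`delta` in group 2. The baseline is constant by design so that planted
  differences are exactly `delta`.
* **Counts.** Poisson draws from the measurement model, with library-size
  factors drawn in 1.0–1.3 to exercise normalisation and per-assay depth
  scaled to `mean_depth` reads per bin.
* **Annotation.** Non-overlapping genes with random strand, TADs tiling
  ~60% of each chromosome, piecewise-constant Beta(1,9) conservation
  background with planted high-score (~0.9) blocks over intergenic bins.
* **Validation data.** Log-normal multiplicative noise around true
  methylation (MSP) and around group means with a configurable fold
  change (expression), at a given coefficient of variation.

The generator does **not** simulate reads (no alignment, duplicates,
mappability), biological replicate variance (each group is one sample, as
in the two-sample design the test addresses), overdispersion relative to
Poisson, CpG-density-dependent enrichment bias, or batch effects. Passing
tests therefore demonstrate that the inference machinery is correct under
its own model — nominal type-I error (the suite checks the null rejection
rate at 10,000 bins lies in [0.03, 0.07]), FDR control, monotone power in
effect size and depth — not that the Poisson model is adequate for any
particular real dataset. With real data showing extra-Poisson variation,
q-values will be anti-conservative; that is a property of the model
family, shared with the approach the package implements.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: calibration
experiments use 10,000 bins, power and recovery experiments 2,000–10,000
bins, sequence-level studies 100–500 kb with 5–8 planted islands, and the
exact-versus-asymptotic comparison enumerates bins with totals 30–100.
Every stochastic component takes an explicit seed; regenerating with the
same seed is byte-identical, and `run_pipeline()` writes a manifest with
the seed and an MD5 of the scientific configuration so a result bundle can
be reproduced exactly.

## Known limitations

* Two samples (one per group) per comparison; replicate-aware extensions
  (pooling or dispersion estimation) are out of scope.
* The methylation estimates are calibrated ratios; absolute levels depend
  on the genome-wide mean methylation through the between-assay scale.
* Term clustering approximates fuzzy clustering by kappa-threshold
  connected components; cluster memberships from proprietary web tools
  are not reproduction targets.
* The chi-square branch is slightly conservative-to-liberal at very low
  per-cell expected counts (single MRE site); lowering `exact_threshold`
  below 20 is never wrong, only slower.
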