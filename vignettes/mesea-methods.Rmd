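---
title: "Methods and design of the mesea pipeline"
author: "mesea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mesea pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesea)
```

# The scientific setting

`mesea` implements the computational side of a maternal-overnutrition study
design: female and male offspring of control-fed (moC) and high-fat-fed
(moHF) mothers are profiled by liver bulk RNA-seq, LC-MS lipidomics and in
vivo metabolic phenotyping, and every question is asked as one of four
two-group contrasts of the 2x2 sex-by-maternal-diet factorial — (M vs F |
moC), (M vs F | moHF), (moHF vs moC | F) and (moHF vs moC | M).  The default
group sizes, 5/5/6/3 animals, reproduce the unbalanced liver-RNA-seq cohort
of that design.

The centrepiece is the **Maximum Estimate Score (MES)**, a running-sum
gene-set enrichment statistic over a ranked gene list, with a permutation
null and Benjamini–Hochberg FDR control across pathways.

# The MES statistic

Genes are ranked by descending log2 fold change of a contrast (N genes in
total).  For a pathway with G members inside the ranked universe, position
i of the list contributes an increment

$$X_i = \sqrt{\frac{N-G}{G}} \;\text{ if gene } i \in \text{pathway},
  \qquad
  X_i = -\sqrt{\frac{G}{N-G}} \;\text{ otherwise.}$$

The increments sum to zero by construction — the running sum
$S_j = \sum_{i \le j} X_i$ starts and ends at 0 — and the score is the
extremum of that walk.  Two modes are provided:

* `literal_max` — $\mathrm{MES} = \max_j S_j$, the printed definition.
  Because $S_N = 0$, this can never be negative.
* `signed_extremum` (default) — the running-sum deviation of largest
  magnitude, keeping its sign; ties in magnitude resolve to the positive
  value.

The default exists because the up/down interpretation of the score (positive
= enrichment at the top of the ranking, negative = depletion) requires a
statistic that can actually go negative; the literal maximum cannot.  The
signed extremum restores the classical enrichment-score convention while
agreeing exactly with the literal maximum whenever the top deviation
dominates.  Both modes are exposed, and all significance machinery is
two-sided on |MES|, so the choice affects reporting direction, not testing.

Useful exact facts, all enforced by tests: $\sum_i X_i = 0$;
$|\mathrm{MES}| \le \sqrt{G(N-G)}$ with equality exactly when the members
occupy a contiguous top or bottom block; and the score depends only on the
membership pattern over rank positions, never on gene labels or fold-change
magnitudes.

## Permutation null and FDR

The null hypothesis is that pathway membership is unrelated to rank.  Each
permutation therefore places the G membership labels uniformly at random
over the N positions and recomputes the score — the only permutation scheme
computable from the ranked list alone (sample-label permutation would
require re-ranking per permutation and is deliberately out of scope).  With
B permutations (default 1000) the two-sided p-value uses the add-one
estimator

$$p = \frac{1 + \#\{b : |\mathrm{MES}_b| \ge |\mathrm{MES}_{obs}|\}}{B+1},$$

so $p \ge 1/(B+1)$ and the estimator is never anti-conservative at zero.
BH q-values are computed across all tested sets of one contrast (never
pooled across contrasts), and a set is called significant at p < 0.05 and
q < 0.1.  Sets with fewer than `min_size` (default 5) members in the
universe, or with G = 0 or G = N, are reported as skipped with a reason
rather than silently dropped.

Implementation note: the observed score is a direct prefix-sum scan, while
the permutation engine exploits the fact that the walk only rises at member
positions, evaluating each permutation in O(G) from the sorted member
positions instead of O(N).  Each set draws from an RNG substream derived
from the seed and the set identifier, so results are independent of
collection order and of which other sets are present.

# Ranking stage

Counts are filtered (>= 1 read in >= 2 samples by default, after collapsing
duplicate gene ids by summation), RPKM-normalized, and ranked by

$$\log_2\mathrm{FC}(g) =
  \log_2(\bar{x}_A(g) + c) - \log_2(\bar{x}_B(g) + c)$$

with pseudocount c = 1 on the RPKM scale.  Ties break by gene id in
C-locale order so the ranking is bit-reproducible across platforms.  A
deliberate design decision: the original analysis ranked DESeq2 log2 fold
changes, but this package uses the pseudocount-stabilized mean-ratio
estimate instead.  MES consumes only the ordering, not shrunken effect
sizes, and the simplified estimator keeps the stage self-contained, exactly
reproducible, and free of model-fitting failure modes; the divergence is
documented in the README.  A Welch-t differential table (on log2(value+1),
BH-corrected, DE at q < 0.1) accompanies each ranking for the Venn-style
cross-contrast summaries; whether enrichment should run on all genes or DE
genes only is ambiguous in the source design, so all filtered genes are the
default and a DE-only list can be passed explicitly if wanted.

# Normalization

* **RPKM** — count x 1e9 / (library size x gene length), the reporting unit.
* **CPM** — count x 1e6 / (library size x factor), a utility.
* **TMM** — between-sample scaling factors via the trimmed mean of M-values,
  delegated to `edgeR::calcNormFactors`, whose defaults are precisely the
  canonical published parameters: 30% two-sided trim on log-ratios, 5% on
  absolute intensity, inverse asymptotic-variance weights, reference = the
  sample whose upper-quartile count fraction is closest to the mean.  Genes
  with a zero in either compared sample are excluded pairwise (no
  pseudocount), and factors are renormalized to geometric mean 1.  The test
  suite checks the wrapper against an independent step-by-step evaluation of
  the trimmed-mean formula.  TMM is applied to the lipid intensity matrix
  (after peak filtering) just as to counts.

# Lipidomics

Species names follow the `CLASS(C:DB)` grammar — total acyl carbons C,
double bonds DB — with a `d` prefix for sphingoid backbones
(`Cer(d34:1)`) and class-level labels (`TG54`) for carbon-class
aggregates.  Parsing is strict (unknown class or malformed body is an
error naming the offender) and round-trips exactly.

The MZmine-style peak filter keeps peaks with raw intensity **strictly
greater than** 1e4 ("higher than") and absolute mass error **within** 5 ppm
inclusive; both boundaries are configurable and the semantics are pinned by
tests.  Downstream panels are all simplex-valued (non-negative, summing to
1 per sample): class / carbon-class / species relative abundance, and
double-bond saturation profiles, optionally stratified by class.

Group fold changes for heatmap panels use log10 of group mean ratios with
zero means floored at half the smallest positive value of the table — a
choice made here (not inherited) to keep panels complete rather than
dropping features — with Welch t-tests per feature and step-down Holm–Šidák
adjustment across the panel.

Desaturase *indices* are conventional product/precursor abundance ratios:
Δ9 = C18:1n-9 / C18:0 (switchable to C16:1n-7 / C16:0) and
Δ5 = C20:4n-6 / C20:3n-6, optionally Δ6 = C18:3n-6 / C18:2n-6.  The exact
formulas were an open design point; these are the standard estimates, and
they are labelled indices because they proxy, not measure, enzyme
activity.  Missing precursors yield flagged NA values instead of errors.

# Phenotyping

* **Tolerance-test AUC** — trapezoidal rule over the measured timepoints
  (0, 15, 30, 60, 120 min), T0 included; units analyte x minutes.
* **QUICKI** — 1 / (log10 insulin_T0 + log10 glucose_T0).  The log base is
  unstated in the printed formula; base 10 is adopted because that is the
  original index convention.
* **Body composition** — total fat and subcutaneous fat are taken as inputs
  and visceral fat derived as VAT = TF − SAT (the printed definitions are
  mutually circular; this direction makes SAT + VAT = TF an invariant).
  Ratios TF/BW, VAT/TF, SAT/TF and SAT:VAT are reported, with degenerate
  denominators flagged rather than thrown.
* **MRS lipid fractions** — peaks whose fit SD is >= 20% are excluded
  first; fLM = lipid/(lipid+water), and fSL/fMUL/fPUL are fractions of the
  classified lipid signal using a shipped, editable grouping of the nine
  liver resonances by chemical shift (methyl/methylene — saturated;
  allylic/olefinic — mono-unsaturated; diallylic — poly-unsaturated).  The
  grouping is explicitly approximate: the source formulas are delegated to
  spectroscopy references and not printed.

# Factorial statistics

Two-way ANOVA uses Type-III sums of squares with sum-to-zero contrasts —
the behaviour of the named GraphPad analysis on unbalanced cells like
5/5/6/3 — via `car::Anova` on an `lm` fit.  Tukey's multiple-comparison
test over the four groups runs only when some ANOVA p < 0.05 (the gate is
part of the contract; a "not triggered" marker is returned otherwise) and
uses the Tukey–Kramer harmonic-mean adjustment on unbalanced groups.
Holm–Šidák is implemented directly (no installed package exposes step-down
Šidák p-values); BH is `p.adjust`.  The Fisher exact test is a
hypergeometric enumeration using the method of small p-values with the
standard 1e-7 relative tie tolerance, matching `fisher.test` to numerical
precision — the in-package enumeration exists because tests pin
enumeration equality to 1e-12, which requires controlling the tie
convention.

# The synthetic-data generator

The generator produces every pipeline input with the statistical structure
the analysis assumes, so the whole package is testable offline:

* **Counts** — negative binomial per gene and sample, variance
  $\mu + \phi\mu^2$, default dispersion $\phi = 0.1$ and log-normal
  baseline means (meanlog 4, sdlog 1.5) — conventional bulk-RNA-seq-like
  values, not calibrated to any deposited dataset (library sizes and
  dispersions are not reported there).  Planted effects are additive
  log2 shifts on selected genes in selected design groups, so planted
  enrichment emerges through the real ranking stage rather than by rank
  surgery.  Library depth is held constant across samples so planted fold
  changes appear directly in raw counts; real libraries vary in depth,
  which is exactly what the normalization stage exists to absorb.
* **Gene sets** — uniform draws from the gene universe; planted-enriched
  sets additionally shift all their members (default +2 log2 units, a
  strong positive-control effect) in the group matching the target
  contrast.
* **Lipid tables** — species drawn from class-plausible carbon/double-bond
  ranges (e.g. TG 46–60 carbons), log-normal intensities strictly above
  zero.
* **Phenotypes** — OGTT-shaped glucose/insulin curves at exactly
  {0, 15, 30, 60, 120} min with a 15–30 min peak, and body composition
  with SAT + VAT = TF by construction.

Every generator draws from an independent substream derived from one
top-level seed, so adding a generator never perturbs the others, and every
output is bit-reproducible under its seed.  What the generator does *not*
emulate: read-level data, mapping artefacts, batch effects, GC/length
biases, and count–lipid–phenotype correlations across assays.  Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the assumed model, not that biological conclusions from
real data would be identical.

# Validation scales and numerical choices

The test suite exercises, among others: exact equality of the O(G)
permutation engine and a brute-force prefix-sum scan on 500 random
instances (N <= 50); increment conservation and the extremal bound on a
grid up to N = 1000 at 1e-9; agreement of the permutation p with the
exhaustive C(6,3) null within Monte-Carlo error at B = 10,000; calibration
of the p < 0.05 rate within [0.03, 0.08] over 200 null synthetic datasets
at B = 1000; and end-to-end recovery of a planted 50-gene set among 2000
genes in at least 95 of 100 seeded runs with at most 10% of unplanted sets
significant.  These problem sizes were chosen as the smallest that make
each property sharp; the same properties hold at larger N by construction.

Other numerical conventions: fold-change ties break by gene id (C locale);
degenerate zero-variance/equal-mean features get p = 1 (never NaN);
skipped sets never enter the BH family; factors and fractions are checked
to 1e-12 where algebra makes them exact.

# Known limitations

* The ranking stage is intentionally simpler than a negative-binomial GLM;
  with very few replicates its ordering is noisier than shrinkage-based
  estimates.
* Permutation of membership labels tests rank association, not
  between-sample variability; biological replication enters only through
  the ranking.
* The MRS peak grouping and desaturase pairings are field conventions, not
  fitted quantities; both are configurable.
* Repeated-measures structure (the same animal measured at mid- and
  end-term) is analyzed per timepoint; no mixed models are fitted.
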