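---
title: "Methods: classifying the inheritance of gene expression in reciprocal hybrid crosses"
author: "crossherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inheritance of gene expression in reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossherit)
```

# The design and the question

`crossherit` analyses a classic quantitative-genetics design applied to
transcriptomes: two lines — here called *wild* (W) and *domesticated* (D), as
in farmed-versus-wild Atlantic salmon — are crossed to produce the two pure
types (W♀×W♂ = `WW`, D♀×D♂ = `DD`) and the two reciprocal F1 hybrids
(W♀×D♂ = `WD`, D♀×W♂ = `DW`). Each cross is assayed on common-reference
two-colour microarrays (test sample in Cy3, a shared reference pool in Cy5),
six biological replicates per cross. Because the reciprocal hybrids have the
same nuclear genome but different dams, differences between them isolate
parent-of-origin effects — in fish embryos, overwhelmingly maternal, through
yolk and maternally deposited mRNA.

The pipeline answers three questions per gene:

1. Is the gene differentially expressed between the stocks (`WW` vs `DD`)?
2. In a hybrid, is its expression additive (mid-parent), dominant (matching
   one parent), or over-dominant (outside the parental range)?
3. Are the significant contrasts among the four crosses explained by the
   maternal line, the paternal line, or both?

At the pathway level, a gene-set perturbation test in the style of generally
applicable gene-set enrichment (GAGE) asks whether functional groups shift
coordinately between the stocks, including the characteristic *two-way
perturbed* signature where members move in both directions.

# Pre-processing model

**Flooring.** Background-subtracted intensities below 1 are raised to 1, so
every log ratio is finite. The floor is the unit of the fluorescence scale,
not a tunable parameter.

**Within-array Lowess.** Two-colour arrays show an intensity-dependent dye
bias. For each array we fit a locally weighted regression of
$M = \log_2(\mathrm{Cy3}/\mathrm{Cy5})$ on
$A = \tfrac12\log_2(\mathrm{Cy3}\cdot\mathrm{Cy5})$ over the non-control
probes and subtract the fitted curve. We use `stats::lowess` — tricube
weights with robustness iterations — with span 0.3 and 3 iterations by
default; both are exposed as arguments. Span 0.3 is the conventional
MA-normalization compromise between following a smooth dye-bias curve and
not absorbing real signal; on synthetic arrays with a planted
$0.5\sin(A)$ bias it recovers the underlying signal with RMSE < 0.05 at
40,000 probes. Normalization is within-array only; with a common reference
in the second channel, between-array scale effects cancel in the ratios.

**Quality filter.** A probe is removed globally if it is a technical
control, or flagged saturated or a probe-population outlier on *any* array.
The paper-style retention rule is then applied to the background flag: a
probe is retained only when it is "positive and significant" against
background on at least 75 % of the arrays (rounded up, so 5 of 6) in at
least two of the four cross-type groups. Global removal for a single bad
array is the conservative reading of the rule; it guarantees a rectangular
matrix with no missing values, which every downstream stage assumes. The
background call itself is consumed as a boolean column from the
feature-extraction software; the package does not re-derive it from pixel
statistics.

**Annotation and collapsing.** Only probes carrying a gene and/or KEGG
Orthology annotation are analysed. Where several probes interrogate one
gene, the probe with the lowest p-value is kept — the Welch t p for the
stock contrast, or the Welch ANOVA p for the four-group analysis, each
computed once at probe level before collapsing. The two collapsed sets may
differ and are kept separate: each analysis sees the probe that is most
informative *for that analysis*, which is how a lowest-p rule must be read
to be well-defined. Ties are broken lexicographically by probe id so the
result is deterministic. By default BH adjustment is applied after
collapsing (`collapseOrder = "pre"`); collapsing on adjusted p-values is
available as `collapseOrder = "post"` since the original order of
operations is not documented.

# Differential expression

The stock contrast uses Welch's unpaired unequal-variance t-test per gene,
Benjamini–Hochberg adjustment across genes, and a linear fold-change filter:
significant means adjusted $p \le 0.05$ **and**
$\max(FC, 1/FC) \ge 1.25$ with $FC = 2^{\bar M_D - \bar M_W}$ computed on
back-transformed means of log ratios. The four-group analysis uses Welch's
heteroscedastic one-way ANOVA with a 10 % BH false-discovery gate, followed
by Student–Newman–Keuls (SNK) stepwise contrasts at $\alpha = 0.05$ per
step.

Two choices here deserve a note:

* **SNK after a Welch ANOVA is internally inconsistent** — SNK assumes a
  pooled error variance while the gate allows unequal variances. The
  combination is implemented as published: the SNK step uses the classical
  pooled mean square with its total degrees of freedom (Tukey–Kramer form
  of the denominator for unequal group sizes), and runs only for genes
  passing the Welch/BH gate. With six replicates per group the practical
  difference is small; it is documented rather than "fixed".
* **The post-hoc is gene-local.** SNK p-values are not adjusted across
  genes; the across-gene error control lives entirely in the ANOVA FDR
  gate.

Degenerate inputs follow fixed conventions: two constant, equal groups give
$p = 1$; constant but different groups give $p = 0$. These arise only in
synthetic noise-free data but must be deterministic there.

# Additivity and dominance

For gene-level group means $W$, $D$, $H$ (hybrid) on the normalized
log2-ratio scale:

$$\alpha = \frac{W - D}{2}, \qquad \delta = \frac{W + D}{2} - H, \qquad
\text{ratio} = \delta/\alpha .$$

A mid-parent hybrid has $\delta/\alpha = 0$; a hybrid matching the wild
parent $-1$; the domesticated parent $+1$. Classification intervals:
additive for $|\delta/\alpha| < 0.5$; wild-dominant for
$(-1.5, -0.5]$; domesticated-dominant for $[0.5, 1.5)$; over-dominant for
$|\delta/\alpha| \ge 1.5$, split into a wild and a domesticated side by the
sign. The published intervals are open at every boundary, leaving the
measure-zero points $\pm 0.5$ and $\pm 1.5$ unassigned; we assign
$\pm 0.5$ to the adjacent dominant class and $\pm 1.5$ to over-dominance so
the classifier is total and deterministic. When $\alpha = 0$ the ratio is
undefined; such genes are reported in their own column, never silently
dropped, and never fabricated as $\pm\infty$.

The scale matters: $\alpha$ and $\delta$ are computed on group means of
normalized log2 ratios, the same scale used for clustering and fold
changes. Since every array shares one reference channel, differences of
log ratios equal differences of log expression, so the classification is
unaffected by the reference.

Summary tables report, per hybrid, the percentage of genes in each of the
five classes among genes with a defined ratio. The $\delta/\alpha$ scatter
omits $|\delta/\alpha| > 5$ for legibility — the table never does.

# Parental-effect categories

The published category lists are internally inconsistent: the maternal list
(WW versus DW, DD or WD) and the paternal list (WW versus WD, DD or DW)
name the same three contrasts, and the maternal list includes a same-dam
contrast (WW vs WD) that cannot isolate a maternal effect. The package's
default `"line"` scheme therefore uses line-sharing logic:

* maternal evidence — a significant pair that changes the dam's line while
  sharing the sire's: {WW, DW} or {WD, DD};
* paternal evidence — shares the dam, changes the sire: {WW, WD} or
  {DW, DD};
* both kinds → *parental*; only the reciprocal contrast {WD, DW} →
  *hybrid-only*; no informative pair → *uncategorized*.

Transcripts whose only significant pair is {WW, DD} are excluded before
categorization — a pure-stock difference says nothing about inheritance.
The verbatim published lists remain available as `scheme = "literal"` for
strict reproduction.

# Gene-set perturbation tests

Fold-change profiles follow the *one-on-group* scheme: each domesticated
replicate is compared against the mean of all wild replicates, giving one
per-gene fold-change column per test replicate. Per column and per set, a
Welch two-sample t-test compares the member fold changes against all genes'
fold changes — one-sided upper for "up", lower for "down", and upper on
absolute fold changes for the *two-way* test that catches coordinated but
bidirectional movement.

Per-replicate p-values are combined by a probit (Stouffer) rule. The
one-on-group columns are not independent: they share the control-group
mean, which makes the per-replicate z-scores equicorrelated with
$\rho = 1/(n_\mathrm{control}+1)$ (with 6 controls, $\rho = 1/7$, so a
naive Stouffer z has variance $12/7$ and is anti-conservative). The
combination therefore divides by $\sqrt{k(1+(k-1)\rho)}$ instead of
$\sqrt{k}$. With the correction, 500 random null sets produce combined
p-values indistinguishable from uniform (Kolmogorov–Smirnov); without it
they are visibly overdispersed — both facts are pinned by tests.
`combineComparisons(p, rho = 0)` still gives the textbook Stouffer formula.

BH adjustment is applied across sets within each direction; significance is
called at adjusted $p \le 0.1$. The source material prints this threshold
as "corrected p value was > 0.1", an evident typo for $\le$ — the package
implements $\le 0.1$ and says so here rather than silently. The focused
two-way list applies a 0.02 cutoff to the combined raw p by default
(`focusOn = "adjusted"` switches it), since the original is ambiguous about
which p the cutoff addressed. Sets are size-filtered to 10–500 members
present in the matrix; functional groups can be excluded wholesale
("Human Diseases" by default, the conventional choice for fish data).

*Essential genes* of a significant set are members whose mean stock
difference deviates from the all-gene mean difference by more than one
standard deviation of those differences **and** whose per-gene Welch t-test
gives unadjusted $p \le 0.05$. Genes in several KEGG groups are assigned
the candidate set with the most members in the analysed gene list, ties
lexicographic.

One caveat is inherent to competitive set tests: when a sizeable fraction
of the matrix is genuinely shifted in one direction, unshifted sets sit
below the contaminated background average and can be flagged "down". This
is a property of the method, visible in the synthetic runs (a handful of
null sets flagged when planted sets are large relative to the gene
universe), not an implementation artifact.

# The synthetic experiment generator

Every stage is validated against `simulateExperiment()`, which emulates the
target design end to end: 4 cross types × 6 replicate arrays, a common
reference channel, 1–3 probes per gene, technical controls, planted
saturated/outlier/low-signal probes, ~62 % annotated genes, and genes
planted with known inheritance:

* stock difference of `effectSize` (default 1.0 log2 units) with random
  sign;
* hybrids at mid-parent (additive), at one parent (dominant), outside the
  parental interval at $\delta/\alpha = \pm 2$ (over-dominant; half an
  $|\alpha|$ beyond the $\pm1.5$ boundary so the true class survives
  default noise), or at the dam's line mean in both hybrids (maternal);
* planted perturbed gene sets (one "up", one "two-way" by default) carried
  by additional stock-shifted genes with mid-parent hybrids, alongside
  null sets;
* replicate noise: additive Gaussian on the log2 scale, SD 0.25 — the
  standard model for two-colour log ratios; biological pooling in the
  emulated design enters as this reduced replicate variance, not as
  explicit individuals;
* an intensity-dependent dye bias `amplitude * sin(A)` (default amplitude
  0.3) injected on the M scale.

The default scale is 2,000 genes (~4,100 probes) with 500 DE-planted genes
and 20 % maternal genes among them — large enough that class percentages
and calibration statistics are stable, small enough that the full pipeline
runs in seconds; the generator handles array-realistic sizes (40,000+
probes) when asked, and the Lowess-recovery tests use that scale. All
randomness flows from the single config seed; regeneration is
byte-identical. A truth record accompanies every run, and
`truthVsCalls()` scores calls against it (per-class precision/recall,
planted-set detection).

What the generator does **not** emulate: spatial slide artifacts,
probe-specific variance heterogeneity (a heavy-tail switch would be the
natural extension), cross-hybridization, and correlated expression between
genes outside planted sets. Passing the synthetic recovery tests therefore
demonstrates that the statistical machinery is correct under the stated
noise model, not that real arrays meet that model.

# Numerical conventions

* Log base 2 throughout.
* BH adjustment via `stats::p.adjust`; Welch tests via `stats::t.test` /
  `stats::oneway.test` (vectorized row-wise versions are cross-checked
  against them); studentized-range tail via `stats::ptukey`; clustering via
  `stats::hclust` (average linkage on $1 - r$, Pearson's $r$ across
  arrays, constant genes at distance 1 with a message).
* p-values are clipped to $(10^{-300}, 1 - 10^{-16})$ before probit
  transforms.
* Every tie-break (probe collapse, primary-function assignment) is
  lexicographic — deterministic and seed-free.

# Known limitations

* The additivity/dominance scheme is a point classification of group
  means; it carries no standard errors and is not a line-cross variance
  decomposition. Genes near interval boundaries will flip class under
  resampling.
* SNK's pooled variance after a Welch gate (above) is reproduced, not
  endorsed.
* The competitive gene-set background contamination effect (above).
* With strongly unbalanced designs the $\rho$ correction for the combined
  set p is approximate for the two-way (absolute fold change) direction,
  where the equicorrelation of |z| differs slightly from $1/(n_c+1)$.
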