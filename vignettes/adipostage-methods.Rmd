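---
title: "Methods: lipid class composition, differentiation staging, and pathway enrichment"
author: "adipostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid class composition, differentiation staging, and pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipostage)
```

# The scientific problem

Well-differentiated (WDLPS) and dedifferentiated (DDLPS) liposarcoma share
their driving genetics (MDM2/CDK4 amplification) but differ sharply in
behaviour, and the working hypothesis this package supports is that the two
subtypes are arrested at different stages of adipocytic differentiation.
Three kinds of evidence bear on that hypothesis:

1. **Lipid composition.** Mature adipocytes store neutral lipids
   (triacylglycerols, diacylglycerols); proliferating, poorly
   differentiated cells are relatively enriched for membrane phospholipids
   (phosphatidylcholine, phosphatidylethanolamine) and sphingomyelin.
   Untargeted lipidomics of tumor tissue therefore reads out
   differentiation state at the metabolite level.
2. **Transcriptome staging.** Cultured stromal vascular fraction (SVF)
   cells differentiate into mature adipocytes over roughly ten days,
   providing a ladder of reference transcriptomes. Projecting a tumor's
   expression profile onto that ladder assigns it a differentiation stage.
3. **Pathway enrichment.** Differential expression between the subtypes,
   summarised at the gene-set level, points at the metabolic programs
   (e.g. the pentose phosphate pathway) that separate them.

`adipostage` implements the dry-lab side of this design end to end, plus a
synthetic-data generator that produces study-shaped data with known ground
truth, so every stage is testable without access to patient data.

# Lipid shorthand parsing

Untargeted lipidomics software reports species in a flat shorthand:
a class token (`TG`, `PC`, `Hex1Cer`, ...) followed by a parenthesised
composition. The composition is either chain-resolved
(`TG(16:0/16:1/18:3)`: three acyl chains, each `carbons:double_bonds`) or
summed (`PC(34:2)`: totals only, chains unresolved). Two decorations
matter: a trailing `e` marks an ether-linked chain, and a leading `d` (or
`t`) on a sphingolipid chain encodes the hydroxylation state of the
sphingoid base (`Hex1Cer(d18:0/20:4)`).

Design choices:

* The class registry is **data-driven** and user-extensible
  ([default_lipid_registry()]): vendor exports disagree on labels, so the
  registry maps tokens to display names rather than hard-coding a class
  list. Tokens match case-sensitively, since `PC` (phosphatidylcholine)
  and a hypothetical lowercase token would be different classes.
  One registry entry deserves a note: vendor software prints `ChE` with
  the label "cholesterol", although the abbreviation conventionally means
  cholesteryl ester; the registry carries both readings rather than
  resolving the ambiguity silently.
* `e` is recorded as a boolean ether flag wherever it appears; O-alkyl
  vs O-alkenyl (plasmalogen) subtypes are not distinguished because the
  shorthand itself does not distinguish them.
* Parsing is strict about structure (balanced parentheses, numeric chain
  tokens, known class) and errors carry the offending token and its
  character offset. At the table level, unparseable rows are dropped with
  a warning by default; `strict = TRUE` turns them into errors.
* Serialisation (`format()`) is the exact inverse of parsing, so a parsed
  table can be written back without information loss.

Class aggregation sums member species per sample; fraction mode divides
by the per-sample total, the quantity shown in stacked composition plots.

# Differential feature analysis

`differential_test()` compares two groups per feature. The fold change is
computed on group means of raw abundances,
$\log_2(\bar a_A + c) - \log_2(\bar a_B + c)$, with pseudocount $c$
defaulting to half the smallest nonzero value (zero when the matrix has
no zeros). For matrices already on the log2 scale (expression after
`log2_transform()` or batch correction), `values_are_log = TRUE` uses the
difference of means instead.

The significance gate is the volcano-plot convention: a feature is called
when $|\log_2 FC| > \tau$ **and** $p < \alpha$. The printed thresholds in
this field ("fold change > 1 or < −1" for lipids, "> 2 or < −2" for
genes) are interpreted on the log2 scale such that both mean a two-fold
change: a signed *linear* threshold of ±1 would exclude nothing, so the
lipid gate must already be log-scale, and reading the gene gate as
$|\log_2 FC| > 1$ keeps the two gates consistent. Both default to
$\tau = 1$, exposed in the interface.

The default test is the two-sample **pooled-variance Student t** on
log2 values. Welch's unequal-variance t, Wilcoxon rank-sum, and
Kolmogorov–Smirnov tests are available (`test =` `"welch"`, `"wilcoxon"`,
`"ks"`). Student's t was chosen as default for two reasons: it is the
test named in the field's standard workflow for this comparison, and at
the small, slightly unbalanced group sizes typical here (6 vs 7) it holds
its nominal size exactly under the equal-variance normal null, whereas
the Welch approximation is measurably conservative (empirical size
≈ 0.047 at $\alpha = 0.05$). No multiple-testing correction is applied by
default, matching the raw `p < 0.05` gates used with volcano plots;
Benjamini–Hochberg adjustment is available via `adjust = "BH"`.

Zero-variance features under the t-test get $p = 1$ with a warning rather
than failing the run. `top_k_by_significance()` breaks ties
deterministically: ascending $p$, then descending $|\log_2 FC|$, then
lexical feature id.

PCA (`pca_scores()`) centres features without unit-variance scaling by
default — abundance data carry meaningful scale — with autoscaling as an
option; constant features are dropped before autoscaling.

# Batch correction

Tissue RNA-seq and cultured-cell RNA-seq are inevitably processed as
separate batches, so staging tumors against the SVF course requires
location–scale batch adjustment first. `fit_combat()` implements the
parametric empirical-Bayes adjustment of Johnson, Li & Rabinovic (2007):

1. **Standardise** each gene: estimate batch means by least squares,
   form the size-weighted grand mean $\hat\alpha_g$ and pooled variance
   $\hat\sigma^2_g$ (residual mean square, divisor $n$), and compute
   $Z = (Y - \hat\alpha_g)/\hat\sigma_g$.
2. **Estimate batch effects** on the standardised scale: per batch $i$
   and gene $g$, the additive effect $\hat\gamma_{ig}$ (batch mean of
   $Z$) and multiplicative effect $\hat\delta_{ig}$ (batch variance).
3. **Shrink** via conjugate priors — normal on $\gamma$, inverse-gamma on
   $\delta$ — with hyperparameters fitted across genes by method of
   moments, iterating the conditional posterior means to a relative
   tolerance of `1e-4` (cap 100 iterations; the parametric variant is
   implemented, matching the cited default).
4. **Correct**: subtract $\gamma^*$, divide by $\sqrt{\delta^*}$,
   back-transform.

The implementation reproduces the reference implementation in the `sva`
package to ~1e-4 on simulated data (that package serves as an independent
oracle in the test suite, never as the implementation). Three behaviours
are worth knowing:

* Genes flat within every batch carry no estimable effect and pass
  through unchanged.
* With batch sizes $n$, the standardised within-batch variance is
  $n/(n-1)$, not 1, so "no batch effect" corrections compress values by
  a factor $\sqrt{(n-1)/n}$ — about 2% at $n = 25$. Idempotence and
  grand-mean preservation therefore hold to that order, not to machine
  precision; the tests assert them at tolerances reflecting this.
* By default no biological covariates are protected. In the staged
  design this is forced: the time-course group coincides exactly with the
  culture batch, so protecting group labels would make the design
  singular. `fit_combat()` warns when batch and group coincide 1:1,
  because correction then removes biological signal along with the batch
  effect — a real limitation of the design, visible in the staging
  simulations (below). A `group` argument exists for designs where
  protection is possible.

Expression inputs are expected on the log2 scale; `log2_transform()`
(log2(x+1)) is the conventional transform for count-derived values.
Cross-species symbol drift (human tumor data vs mouse SVF data) is
handled by `merge_by_symbol()`: case-insensitive symbol intersection,
unmatched genes dropped with a reported count, one-to-many collisions
resolved to the higher-mean row.

# Differentiation staging

For each SVF day $d$, let $x_d$ be the mean corrected profile of that
day's replicates, $\bar T$ the tumor-group mean and $\bar N$ the
normal-tissue mean. The score is built from two Euclidean distances,

$$ d_T(d) = \lVert x_d - \bar T \rVert_2, \qquad
   d_N(d) = \lVert x_d - \bar N \rVert_2, $$

the **relative distance** $d_T(d) - d_N(d)$ (how much closer the day-$d$
profile is to the tumor than to normal tissue), and the **similarity**
$1 / (d_T(d) - d_N(d))$.

The reciprocal form has an awkward property: when an SVF day is closer to
the tumor than to normal tissue the similarity is *negative*, and its
magnitude grows as the match improves — so "higher bar = more similar"
and the literal formula cannot both be true at once. The package
resolves this by separating display from inference:

* the literal similarity is always computed and reported;
* the **stage call** (`best_day`) is the argmin of the relative distance,
  which is monotone-consistent with any reading of the score and
  well-defined on both sides of the singularity;
* a display-oriented magnitude $1/|d_T - d_N|$ is also exported, flagged
  as non-literal.

Further conventions: SVF replicates are averaged into $x_d$ before the
distance (one bar per day); distances run over the full shared gene set
on the corrected log scale, unweighted; the normal reference is the
pooled normal mean; days tied within `1e-9` report the earlier day with a
tie flag; $|d_T - d_N|$ below `1e-9` is flagged undefined rather than
reported as a huge number. `stage_stability()` provides a gene-subsampling
diagnostic (agreement of the stage call across 80% subsamples).

# Preranked gene-set enrichment

`rank_genes()` orders genes by signed log2 fold change or by
$-\log_{10}(p)\cdot\mathrm{sign}(\log_2 FC)$, with lexical tie-breaks so
the ranking is a deterministic function of its input.
`enrichment_score()` computes the weighted running-sum statistic: hits add
$|s|^p / \sum_{hits} |s|^p$ (weight exponent $p = 1$ by default, $p = 0$
for the unweighted form). Two baselines for the subtracted walk are
provided:

* `"uniform"` (default): every position subtracts $1/N$, comparing the
  hit-weight ECDF against the uniform walk. With $p=0$ this is a
  one-sample Kolmogorov–Smirnov statistic, with the convenient closed
  form that a set consisting of the single top-ranked gene scores
  $1 - 1/N$.
* `"outside"`: only non-members subtract, by $1/(N - N_{hits})$ — the
  two-ECDF form of Subramanian et al. (2005), byte-compatible with
  `fgsea` (checked in the tests).

The two differ by at most $N_{hits}/N$ and agree closely for small sets;
both flag an empty intersection or a set spanning the whole list as
not-computable rather than returning a degenerate number.

The null for `permutation_nes()` is **gene-label permutation** —
same-size random sets from the ranked list — because the preranked
interface has no per-sample phenotypes to permute; this is a documented
divergence from classic two-class GSEA. NES normalises the observed ES by
the mean |ES| of the same-signed null scores; the p-value is
$(1 + \#\{|ES_{null}| \ge |ES|\}) / (n_{same sign} + 1)$, which respects
the $1/(n+1)$ permutation floor. The selection flag reproduces the
two-sided printed gate: `(NES > 1 or NES < −1) and p < alpha`. Under the
null this gate's false-selection rate is at most $\alpha$ (verified by
simulation in the acceptance tests). Gene sets are consumed from
user-supplied GMT files; no pathway database is bundled (version and
licence drift), only a clearly synthetic fixture for examples and tests.

# The synthetic-data generator

`simulate_expression()` and `simulate_lipidomics()` generate the study
design with complete ground-truth bookkeeping. What the generator
emulates, and the defaults chosen:

* **Differentiation program**: 400 of 2,000 genes follow monotone
  per-gene sigmoid trajectories over days 0–10. Each gene has its own
  activation midpoint (uniform across the course) and a common slope
  (2 /day), reflecting the well-documented phased activation of the
  adipogenic program — early transcription factors switch in the first
  days, late adipokine and lipid-droplet genes towards the end.
  Amplitudes are uniform on ±[1, 10] log2 units; inductions of tens to
  hundreds-fold are characteristic of this differentiation system.
  The midpoint spread matters beyond realism: it makes the early and
  late trajectory segments nearly orthogonal in gene space, which is
  what renders an interior differentiation stage identifiable by the
  staging score. With a single shared midpoint the distance-to-normal
  term has a day gradient that dominates the tumor term for any interior
  stage, and the stage call collapses to day 0 regardless of the planted
  stage — a geometric fact of the score, not a bug in the correction.
* **Cohort shape**: 6 + 7 tumors (planted at day 4 and day 0
  respectively), 13 normals at the post-course mature profile, 3 SVF
  replicates per day.
* **Tumor context**: a 100-gene malignancy signature (±1 log2) shared by
  both tumor groups, so tumors are never literally on the SVF ladder.
  An optional normal-tissue context signature (off by default) can model
  bulk-tissue programs absent from culture.
* **Batch design**: tissue (tumor + normal) vs culture (SVF) batches;
  the culture batch gets a +2 log2 additive shift on every gene and a
  ×1.5 noise-scale factor. Residual noise is Gaussian, sd 0.3 log2.
* **Lipidome**: 10 classes × 20 species with grammar-exercising names
  (multi-chain, summed, ether, sphingoid forms); log-normal abundances;
  planted class-level effects — TG/DG +1.5 log2 in the
  well-differentiated group, PC/PE/SM −1.5 and ChE −1 (up in the
  dedifferentiated group); within-class dispersion 0.5 log2.
* Expression is generated directly on the log2 scale (all downstream
  stages operate there); `count_mode = TRUE` provides Poisson-lognormal
  counts for workflows that start from raw counts.

What it does **not** emulate: LC-MS acquisition noise (retention-time
drift, isotope interference, missingness), read-level RNA-seq artefacts,
library-size effects, correlated gene modules beyond the planted
signatures, or patient-level covariates. Passing tests on this generator
therefore demonstrate the *correctness of the computations* under the
assumed signal structure, not robustness to every failure mode of real
data.

Problem sizes in the test suite (2,000 genes, 100 staging replicates,
50 × 2,000 null tests, 200-permutation nulls) were chosen as desk-scale
sizes that make the binomial error bands tight enough to be meaningful.

# Numerical and degenerate-input conventions

* Convergence: empirical-Bayes iterations stop at relative change
  `1e-4` (max 100 iterations).
* Staging ties and near-zero denominators: tolerance `1e-9`; earlier day
  wins ties, undefined similarities are flagged, never numbers.
* Deterministic tie-breaks everywhere a ranking is produced (lexical ids
  as the final key), so identical inputs give byte-identical outputs.
* All simulation and permutation functions take explicit seeds; the same
  seed gives bit-identical results.
* Degenerate inputs error early with informative messages: single-sample
  batches, unknown batch labels at apply time, constant matrices for
  PCA, empty gene-set intersections, stage assignments outside the
  simulated course.

# Known limitations

* The staging design confounds batch with biology (culture vs tissue);
  correction without covariate protection removes some differentiation
  signal. The generator's defaults produce data where staging still
  succeeds; weaker programs or noisier data will degrade it, and the
  gene-subsampling diagnostic is the first thing to inspect.
* Equation-style similarity ($1/(d_T - d_N)$) is reported as defined but
  is a fragile display quantity near $d_T \approx d_N$; inference should
  use the relative distance (the package's stage call does).
* The enrichment p-value is a permutation p per set; no FDR machinery
  beyond optional Benjamini–Hochberg in the differential module.
* The lipid parser covers the flat shorthand only — no sn-position,
  stereochemistry, or full structural nomenclature.
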