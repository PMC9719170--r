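---
title: "Comparing divergence-time estimates between dating methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing divergence-time estimates between dating methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocomp)
```

## The comparison problem

Two programs date the same topology from the same alignment and disagree.
How much, where, and why? `chronocomp` treats one timetree as the
*reference* (in practice a Bayesian chronogram with 95% credibility or HPD
intervals) and the other as the *estimate* (a fast method such as
penalized likelihood or the relative rate framework), matches internal
nodes by the leaf set they subtend, and summarizes the disagreement per
dataset so that studies of very different ages — tens of Ma to the
Precambrian — can sit on one axis.

All statistics work on node *ages*: time before present, leaves at 0, in
whatever unit the source trees carry (typically Ma). All I/O converts into
this convention, because it is the semantics shared by every chronogram
dialect, and because it makes pruning trivially age-preserving: removing
an outgroup cannot move any remaining divergence away from the present.

## The statistics

With matched pairs $(t_{i,\mathrm{ref}}, t_{i,\mathrm{est}})$ over the $n$
shared internal nodes:

* **Slope through the origin.**
  $\hat\beta = \sum t_{i,\mathrm{ref}} t_{i,\mathrm{est}} / \sum t_{i,\mathrm{ref}}^2$.
  A through-origin fit is the right model because both methods agree, by
  construction, that tips are at age 0; an intercept would absorb exactly
  the kind of systematic bias $\beta$ is meant to expose. We report the
  *uncentered* $R^2 = 1 - \mathrm{RSS}/\sum t_{i,\mathrm{est}}^2$: the
  centered version has no clean interpretation without an intercept and
  can be negative, but it is computed too (`r2_centered`) since the
  convention is genuinely ambiguous in the literature. MSE is
  $\mathrm{RSS}/n$, in squared time units — the only statistic here that
  is not unit-free.

* **Mean normalized difference.**
  $\bar D = \frac{1}{n}\sum |t_{i,\mathrm{est}} - t_{i,\mathrm{ref}}| / t_{i,\mathrm{ref}} \times 100\%$,
  with the signed per-node values kept (`delta_signed`) since asymmetry of
  their distribution is itself diagnostic.

* **Coverage.** The percentage of estimate ages inside the reference
  interval, bounds inclusive — HPD endpoints are conventionally closed,
  and a degenerate interval $(t, t)$ should cover an identical estimate.
  The direction is configurable; note that a point estimate may legally
  fall outside *its own* method's interval (bootstrap intervals do this),
  which is why intervals are stored per node rather than derived.

* **Normalized uncertainty width.**
  $U_i = (t_{i,\max} - t_{i,\min}) / t_i$ per interval-carrying node, and
  the per-dataset median (mean of central order statistics for even
  counts).

**The age floor.** Every statistic above that divides by an age excludes
nodes with ages below `age_floor` ($10^{-10}$ by default) and reports the
count. The published protocol states this exclusion for $U$ width only;
we apply the same floor to $\bar D$ and the per-node deltas because the
numerical hazard — division by a near-zero age — is identical, and the
`n_excluded_*` counts keep the choice transparent.

## Matching and its failure modes

Nodes are matched by *clade key*: the sorted leaf-label set joined by
`";"`. The default `strict` mode errors on any topological mismatch: when
both methods dated one fixed topology, a mismatch is an input bug, and
silently intersecting would mask it. `intersect` mode exists for
deliberately different summaries and records how many clades each side
lost. The root row is included when present in both trees (it typically
carries a calibration); `drop_root = TRUE` removes it, since published
analyses are not always explicit about the root's membership in the
regression. Polytomies are matched as the clades actually present — no
arbitrary resolution.

## I/O decisions

* Ultrametricity is checked as *relative* tip-depth spread
  (`eps_ultra = 1e-6` of the maximum tip depth): MCMC summary trees carry
  rounding noise that an absolute test would misclassify at Precambrian
  scales.
* Annotated NEXUS: the interval annotation key is an ordered,
  user-configurable list (default `height_95%_HPD`, `95%`, `CI`; first
  hit wins) because BEAST, MCMCTree and RelTime dialects do not agree.
  Node ages default to the `height` annotation when present, falling back
  to branch-length depths; when both exist and disagree beyond
  `eps_ultra`, a warning reports the discrepancy. We default to `height`
  because a summary tree's annotation is the value its producing program
  reports, while depths can drift through branch-length rounding;
  `age_source = "depth"` flips the preference.
* Writers emit 17 significant digits by default so that NEXUS round-trips
  reproduce doubles bit-exactly (the Newick path re-derives ages from sums
  of branch lengths, so exactness there holds only when the arithmetic is
  exact — e.g. dyadic fixture values).

## Calibrations

Density calibrations convert to hard bounds via the 2.5% and 97.5%
quantiles; uniform priors pass their bounds through untouched. The skew-t
has no closed quantile here: we draw $10^6$ variates (Azzalini
construction: skew-normal over the root of a scaled $\chi^2_\nu$) and fit
a normal by maximum likelihood (sample mean and ML SD), deterministic
given the seed. Sampling-plus-fit, rather than moment formulas, matches
how such priors are ported in practice and generalizes to any density.
Offsets on the exponential and lognormal reflect fossil-minimum anchoring
and default to 0. The calibration-density denominator ("number of tree
nodes") is taken as the internal-node count of the pruned ingroup tree —
the nodes that can actually carry a calibration — and is configurable
where it enters (`dataset_features(n_nodes = ...)`).

## The synthetic study generator

`generate_study_collection()` emulates the *statistical structure* the
comparison assumes, not the biology:

* **Trees**: Yule (pure birth), rescaled so the root age is exact. Tree
  shape enters no statistic's definition, so a single simple branching
  model suffices.
* **Method distortion**: the root age is multiplied by
  $k\,e^{\varepsilon_0 - \sigma^2/2}$, $\varepsilon_0 \sim N(0, \sigma^2)$
  (the half-variance term makes the root distortion mean-one, so
  $E[\hat\beta] \approx k$ — approximately, not exactly, since $\beta$ is
  a ratio estimator); each internal node below keeps its relative
  position $r = t/t_{\mathrm{parent}} \in [0,1)$ raised to
  $g = e^{\delta}$, $\delta \sim N(0, \sigma^2)$. Because $r^g$ stays in
  $[0,1)$, parent–child ordering survives *any* $\sigma$ without
  clipping — clipping would bias slope-recovery experiments, which is why
  additive noise was rejected.
* **Intervals**: $(t(1-w),\ t(1+w))$, so every per-node width is exactly
  $2w$. Defaults $w_{\mathrm{ref}} = 0.32$ and $w_{\mathrm{est}} = 0.10$
  give normalized widths of 0.64 and 0.20 — the order of magnitude of
  Bayesian credibility intervals and of narrow bootstrap confidence
  intervals on phylogenomic data, respectively.
* **Across-dataset heterogeneity**: features are drawn log-uniformly over
  16–615 taxa and 5×10³–4.25×10⁶ sites, with 1–31 calibrations — the
  spans of published phylogenomic dating studies — and the per-dataset
  bias is $k_d = k\,e^{\gamma z_d}$ with $z_d$ the standardized target
  feature, planting a recoverable feature signal when $\gamma \neq 0$.

What the generator does *not* emulate: sequence data and branch-length
estimation error, autocorrelated vs independent rate models, fossil
placement, and topology error. Passing tests therefore demonstrate that
the statistics, matching and I/O are computed correctly and that planted
effects are recovered — not that any dating method is well calibrated on
real data.

### Design of the recovery experiments

The slope-recovery experiment uses $k = 1.5$, $\sigma = 0.05$, 50 taxa,
200 datasets. The feature-recovery experiment plants $\gamma = 0.3$ on
log site count in 23-dataset collections — and runs at baseline
$k = 1.5$, not $k = 1$. This is an identifiability requirement, not a
tuning choice: with a mean-unbiased baseline the response
$|\beta - 1| \approx |e^{\gamma z} - 1|$ is V-shaped in $z$, and no
*linear* model can be expected to attribute a non-monotone signal; a
biased baseline makes the response monotone in the planted feature, which
is also the empirically relevant regime (systematic deep-node bias is
exactly what penalized likelihood exhibits when deep calibrations are
loose).

## Feature models

OLS with intercept on standardized predictors; `taxa_count` and
`site_count` enter as log10 by default because they span orders of
magnitude. Importance is each non-intercept term's share of the summed
$|t|$ statistics, in percent. Shares are used (rather than caret-style
min–max scaling) because min–max over three predictors forces 0/100
endpoints, which cannot represent the graded importances such analyses
report; the raw $|t|$ values are returned alongside so any rescaling can
be applied downstream. Standardization makes the ranking invariant to
affine rescaling of any raw predictor.

## Numerical and degenerate-input conventions

* Smoothing-grid enumeration includes a value equal to `cv_stop` within
  relative $10^{-9}$, guarding against accumulated floating-point drift
  on long grids (e.g. 1e17 down to 1e-19 in 37 steps).
* Zero-length branches and all-zero (degenerate) trees are valid input;
  ages are clamped at 0 after depth subtraction.
* `perturb_timetree` with $\sigma = 0$ takes an exact multiplicative
  path, so scaling contracts hold to the last bit.
* Constant or collinear predictors, empty interval sets, all-excluded
  tables and sub-minimal sample sizes raise errors naming the offender
  rather than returning NA bundles.

## Problem sizes in the test suite

The suite validates at sizes chosen to keep the full run in a couple of
minutes while leaving Monte-Carlo error well inside the asserted bands:
2000 replicates against the independent Yule split-time oracle (6 taxa),
100 random self-comparisons (5–40 taxa), 200 slope-recovery datasets
(50 taxa), 100 feature-recovery collections (23 datasets each, 16–615
taxa), and 20 random tables against the grid-search and normal-equations
oracles.

## Known limitations

* Only summary trees are parsed — not posterior samples; NEXUS DATA
  blocks and substitutions-per-site trees are out of scope.
* Matching assumes identical leaf sets; there is no approximate matching
  across conflicting taxon sampling.
* The skew-t normal approximation is a two-moment summary; heavy tails
  ($\nu \le 4$) are poorly represented by any normal, and the fitted SD
  is then sample-size sensitive.
* Credibility and confidence intervals are summarized with the same width
  and coverage machinery; the package deliberately does not pretend they
  are statistically interchangeable — it reports, per method, the
  operational quantities practitioners use.
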