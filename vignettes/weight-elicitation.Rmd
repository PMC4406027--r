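---
title: "Comparing weight-elicitation techniques for MCDA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing weight-elicitation techniques for MCDA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitMCDA)
```

## The problem

Additive MCDA values an intervention as $V = \sum_i w_i v_i$, with
normalized criterion weights $w_i \ge 0$, $\sum_i w_i = 1$, and
performance scores $v_i$ on a declared scale $[0, s_{\max}]$. Since
weights sum to one, the maximum attainable value is $s_{\max}$ and the
normalized value is $100 \cdot V / s_{\max}$ percent of maximum.

The weights must be elicited, and elicitation formats differ in cognitive
demand and in how much of a respondent's latent importance structure they
can express. This package implements five techniques against the EVIDEM
criteria set — 14 criteria in 6 categories — and the statistics used to
compare them: discriminative power, rank reversals, correlations, and
Bland-Altman agreement, together with a synthetic-respondent model that
makes every stage runnable and testable without survey data.

## The criteria hierarchy

The bundled hierarchy (`evidem_hierarchy()`) is two-level: 6 categories
over 14 leaves (D:2, C:2, I:3, T:2, E:3, Q:2), with the canonical leaf
order D1, D2, C1, C2, I1–I3, T1, T2, E1–E3, Q1, Q2. A single fixed order
prevents silent weight/score misalignment; deeper trees are rejected
because every instrument here addresses exactly two levels. Hierarchical
derivations compute local shares per block and propagate,
$w_\text{leaf} = \text{category share} \times \text{within share}$.
Note that hierarchical-uniform is *not* flat-uniform: equal shares
everywhere give leaves $1/12$ (2-leaf categories) or $1/18$ (3-leaf
categories), not $1/14$. This structural re-weighting of larger
categories is visible in every hierarchical technique and is one reason
group rank orders differ across instruments even for noiseless
respondents.

## From responses to weights

None of the five instruments dictates a unique numeric conversion, so the
conversions are declared options with defaults:

- **Ratings (RS_nH, RS_H)** — direct sum-normalization of the 1–5
  ratings per block, the convention of the published EVIDEM framework.
- **Ranking (RA)** — rank-sum surrogate shares by default
  ($(n-j+1)$ over $n(n+1)/2$ for rank $j$ of $n$), rank-order centroids
  ($\frac{1}{n}\sum_{t \ge j} 1/t$) as an option. Both discard magnitude
  information by construction.
- **Point allocation (PA)** — block allocations divided by the block
  total (scale-invariant; totals that are not 100 are validation
  findings, a zero block is an error).
- **Pairwise comparison (PC)** — reciprocal matrices per block
  (judgments on the $1/9 \ldots 9$ grid; out-of-range values are errors,
  never clamped), local weights by row geometric means by default:
  deterministic, with no iteration, and identical to the principal
  eigenvector on consistent matrices. The eigenvector route (power
  iteration, tolerance $10^{-10}$) is available for fidelity to classical
  AHP; Saaty consistency ratios are reported but never used to reject
  responses.
- **Best-worst scaling (BWS)** — counting analysis: with $B_i$, $W_i$,
  $r_i$ the best, worst and appearance counts, the default shifted score
  $(B_i - W_i + r_i)/2r_i \in [0,1]$ is normalized to a weight vector;
  $\sqrt{(B_i + 0.5)/(W_i + 0.5)}$ is the alternative.

The pairwise instrument is hierarchical by default — the category block
plus within-category blocks, 15 + 9 judgments — because a flat design
needs $\binom{14}{2} = 91$ judgments. The 12-set, size-4 BWS design
cannot show 14 criteria equally often in 48 slots; `make_bws_design()`
targets the closest feasible balance, appearance counts in $\{3, 4\}$,
spreading co-appearances greedily with seeded tie-breaks.

## Comparison statistics

Discrimination is measured within respondent on the sorted weight vector:
$d_{13} = w_{(1)} - w_{(3)}$, $d_{ml} = w_{(1)} - w_{(n)}$, and
$d_{eq} = \frac{1}{n}\sum_i |w_i - 1/n|$, all zero exactly when the
vector is uniform. One-sample t-tests check whether these distances
differ from zero across respondents; the degenerate zero-variance case is
reported with an explicit convention ($t = 0, p = 1$ at mean zero,
flagged $\pm\infty$ otherwise) rather than failing.

Agreement between techniques uses the two-level view: the correlation of
the per-criterion group means (noise averages out, so this is high) and
the mean within-respondent correlation (noise does not, so this is
lower). Pearson is the default coefficient, Spearman an option. Rank
reversal is the mean absolute per-criterion rank difference, computed at
the group level and within respondents (averaged within respondent first,
then over respondents); ties in rank orders are broken by the canonical
criterion order and flagged, because silent ties corrupt the statistics.
Bland-Altman analysis reports the bias (mean difference), the 95% limits
of agreement ($\text{bias} \pm 1.96\,\mathrm{sd}$), outliers, and a
paired t-test of the bias; plots are emitted alongside a CSV of the
plotted coordinates so agreement numbers are testable without reading
figures. A regression-based trend correction is deliberately out of
scope.

## The synthetic-respondent model

The generator stands in for a 60-respondent, four-arm survey: every
respondent answers the flat rating scale plus one of ranking + point
allocation, pairwise comparison, BWS, or hierarchical rating (15 each),
in randomized order.

Latent importances are Dirichlet draws. The base profile is the published
group-mean rating-scale weight vector for these criteria
(`evidem_reference_weights()`), scaled by a concentration of 75; this
reproduces the individual-level spread seen in student weighting samples
(mean distance from equal weights around 0.02–0.03). The Dirichlet is the
simplest simplex family with a single spread knob; it does not model
demographics, cross-country differences, or dropout.

Responses are noisy functions of the latent vector $w$ with a consistency
parameter $\kappa$ (noise scale $1/\kappa$; $\kappa = \infty$ is
noiseless, the default $\kappa = 4$ is moderate):

- *Ratings* use an anchored absolute rule,
  $\text{rating} = \mathrm{clamp}(\mathrm{round}(3 + g\log(s \cdot n)), 1, 5)$
  with gain $g = 3$ on the block share $s$: uniform importance maps to
  the scale midpoint, and each rating step is a factor $e^{1/g}$ in
  relative importance. An anchored rule (rather than a quantile map that
  forces a uniform rating histogram) preserves magnitude information,
  matching how respondents use importance scales and keeping the
  noiseless round-trip faithful. Noise is logistic on the log-share.
- *Ranking* ranks a perturbed latent per block; *points* allocate 100 by
  largest-remainder rounding of perturbed shares (deterministic at
  $\kappa = \infty$ up to half-point rounding).
- *Pairwise* judgments are latent ratios with lognormal noise snapped to
  the admissible grid — reciprocity holds by construction, and grid
  snapping realistically injects inconsistency.
- *BWS* picks argmax/argmin of a freshly perturbed latent per choice set.

Anchoring: when an instrument comes second in the survey, the latent is
shrunk toward uniform, $w \leftarrow (1-\alpha) w + \alpha/n$, before
responding (default $\alpha = 0.3$; no quantitative magnitude is
published for this effect, so it is a free simulation parameter, and
$\alpha = 0$ disables it). This reproduces the observed direction —
respondents discriminate less at second position.

All randomness flows from one master seed through named substreams
(latents, order, noise, design, scores), so each stage is independently
reproducible and cohort files are byte-identical under a repeated seed.

### What noiseless round-trips can and cannot recover

At $\kappa = \infty$, point allocation recovers the latent almost exactly
(within-respondent Pearson $r \approx 0.999$), pairwise comparison
$r \approx 0.97$ (grid resolution), and both rating modes
$r \approx 0.95$–$0.96$ (five response levels). Ranking and BWS are
different in kind: a rank permutation or a best/worst count contains no
magnitude information, so any surrogate conversion caps the correlation
with the latent — about $0.84$ for rank-sum ranking and $0.88$–$0.92$
for a 12-set BWS design, for any realistic Dirichlet spread. This is a
property of the instruments, not of the noise model, and it is the main
caveat when interpreting passing tests: the simulator shows the pipeline
is faithful to what each instrument *can* express, not that rank-based
instruments measure latent importance on an interval scale.

## Numerical choices and degenerate inputs

Weight vectors must sum to 1 within $10^{-9}$ and be nonnegative; block
shares are validated at $10^{-8}$ before propagation. Power iteration
stops at $10^{-10}$. The score-scale maximum defaults to
$s_{\max} = 3$ (the scale implied by published EVIDEM value tables,
where a mean value of 1.370 is reported as 45.7% of maximum) and is a
parameter, never hard-coded. Validation reports violations instead of
raising — explicit failure beats silent imputation — while derivation
functions are strict. Zero-variance respondents are excluded from
within-respondent correlations and logged.

## Problem sizes used in the tests

The test suite exercises the full 60-respondent study design for
pipeline-level properties, a 200-respondent noiseless cohort for
parameter recovery, 200 small (16-respondent) cohorts for the
anchoring-direction Monte-Carlo, 1,000 random consistent matrices and 500
random BWS designs for the oracle equivalences. These sizes were chosen
so each property is measured well clear of Monte-Carlo noise while the
whole suite stays fast.

## Known limitations

- Rank-based instruments cannot be validated against latent magnitudes
  (above); their surrogate conversions are conventions, not estimates.
- The simulator emulates design structure and response noise, not real
  respondent behaviour: no learning across instruments beyond the
  one-parameter anchoring shrinkage, no demographics, no dropout, no
  positional effects within BWS sets.
- Group-consensus AHP (aggregating matrices before deriving weights) and
  incomplete-matrix completion are out of scope, as are EVIDEM's
  contextual criteria and probabilistic value distributions.
- Performance scores for the value model are synthetic; only the
  convergence of value estimates across techniques is meaningful, not
  their absolute level.
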