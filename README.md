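# elicitMCDA

Weight elicitation and technique comparison for multi-criteria decision
analysis (MCDA) in health technology assessment.

When a committee values a health innovation with an additive MCDA model,

    V = Σᵢ wᵢ · vᵢ ,

the criterion weights `wᵢ` (nonnegative, summing to 1) must first be
elicited from respondents, and the elicitation technique itself is a design
choice: a five-point rating scale, a ranking, a 100-point allocation, AHP
pairwise comparison, or best-worst scaling (BWS case 1) all claim to
measure the same latent importances. This package implements, for the
14-criterion EVIDEM framework (6 categories: disease impact, context,
intervention outcomes, type of benefit, economics, quality of evidence),
the full comparison pipeline:

- **Weight derivation** for all five techniques, including hierarchical
  propagation (leaf weight = category share × within-category share),
  AHP local weights by row geometric means or the principal eigenvector
  (with Saaty consistency ratios), rank-sum or rank-order-centroid
  surrogates, and BWS counting analysis with the shifted best-minus-worst
  score `(B − W + r) / 2r`.
- **Value aggregation**: `V = Σ wᵢ·vᵢ` and its normalization to percent of
  the maximum attainable value.
- **Comparison statistics**: discriminative power (`d13`, `dml`, `deq` —
  weight distances between top-ranked criteria and from equal weights),
  one-sample t-tests, group- and individual-level rank reversals,
  across- and within-respondent correlations, and Bland-Altman agreement
  analysis with 95% limits of agreement, including an order-effect
  (anchoring) variant.
- **A synthetic-respondent generator**: latent Dirichlet importance
  vectors, technique-specific response models with a consistency
  parameter κ, randomized technique order, and an optional anchoring
  effect that shrinks second-position preferences toward uniform — so the
  whole pipeline runs and is testable without survey data.

## Worked example

```r
library(elicitMCDA)

h <- evidem_hierarchy()
pc_num_comparisons(14)        # 91 judgments for a flat pairwise design
round(equal_weights(h)[1], 2) # 0.07, the no-prioritization baseline

run <- run_pipeline(seed = 1) # simulate 60 respondents, 4 arms of 15
print(run)
```

```
MCDA weight-elicitation comparison run (seed 1 )

Value estimates by technique:
 technique  N V_mean    V_se    V_sd pct_of_max pct_min pct_max
     RS_nH 60  1.153 0.01345 0.10416      38.42   30.99   49.09
        RA 15  1.171 0.03534 0.13687      39.05   32.24   47.68
        PA 15  1.195 0.02994 0.11594      39.83   33.69   47.55
        PC 15  1.121 0.01695 0.06563      37.35   34.41   41.53
       BWS 15  1.122 0.02560 0.09915      37.39   31.82   46.00
      RS_H 15  1.185 0.02896 0.11215      39.51   32.28   46.43

Discrimination (group means):
 technique d13_mean dml_mean deq_mean
     RS_nH   0.0259    0.108   0.0320
        RA   0.0476    0.145   0.0346
        PA   0.0399    0.108   0.0252
        PC   0.0325    0.106   0.0239
       BWS   0.0240    0.135   0.0330
      RS_H   0.0984    0.182   0.0351

Agreement with RS_nH :
 technique across_r mean_within_r  n
        RA    0.308         0.319 15
        PA    0.855         0.471 15
        PC    0.913         0.598 15
       BWS    0.758         0.562 15
      RS_H    0.559         0.351 15
```

Reading the output: value estimates converge at the group level (group
means a couple of percentage points apart) while individual estimates
spread much wider (the min–max columns); discrimination differs by
technique (`d13`, `dml`, `deq` are the weight gaps between the 1st and 3rd
ranked criterion, most and least important, and from equal weights);
across-respondent correlations with the reference rating scale exceed the
within-respondent correlations, the same qualitative pattern reported for
real panels. The value percentages depend on the synthetic performance
scores drawn for the run — only their convergence across techniques is
meaningful, not their level.

`compare_report(run)` returns the cross-technique table;
`run_pipeline(..., out_dir = "reports")` writes every table as CSV plus a
run log; `write_cohort()` / `read_responses()` round-trip the raw response
files.

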