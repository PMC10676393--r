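# clpnet

Cross-lagged panel networks for multi-wave dichotomous symptom data.

Longitudinal panel studies of depression — for example older-adult cohorts
completing the eight-item dichotomous CES-D every two years — are
increasingly analyzed as *symptom networks* rather than sum scores: each
symptom at wave *t+1* is regressed on **all** symptoms at wave *t*, so that
directed edges separate what a symptom *predicts* from what *predicts it*.
clpnet implements that workflow end to end for binary items: cross-lagged
panel network (CLPN) estimation, centrality, resampling-based accuracy and
stability, cross-sectional Ising networks, cross-network comparison, a
missing-data stage, and a seeded synthetic-data generator for validating
every step without access-restricted cohort data.

## The model

For each consecutive wave pair and outcome item *k*,

```
logit P(y[k, t+1] = 1) = c_k + Σ_j β[j,k] · y[j, t] + γ_k' z
```

fit by lasso-penalized logistic regression (glmnet) with 10-fold
cross-validated penalty selection, covariates `z` (gender, ethnicity)
included. `β[j,k]` is the directed edge *j → k* on the log-odds scale
(`exp(β)` = odds ratio; OR 1 = no relationship). Diagonal entries are
autoregressive paths; off-diagonal entries are cross-lagged paths.
Centrality is cross-lagged expected influence: in-EI(k) = Σ_{j≠k} β[j,k],
out-EI(j) = Σ_{k≠j} β[j,k], covariates and autoregressive paths excluded.

Accuracy and stability follow the standard bootstrap toolkit: percentile
CIs from nonparametric bootstrap, edge and centrality difference tests,
and the case-drop CS-coefficient (largest drop proportion keeping ≥95% of
subsample centralities correlated ≥0.7 with the full sample).

## Worked example

```r
library(clpnet)

spec  <- default_ground_truth(seed = 1)      # fixed synthetic ground truth
panel <- simulate_panel(spec, 3000)          # 3000 subjects x 9 waves x 8 items

net <- clpn(panel, wave = 1, seed = 11)      # waves 1 -> 2
net
#> Cross-lagged panel network (waves 1 -> 2), log-odds scale
#>   n = 3000; penalty rule: 1se (10-fold CV)
#>   nonzero cross-lagged edges: 11 / 56; autoregressive range [1.06, 1.47]
#>   covariates: gender, ethnicity

expected_influence(net)
#>   item     in_ei    out_ei    in_ei_z     out_ei_z
#> 1  dep 0.6102524 0.2958173  0.7047110 -0.349458509
#> 2  eft 0.7314178 0.5303730  1.0756544  0.623478514
#> 3  slp 0.0000000 0.3778771 -1.1635545 -0.009074323
#> ...
```

The printed network says: at n = 3000 the penalty keeps 11 of the 56
possible cross-lagged edges, and every symptom predicts itself two years
later with log-odds 1.1–1.5 (OR ≈ 2.9–4.4). The centrality table says
effort (`eft`) is both strongly predicted by other symptoms (in-EI 0.73)
and predictive of them (out-EI 0.53), while restless sleep (`slp`) has
outgoing but no incoming influence — the precursor pattern.

Compare transitions, check accuracy, and quantify stability:

```r
cmp <- compare_networks(clpn(panel, 1, seed = 1), clpn(panel, 2, seed = 1))
bt  <- bootstrap_edges(panel, wave = 1, B = 1000, seed = 2)   # percentile CIs
st  <- casedrop_stability(panel, wave = 1, B = 1000, seed = 3)
edge_difference_test(bt); centrality_difference_test(bt, "in")
```

For panels with attrition: `little_mcar_test()`, `dropout_model()` and
`impute_chained()` (chained equations with logistic models, one imputed
dataset) precede fitting. `run_pipeline()` drives the whole sequence from
a YAML config and writes CSV/GraphML artifacts plus a manifest;
`read_panel()`/`write_panel()` handle wide and long CSV panels.

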