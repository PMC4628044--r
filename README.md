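# triqsar

QSAR modeling of 1,2,3-triazole cytotoxicity with graph and geometry
descriptors.

## The problem

A reference study assayed 32 disubstituted 1,2,3-triazole derivatives
against four cancer cell lines (HuCCA-1 cholangiocarcinoma, HepG2
hepatoblastoma, A549 lung carcinoma, MOLT-3 leukemia), built one multiple
linear regression (MLR) model per cell line from molecular descriptors, and
used those equations to rank 64 in-silico-modified analogs. `triqsar`
re-implements that whole workflow as a tested, reusable R pipeline for
anyone who wants to (a) apply the four published equations to new or
modified triazole analogs, or (b) rebuild models of the same family
(correlation screen, stepwise MLR, leave-one-out cross-validation) on their
own descriptor-activity tables.

## The model

Activity is pIC50 = -log10(IC50 in uM). Each cell-line model is an ordinary
least squares fit of

    Y = B0 + sum_n Bn * Xn

over two descriptors selected by a univariate screen (|Pearson r| >= 0.6
against pIC50) followed by stepwise MLR (partial-F entry at p <= 0.05,
removal at p >= 0.10). Predictive quality is summarized by Pearson R and
RMSE (denominator N) for the training fit (R_Tr, RMSE_Tr) and for pooled
leave-one-out predictions (R_CV, RMSE_CV).

The published equations, shipped as `published_models()`:

| cell line | equation | N | R_CV | RMSE_CV |
|---|---|---|---|---|
| HuCCA-1 | pIC50 = -84.0157 (R5e+) + 1.0288 (nArCOOR) + 0.8738 | 13 | 0.8957 | 0.2562 |
| HepG2   | pIC50 = 0.0784 (RDF105m) + 5.1878 (MATS7m) - 1.7524 | 24 | 0.6724 | 0.4526 |
| A549    | pIC50 = 1.5979 (MATS8v) + 0.9251 (nArCOOR) - 1.7829 | 16 | 0.5958 | 0.4211 |
| MOLT-3  | pIC50 = 1.0649 (Lop) + 10.3977 (R7m) - 5.6832       | 20 | 0.8430 | 0.2070 |

The seven descriptors these models consume are computed by the package from
any 3D structure (SDF V2000; XYZ; or SMILES plus the built-in deterministic
embedder):

- **R5e+ / R7m** — GETAWAY R-indices: over atom pairs at topological lag k,
  terms sqrt(h_i h_j) w_i w_j / r_ij with h the leverages of the molecular
  influence matrix of centred coordinates; R5e+ is the max term at lag 5
  with Sanderson-electronegativity weights, R7m the summed terms at lag 7
  with mass weights.
- **MATS7m / MATS8v** — Moran autocorrelations of carbon-scaled atomic
  weights at topological lags 7 / 8 (mass / van der Waals volume weights),
  on the hydrogen-depleted graph.
- **RDF105m** — radial distribution function sum_{i<j} w_i w_j
  exp(-beta (10.5 - r_ij)^2), mass weights, beta = 100 per square Angstrom.
- **Lop** — lopping centric index: the Shannon entropy (base 2) of the
  partition of heavy atoms by iterative pruning of terminal vertices.
- **nArCOOR** — count of aryl esters (C(=O)-O-C with the carbonyl carbon on
  an aromatic atom).

## Worked example

```r
library(triqsar)

# score two candidate analogs with the published HuCCA-1 equation
model <- published_models("HuCCA-1")
print(model)

cand <- data.frame(compound_id = c("8N", "7D"),
                   `R5e+` = c(0.022, 0.057), nArCOOR = c(1, 0),
                   check.names = FALSE)
preds <- data.frame(compound_id = cand$compound_id, cell_line = "HuCCA-1",
                    pic50 = predict(model, cand))
print(rank_candidates(preds), digits = 3)

# refit a model end to end on a synthetic descriptor-activity table
d <- generate_linear_dataset(synthetic_spec(seed = 42))
sel <- stepwise_mlr_select(d, candidates = correlation_filter(d)$selected)
rep <- loo_cross_validate(d, sel$selected)
print(rep)
```

prints

```
<qsar_model HuCCA-1 [published]> pIC50 = -84.0157(R5e+) +1.0288(nArCOOR) +0.8738
  compound_id cell_line   pic50    predicted_class rank
1          8N   HuCCA-1  0.0543      highly active    1
2          7D   HuCCA-1 -3.9151 weakly to inactive    2
<validation_report N=24  R_Tr=0.8980 RMSE_Tr=0.3828  R_CV=0.8704 RMSE_CV=0.4296>
```

Compound 8N (an aryl ester with the lowest R5e+ among the modified series)
scores pIC50 0.054 — "highly active" under the predicted-activity classes
(pIC50 > 0 highly active, -1..0 moderately active, < -1 weakly to inactive)
— while the trifluoromethyl ketone 7D, whose high electronegativity drives
the largest R5e+, scores -3.915. The synthetic refit shows the full
selection/fit/LOO-CV loop recovering a planted two-descriptor model with
cross-validated statistics in the range of the published ones.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "triqsar.R", package = "triqsar"))')
Rscript $CLI descriptors --config config.json --out-dir out   # structures -> descriptor table
Rscript $CLI train       --config config.json --out-dir out   # filter/stepwise/MLR/LOO per cell line
Rscript $CLI predict     --config config.json --model published:HuCCA-1
Rscript $CLI reproduce   --target all                         # re-check reference numbers
```

Configuration is JSON (schema in `inst/extdata/config_schema.json`). Exit
codes: 0 success, 1 partial per-record failures, 2 unusable input.

## What the package does not do

Quantum-chemical geometry optimization (structures are taken as given, or
embedded by a light deterministic distance-geometry routine), the ~3,200
other descriptors of the original descriptor software, regularized or
nonlinear models, and applicability-domain analysis. The original study's
machine-readable structures and full descriptor table were never published;
descriptor values computed here from user-drawn structures will not match
the printed ones exactly (geometry- and parameterization-dependent), which
is why the published equations are shipped verbatim and the engine is
validated against brute-force oracles and invariance properties instead.
See `vignettes/triqsar-methods.Rmd` for the full methods discussion.
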