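# molgsl

Molecular property prediction with two levels of graph representation:
atom-level molecular graphs encoded by a graph isomorphism network (GIN),
and a molecule-level similarity graph (MSG) refined by metric-based graph
structure learning (GSL).

## Who this is for

Cheminformatics practitioners predicting assay outcomes
(classification) or physicochemical properties (regression) from SMILES,
especially on *small* labelled compound sets where relationships between
molecules carry real signal — and where that signal is corrupted by
activity cliffs (structurally similar pairs with very different
properties).

## The model

Each molecule `m` is an attributed graph `G_m = (V, E)` of heavy atoms
and bonds. A K-layer GIN updates node states

```
h_v^(k) = MLP_k( (1 + eps_k) · h_v^(k-1) + Σ_{u ∈ N(v)} h_u^(k-1) ),
```

and a readout pools layers `k = 0..K` into the initial molecular
embedding. Molecules then become nodes of the MSG, whose initial
adjacency `A⁰` holds ECFP4 Tanimoto similarities thresholded at
`ε_tc`. For `t = 1..T` rounds, the structure learner computes an
m-perspective weighted cosine similarity over current embeddings,

```
s_ij = (1/m) Σ_p cos(w_p ⊙ v_i, w_p ⊙ v_j),
```

sparsifies it at `ε` into `A^(t)`, fuses
`Ã^(t) = λ A⁰ + (1 − λ)(η A^(t) + (1 − η) A^(1))`, and re-propagates the
embeddings through an L-layer inter-molecule GNN
`H^(l) = ReLU(Ã H^(l-1) W_l)`. A fully connected head predicts from the
final embeddings; training minimises `L = Lpred + LGSL`, where the
graph-quality term `LGSL` pulls same-label training pairs together
(classification) or penalises edges between property-discordant training
pairs (regression) — the mechanism that down-weights activity-cliff
edges.

The method is transductive (all molecules sit in the MSG; only training
labels enter losses). New molecules are attached inductively as
receive-only nodes, leaving reference predictions untouched.

## Worked example

```r
library(molgsl)

## a seeded synthetic compound set: 5 scaffold families, known property
## function, 5 planted activity-cliff pairs
rec <- generate_dataset(synthetic_spec(
  n_molecules = 120, n_clusters = 5, task_type = "regression",
  noise_sd = 0.3, ac_pair_count = 5, seed = 1))
rec <- random_split(rec, c(0.8, 0.1, 0.1), seed = 1)

cfg <- run_config(task_type = "regression", K = 2, hidden_dim = 48,
                  m = 2, L = 2, T_rounds = 2, epochs = 150, patience = 30,
                  learning_rate = 5e-3, seed = 1)
model <- train_model(rec, cfg)
print(model)
#> <molgsl_model> regression (full), 120 molecules, best epoch 75
#>   train: rmse=0.7327 mae=0.3888
#>   valid: rmse=0.4461 mae=0.3859
#>   test: rmse=1.0215 mae=0.5724

evaluate_model(model, "test")
#> $rmse
#> [1] 1.021531
#> $mae
#> [1] 0.5724359

## predictions for new molecules (receive-only MSG nodes)
predict_new(model, c("c1ccccc1CCO", "C1CCNCC1CC"))
#>        smiles     target error
#> 1 c1ccccc1CCO -1.7827426  <NA>
#> 2  C1CCNCC1CC -0.1166219  <NA>
```

The RMSE/MAE are in the units of the synthetic target (scaffold-family
mean in `[-2, 2]` plus substituent effect); the GIN-only ablation
(`ablation_variant = "not_any"`) on the same split lands at test RMSE
1.10, illustrating what the similarity graph contributes. Ablation
switches `not_any`, `only_a0`, `only_gsl`, `no_gsl_loss` select the
corresponding reduced models.

A thin CLI covers the same surface:

```sh
inst/cli/molgsl simulate --n_molecules 120 --task_type regression --out d.csv
inst/cli/molgsl split --data d.csv --seed 1 --out splits.csv
inst/cli/molgsl train --data d.csv --splits splits.csv --task_type regression
```

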