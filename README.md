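# combonet

Predicting whether two drugs combine **synergistically** (+1) or
**antagonistically** (−1) from a heterogeneous drug–protein network, by
*jointly* learning drug embeddings and the pair classifier.

Most pipelines first extract drug features from a network and then train a
classifier on them, so the features are never informed by the prediction
task.  `combonet` couples the two: nonnegative matrix factorizations of the
network layers and a hinge-loss kernel classifier on drug pairs are
minimized under one objective, so the embedding is shaped by the labels it
must explain.

## The model

Three network layers over `n_d` drugs and `n_t` targeted proteins:

- `S_d` — drug–drug similarity in [0, 1] (Jaccard of ATC code sets, of
  166-bit structural fingerprints, or their probabilistic fusion
  `1 − (1 − s_ATC)(1 − s_CSS)`);
- `B_t` — binary drug–target incidence;
- `A_p` — protein–protein interactions among the targets.

The objective combines three losses over nonnegative factors
(`W_d, H_d : n_d×k`, `W_t : n_d×k`, `H_t : n_t×k`):

```
L = ½‖S_d − W_d H_d′‖² + ½λ_sym‖W_d − H_d‖²                (drug network, relaxed symmetric NMF)
  + λ1 [ ½‖B_t − W_t H_t′‖² + ½ tr(H_t′ L H_t) ]           (drug–target network, PPI-Laplacian regularized)
  + λ2 Σ_{c_ij=±1} max(0, 1 − c_ij φ(E_i, E_j))            (hinge loss of the pair classifier)
```

where `E_i = [W_d[i,] | W_t[i,]]` (standardized) is the embedding of drug
`i`, pairs are represented by the order-symmetric feature
`[E_i∘E_j | |E_i−E_j|]`, and `φ` is a kernel SVM decision function
(polynomial degree 3 by default).  Training alternates classifier refits
with Armijo-backtracked projected-gradient updates of the four factors;
the hinge subgradient is routed back into the drug factors, which is what
makes the learning joint.  See `vignettes/joint-embedding.Rmd` for the
full account.

## Worked example

Everything runs on synthetic data with planted low-rank structure — no
downloads:

```r
library(combonet)

inst <- simulate_hetnet(seed = 1)   # 60 drugs, 120 proteins, planted rank 5
inst$net
#> hetnet: 60 drugs, 120 targeted proteins
#>   drug-target edges: 586, PPI edges: 325
#>   mean off-diagonal similarity: 0.5939
inst$labels
#> combination_labels: 442 pairs (144 synergistic, 298 antagonistic) over 60 drugs

# hold out 20% of the labeled pairs, train on the rest
set.seed(2)
idx   <- sample.int(nrow(inst$labels), 88)
test  <- inst$labels[idx, ]
train <- combination_labels(inst$labels$i[-idx], inst$labels$j[-idx],
                            inst$labels$label[-idx], inst$net$drugs)

fit <- fit_joint(inst$net, train, train_config(k = 8, seed = 1))
fit
#> train_result (joint learning): k = 8, 23 iterations, converged
#>   final losses: drug 5.387, target 203.5, classifier 0.008153, total 208.9

pred <- predict(fit, cbind(test$i, test$j))
head(pred, 3)
#>   i  j      score label
#> 1 1 11 -0.7088651    -1
#> 2 1 26 -0.2305717    -1
#> 3 1 36  1.3560949     1

roc_auc(pred$score, test$label)             # 0.860
average_precision(pred$score, test$label)   # 0.764
classification_metrics(confusion_counts(pred$label, test$label))
#> accuracy 0.807, precision 0.727, recall 0.750, F 0.738, MCC 0.586
```

The final losses say the similarity matrix is reconstructed almost
exactly (`drug 5.4` against `½‖S_d‖² ≈ 670` for zero factors), the binary
incidence keeps an irreducible Bernoulli residual (`target 203.5`), and
nearly every training pair is classified outside the margin
(`classifier 0.008`).  A held-out AUC of 0.86 on a noisy instance
(similarity noise σ = 0.05) against a 2:1 class imbalance is what the
planted signal supports; at σ = 0 it exceeds 0.9.

`kfold_cv(net, labels, config, folds = 10, seed = 1)` runs the stratified
pair-level cross-validation and reports mean ± sd for all metrics.  A
command-line interface with `simulate`, `similarity`, `train`, `predict`,
`evaluate` and `sweep` subcommands is installed at
`system.file("cli", "combonet.R", package = "combonet")`.

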