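# movida

Multi-omics visible drug activity prediction: an R package for predicting
the dose–response AUC of cancer cell lines with a neural network whose
hidden modules are Gene Ontology biological-process terms, wired by the
ontology's own `is_a` hierarchy.

## Who this is for

Computational pharmacologists and method developers who want a drug
sensitivity predictor whose internals can be read: every hidden module is a
named pathway, so "why is this cell line predicted sensitive?" has a
concrete answer in terms of pathways, and pathway ablation scores feed a
drug-combination prioritization procedure. The package also ships a full
synthetic-study generator with planted causal pathways, so the entire
pipeline — ontology parsing, multiomics encoding, imbalance-aware training,
evaluation, interpretation, synergy classification — runs and is tested
end-to-end without any external downloads.

## The model

A cell line enters as three binary gene vectors (mutation, amplification,
deletion) plus a per-term expression enrichment score, the single-sample
Mann–Whitney–Wilcoxon gene-set statistic

```
NES = 1 − U/(mn),   U = mn + m(m+1)/2 − T,
```

with `T` the rank sum of the term's `m` genes among all `m + n` genes of the
sample — the probability that an in-set gene outranks an out-of-set gene.
Each retained ontology term `s` is a module of `k` units (default 6):

```
E_s = f( W_M·M_s + W_A·A_s + W_D·D_s + W_NES·NES_s
         + Σ_{c ∈ children(s)} (W_c·E_c + W_NESc·NES_c) + b_s ),
```

with `f` = tanh followed by batch normalization. The root embedding is
concatenated with a drug embedding (fingerprint bits ‖ molecular
descriptors through a 100–50–6 dense branch) and a small head predicts the
AUC. Training is Adam with a multinomial weighted sampler and the
double-weighted loss `L(p,t) = max(w_bin(p), w_bin(t))·(p−t)²`, where `w`
are smoothed inverse bin frequencies over twelve AUC bins on [0, 1.2] —
both countermeasures against the extreme skew of real drug screens.
Evaluation is imbalance-aware as well: macro-averaged MSE over bins and
correlations on class-balanced resamples. Ablating a module (or its
children) yields the relative improvement score
`RIS = (s_cf − s_f)/(s_cf + s_f)` per (cell, drug, term), whose top-ranked
terms drive candidate combination partners scored by a one-sided binomial
enrichment test. A twin-drug (Siamese) variant with focal loss classifies
drug-pair synergy.

## Worked example

```r
library(movida)

# a complete synthetic study: ontology, cohort, drugs, AUC triplets
ps  <- simulate_preset("default", seed = 1)   # 200 cells x 40 drugs, 40 terms
lay <- ps$layout
sim <- ps$sim

cfg <- movida_config(epochs = 40, batch_size = 128, learning_rate = 5e-3,
                     seed = 1)
model <- build_model(lay, cfg, n_drug_features = ncol(sim$drugs))
fit   <- train_model(model, sim$cohort, sim$drugs, sim$triplets)

te    <- fit$split$test
preds <- predict_batch(fit$model, sim$cohort, sim$drugs, sim$triplets[te, ])
bc    <- balanced_correlation(preds$predicted_auc, sim$triplets$auc[te],
                              runs = 500, seed = 1)
rep   <- macro_mse(preds$predicted_auc, sim$triplets$auc[te])
cat(sprintf("balanced Pearson %.3f / Spearman %.3f, MMSE %.4f\n",
            bc$pearson, bc$spearman, rep$mmse))
```

```
balanced Pearson 0.730 / Spearman 0.713, MMSE 0.0751
```

The balanced correlations are computed on equal-size resamples from every
occupied AUC bin, so they are not inflated by the no-effect majority class;
the macro-averaged MSE (here 0.075 against 0.160 for a constant
mean-predictor) averages per-bin errors so the rare sensitive bins count as
much as the common resistant ones. Pathway interpretation for one pair —
CL008 activates the planted causal pathway that drug D005 targets:

```r
leaves <- names(which(lengths(lay$children) == 0))
ris <- ris_scores(fit$model, sim$cohort, sim$drugs,
                  data.frame(cell_id = "CL008", drug_id = "D005"),
                  terms = leaves)
head(ris[order(-ris$ris), c("term", "s_f", "s_cf", "ris")], 5)
```

```
       term      s_f     s_cf   ris
 GO:SIM0026 0.076109 0.237888 0.515
 GO:SIM0028 0.004293 0.012246 0.481
 GO:SIM0040 0.016489 0.033340 0.338
 GO:SIM0018 0.000274 0.000459 0.252
 GO:SIM0029 0.001060 0.001749 0.245
```

`GO:SIM0026` is exactly the causal term this drug-cell pair engages in the
generator's ground truth, and its ablation deviations dwarf the rest.
`candidate_combinations()` turns the top five leaf terms into partner-drug
candidates via a target table, and `synergy_enrichment()` tests them
against validated combinations.

A thin command-line wrapper over the same functions lives at
`inst/scripts/movida.R`
(`simulate | train | predict | evaluate | explain | combine | train-synergy`,
each taking `--config`, `--seed`, `--out`).

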