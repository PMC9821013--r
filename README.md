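# qsarboost

Gradient-boosted QSAR modelling and virtual screening for covalent
KRAS G12C inhibitors.

The KRAS G12C oncoprotein — the most common KRAS mutation in
non-small-cell lung cancer — became druggable with covalent inhibitors
(sotorasib, adagrasib) that bond the mutant cysteine, but resistance
makes new chemical matter urgent. A practical shortcut is drug
repurposing: score already-approved covalent drugs against a model of
KRAS G12C potency and prioritize the hits. qsarboost implements that
workflow end to end for computational chemists and cheminformaticians:

* **Curation** — IC50 activity tables (ChEMBL/BindingDB-style exports)
  are converted to pIC50 = −log10 IC50 (M), deduplicated by canonical
  structure key keeping the most potent record, filtered at 1000 Da, and
  labelled active (pIC50 ≥ 6) or inactive, with a full curation log.
* **Features** — the conjoint fingerprint block (881 PubChem bits + 307
  substructure counts = 1188 columns) via pluggable providers, plus
  max–min normalization and a PCA chemical-space diagnostic.
* **Models** — a second-order gradient-boosted tree learner written from
  the regularized objective
  `L = Σ l(y, ŷ) + Σ [γT + ½λ‖w‖² + α‖w‖₁]`,
  with exact greedy split finding, closed-form leaf weights
  `w* = −soft(G, α)/(H + λ)`, and gain
  `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ`
  (L1-soft-thresholded when α > 0). One learner serves both heads:
  a logistic-loss active/inactive classifier and a squared-loss pIC50
  regressor. The xgboost library is an optional backend and the
  independent cross-check in the tests.
* **Validation** — accuracy and ROC AUC, MAE and R²/Q², 5-fold
  cross-validation, Y-randomization (label scrambling, n = 100), and a
  standardized-residual applicability domain flagging |z| > 3.
* **Explanation** — exact Shapley values (exhaustive over feature
  subsets, tree-conditional expectations) for compact models, delegated
  TreeSHAP for the full 1188-column block, and a global mean-|SHAP|
  importance ranking.
* **Screening** — both heads score a candidate covalent-drug library
  into a ranked repurposing table (predicted class, predicted pIC50).
* **Synthetic data** — a generator emulating the curated KRAS G12C
  dataset (1255 compounds, pIC50 6.56 ± 1.22, sparse bit→activity
  structure, a 67-candidate library with 7 true hits) so the entire
  pipeline runs and is tested fully offline.

## Worked example

```r
library(qsarboost)

spec <- generator_spec(seed = 7)              # study-scale synthetic data
raw  <- generate_activity_table(spec)         # raw export, with curation work
cur  <- curate_dataset(raw$table)
cur$records <- split_train_test(cur$records, train_fraction = 0.7, seed = 8)
print(cur)
#> Curated dataset: 1255 compounds (860 active, 395 inactive)
#>   input                        removed    0, remaining 1320
#>   unparseable_structure        removed    0, remaining 1320
#>   duplicate_structure          removed   45, remaining 1275
#>   molecular_weight_gt_1000     removed   20, remaining 1255
#>   curated                      removed    0, remaining 1255

x  <- raw$dataset$features$values[cur$records$compound_id, ]
tr <- cur$records$split == "train"

regressor  <- qsar_boost(x[tr, ], cur$records$pic50[tr],
                         boost_params(loss = "squared", alpha = 0.1))
classifier <- qsar_boost(x[tr, ], (cur$records$activity == "active")[tr],
                         boost_params(loss = "logistic"))

q2  <- r2_score(cur$records$pic50[!tr], predict(regressor, x[!tr, ]))
err <- mae(cur$records$pic50[!tr], predict(regressor, x[!tr, ]))
round(c(q2_ext = q2, mae_ext = err), 2)
#>  q2_ext mae_ext
#>    0.74    0.45

lib <- generate_candidate_library(spec)       # 67 candidates, 7 true hits
print(screen_library(lib$candidates, classifier, regressor, lib$features))
#> Screening report: 67 candidates scored, 7 predicted active
#>    1. CAND060      active   pIC50 = 8.21
#>    2. CAND009      active   pIC50 = 8.11
#>    3. CAND012      active   pIC50 = 7.50
#>    4. CAND006      active   pIC50 = 7.22
#>    5. CAND061      active   pIC50 = 6.78
#>    6. CAND010      active   pIC50 = 6.47
#>    7. CAND038      active   pIC50 = 6.32
#>    8. CAND005      inactive pIC50 = 5.15
#>   ...
```

An external Q² of 0.74 with MAE 0.45 pIC50 units means the regressor
explains most of the held-out potency variance with errors under half a
log unit, and the screen recovers the planted hits: the model ranks the 7
constructed actives at the top of the 67-drug library with predicted
potencies above the activity threshold, mirroring how a real repurposing
screen surfaces a handful of covalent drugs as candidate KRAS G12C
inhibitors.

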