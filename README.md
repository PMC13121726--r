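# couchshift

Two-stage analysis of per-patient CBCT session trajectories in prostate
radiotherapy, for medical physicists and clinical data scientists who want
a *baseline* (planning-CT) rectal-volume cutoff that flags patients at
risk of unstable setup during treatment.

Each imaging session contributes three features: the rectal-volume change
ΔRV = V<sub>CBCT</sub> − V<sub>planning</sub> (cm³), the couch
displacement magnitude √(ΔVrt² + ΔLng² + ΔLat²) (cm), and the rectal
volume itself. **Stage 1** embeds each patient's standardized, padded,
masked feature sequence with a Transformer autoencoder (d_model = 64,
4 heads, 2 encoder layers, feed-forward 128; masked mean pooling over
real tokens; model selection by 5-fold grouped cross-validation on masked
reconstruction MSE), implemented natively in R with hand-derived
backpropagation and Adam. **Stage 2** clusters the patient embeddings
with K-means (k = 3), renumbers clusters so median baseline volume
ascends (cluster 2 = high-volume group), and derives the operating cutoff
from the ROC curve of baseline volume against cluster-2 membership by
maximizing Youden's J = sensitivity + specificity − 1. The surrounding
statistical chain (Shapiro–Wilk, Spearman, Kruskal–Wallis, pairwise
Bonferroni-corrected Mann–Whitney U) matches standard clinical reporting.
A synthetic cohort simulator with planted patient groups and a known
decision boundary makes every stage testable.

## Worked example

```r
library(couchshift)

report <- run_pipeline(run_config(
  simulation = separated_cohort_config(),  # benchmark cohort, known truth
  seed       = 1
))
print(report)
#> couchshift run: 38 patients, 507 CBCT sessions
#>   rectal volume mean/median: 62.71 / 63.30 cm3
#>   CV reconstruction MSE (selected fold 1): 0.0041
#>   cluster sizes: 14, 13, 11
#>   Kruskal-Wallis p = 7.57e-08
#>   ROC AUC = 1.000; Youden cutoff = 79.88 cm3 (J = 1.000)
```

Reading the output: the simulator planted three patient groups whose
baseline volumes separate at (65 + 100)/2 = 82.5 cm³. The pipeline —
which never sees the labels — recovers three clusters whose
high-volume cluster is perfectly separable by baseline volume
(AUC = 1.0), and places the operating cutoff at 79.9 cm³, about 3% from
the planted boundary. The Kruskal–Wallis p-value says baseline volume
differs strongly across the recovered clusters. Against the planted
labels the clustering reaches an adjusted Rand index of 0.91:

```r
truth <- report$truth$group_labels
mclust::adjustedRandIndex(report$canonical$labels[names(truth)], truth)
#> [1] 0.9148244
```

A patient whose planning-CT rectal volume exceeds the cutoff would be
flagged for bowel-preparation review before treatment starts.

`default_cohort_config()` simulates the realistic, *overlapping* cohort
(38 patients, ~494 CBCTs, mean volume ≈ 65 cm³, median ≈ 58.5 cm³); there
only the high-volume group is reliably separable, which is the clinically
relevant distinction. A thin command-line front end is included:

```sh
Rscript inst/cli/couchshift.R simulate --out cohort.csv --seed 7
Rscript inst/cli/couchshift.R run --input cohort.csv --out-dir results --seed 1
```

Runs write `cohort.csv`, `embeddings.csv`, `clusters.csv` and
`report.json` (plus optional t-SNE/box/ROC figures with `--figures`).

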