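# masir

Marker-assisted standardization and integration of single-cell RNA-seq data.

## The problem

Reference-based annotation of scRNA-seq data usually means training a model —
an SVM, a deep autoencoder, a harmonized latent space — and paying for it in
compute, memory and tuning. `masir` implements a model-free alternative for
analysts who need to transfer cell-type labels from a labelled reference onto
query datasets (often spanning several batches, platforms or labs) on modest
hardware: instead of learning a latent space, it converts the expression
matrix into a **cell-type score matrix** built from marker genes, and uses
that low-dimensional, biologically interpretable space for both annotation
and batch integration.

## The method

1. **Marker discovery.** Per cell type, one-vs-rest differential-expression
   scores (`wilcoxon`, `welch_t`, `logfc`, `cosg`) rank all genes; the
   per-method rankings are combined either by **robust rank aggregation** —
   each gene scored by ρ(g) = min<sub>k</sub> P(β<sub>(k)</sub> ≤ r<sub>(k)</sub>),
   the smallest Beta order-statistic probability of its normalized ranks
   r<sub>(1)</sub> ≤ … ≤ r<sub>(m)</sub> — or by **Lancaster p-value
   combination**, T = Σ<sub>j</sub> Q(1 − p<sub>j</sub>; w<sub>j</sub>),
   which reduces to Fisher's method at weights w<sub>j</sub> = 2.
2. **Marker weighting.** The i-th of N ranked markers contributes
   w<sub>i</sub> = 1 − (i/N)/2 of its expression (w<sub>1</sub> = 1): the top
   marker counts 100%, the last 50%.
3. **Scoring.** score(c, A) = Σ<sub>g∈markers(A)</sub> w<sub>g</sub> ·
   x(c, g) on the log-normalized matrix; the default *PlinerScore* variant
   first suppresses each marker's values below its 25th percentile and
   applies a TF-IDF transform, idf(g) = ln(1 + n/(1 + n<sub>expressing</sub>)).
4. **Consensus annotation.** Each cell gets an argmax label (Label 1); the
   score matrix is over-clustered by Louvain at resolutions {3, 5, 7} ×
   neighbourhood sizes {5, 10, 15} (Label 2 ensemble); each cluster adopts
   its majority Label 1 and the per-cell consensus is the mode over the nine
   runs. A certainty score C = 1 − D<sub>1st</sub>/D<sub>Nth</sub>
   (nearest vs farthest reference centroid) flags cell types absent from the
   reference: cells below a threshold (default 0.55) can be relabelled
   `unassigned`.

Evaluation metrics (overall accuracy, macro F1, rescaled cell-type
silhouette, normalized batch-entropy mixing, ARI, NMI) and a multi-batch
negative-binomial simulator with known ground truth are included.

## Worked example

```r
library(masir)

sim <- simulate_multibatch(n_types = 4, n_cells_per_type_per_batch = 100,
                           n_batches = 2, n_genes = 400,
                           n_markers_per_type = 10, fold_change = 4,
                           batch_effect_sd = 1, seed = 42)
fit <- masi(sim$expr, sim$truth$cell_type, top_k = 10)
fit
#> Marker-assisted annotation model
#>   reference: 800 cells, 4 cell types
#>   markers:   4 types, 10-10 genes per type (wilcoxon+welch_t+logfc+cosg, top_k_rra)
#>   scoring:   pliner (X = 0.25, weights on)

ann <- predict(fit, sim$expr, seed = 42)
head(as.data.frame(ann), 3)
#>     cell_id label certainty tie_flag
#> 1 cell00001 type1 0.7694241    FALSE
#> 2 cell00002 type1 0.8525784    FALSE
#> 3 cell00003 type1 0.5487544    FALSE

evaluate_annotation(ann$label, sim$truth$cell_type,
                    representation = attr(ann, "scores"),
                    batch = sim$truth$batch, seed = 42)
#> masi_metrics:
#>   accuracy        0.9113
#>   macro_f1        0.9110
#>   ari             0.7777
#>   nmi             0.7257
#>   silhouette      0.6789
#>   entropy_mixing  0.9198
```

Reading the report: 91% of the 800 cells recover their true type and macro
F1 ≈ 0.91 says the recovery is balanced across the four types; a silhouette
of 0.68 on the score matrix means cell-type structure is preserved in the
integration space, while an entropy-mixing score of 0.92 means the two
simulated batches are locally well mixed there — the "good balance" the
score-matrix representation is designed for. Certainty values near 1 mark
cells solidly inside a reference type.

The same chain is scriptable: `run_pipeline("config.yaml")` (or the
`exec/masi` command-line wrapper with subcommands `simulate`, `markers`,
`score`, `annotate`, `evaluate`, `run`) reads reference/query matrices in
Matrix Market or dense form and writes `markers.csv`, `scores.tsv`,
`annotation.tsv` and `report.json`.

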