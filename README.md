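# scdec

Deep embedded clustering of single-cell RNA-seq count data with
batch-effect removal through iterative self-training.

## What it does, and for whom

A recurring problem in scRNA-seq analysis: cells must be clustered into
putative types, but technical batch effects (processing day, chip,
protocol, donor) distort expression in ways that split or smear real
clusters. `scdec` addresses both at once. A stacked autoencoder learns a
low-dimensional embedding of the normalized expression matrix; Louvain
community detection on the embedding supplies the number of clusters K
and initial centroids; then cells are softly assigned to centroids with
a Student-*t* kernel,

```
q_ij = (1 + ||z_i − μ_j||²/α)⁻¹ / Σ_j' (1 + ||z_i − μ_j'||²/α)⁻¹ ,
```

and encoder weights and centroids are jointly optimized by SGD on the
Kullback–Leibler divergence KL(P‖Q) against the self-training target

```
p_ij = (q_ij² / f_j) / Σ_j' (q_ij'² / f_j'),   f_j = Σ_i q_ij ,
```

which concentrates probability on confident assignments. Training stops
when fewer than `tol = 0.005` of the cells change hard assignment
between consecutive target updates. Because the sharpening force acts on
coherent within-cluster displacements, batch structure is removed
gradually over iterations without ever requiring batch labels. The
package also provides the two evaluation instruments used to judge such
methods — the adjusted Rand index and a kNN-based batch-mixing KL
divergence — plus a negative-binomial simulator with planted clusters
and a configurable batch-distortion knob, so the whole pipeline is
testable end to end without any external data.

Intended users: computational biologists clustering UMI count matrices
(MTX bundles or dense CSV/TSV) who want batch-robust, probabilistic
cluster assignments with reproducible, seed-stable runs.

## Worked example

```r
library(scdec)

d  <- simulate_counts(scenario_config("easy", seed = 1))   # 900 cells, 3 clusters, 2 batches
xp <- preprocess_counts(count_matrix(d$counts))            # normalize, log, z-score
fit <- dec_fit(xp, dec_config(seed = 1))                   # pretrain → Louvain → self-train

fit
#> dec_fit: 900 cells, K = 3, 300 epochs (converged), final change fraction 0.002222

adjusted_rand_index(fit$labels, d$true_labels)
#> [1] 0.9538983

batch_mixing_kl(fit$embedding_init, d$batch_labels, seed = 1)$median  # before self-training
#> [1] 0.07977813
batch_mixing_kl(fit$embedding, d$batch_labels, seed = 1)$median       # after
#> [1] 0.06563191
```

The fit recovers the three planted clusters (ARI 0.95; 1.0 means perfect
agreement) and the self-training phase lowers the batch-mixing KL of the
embedding from 0.080 to 0.066 — closer to the metric's well-mixed floor
(≈ 0.05 at neighbourhood size 10) and far from the fully separated
ceiling ln 2 ≈ 0.693. `fit$max_prob` carries each cell's assignment
confidence, `fit$probabilities` the full soft-assignment matrix.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/scdec.R simulate --out sim --scenario easy --seed 1
Rscript inst/cli/scdec.R cluster  --input sim --out run --seed 1
Rscript inst/cli/scdec.R evaluate --out eval \
    --labels run/assignments.tsv --reference sim/truth.tsv \
    --embedding run/embedding.tsv --batch sim/batches.tsv
```

See `vignettes/deep-embedded-clustering.Rmd` for the model, parameter
guidance, and the simulator's design.

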