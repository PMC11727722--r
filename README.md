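# spadom

Spatial domain identification for spatial transcriptomics, combining a
**cell-type-aware spatial neighbor graph**, a **weight-tied graph attention
autoencoder**, and **multiscale deep subspace clustering** with
self-supervised refinement.

## Who this is for

Analysts of sequencing-based spatial transcriptomics (10x-Visium-style
arrays, STARmap, Stereo-seq) who need to partition a tissue section into
contiguous spatial domains — cortical layers, tumor compartments, organ
regions — from a spots × genes count matrix plus spot coordinates, and
then rank marker genes per domain.

## The model in brief

Spots are connected by a spatial neighbor network *A* (edge when the
Euclidean distance is `< rad_cutoff`, or symmetrized 6-NN for hexagonal
arrays, plus self-loops). An expression-only Louvain preclustering prunes
cross-cluster edges, giving the cell-type-aware graph. A graph attention
encoder embeds each spot by aggregating its neighborhood,

    h_i^(k) = ELU( Σ_{j∈S_i} att_ij^(k) · W_k h_j^(k-1) ),

with attention logits `Sigmoid(v_s·W_k h_i + v_r·W_k h_j)` softmaxed over
each neighborhood, and the two graphs' attention streams mixed as
`(1−α)·att_spatial + α·att_aware`. The decoder is tied (`Ŵ_k = W_kᵀ`,
shared attention). Each encoder layer k learns a zero-diagonal
self-expression matrix `C_k` (`Z_k ≈ C_k Z_k`); the layers fuse into
`C_F = Σ τ_k C_k / Σ τ_k`, whose symmetrized absolute value
`Λ = ½(|C_F| + |C_Fᵀ|)` is spectrally clustered, and a small classifier
head is trained against those labels. The joint objective is

    L_total = L_1 + L_reg + λ·L_mss + L_sup

(reconstruction + weight decay, coefficient regularization, multiscale
self-expression, self-supervised cross-entropy). Final domains are called
on the learned embedding with Louvain/Leiden (resolution tuned to a target
domain count) or a Gaussian mixture, then optionally smoothed by a
neighborhood majority vote of radius `r`. Evaluation ships with ARI,
Davies–Bouldin, Calinski–Harabasz and S_Dbw, and per-domain Welch-t marker
ranking with BH correction.

See `vignettes/spadom-methods.Rmd` for the full model, parameter
meanings, defaults and design rationale.

## Worked example

Everything below runs on simulated tissue — no downloads.

```r
library(spadom)

spec <- synthetic_spec(rows = 12, cols = 12, k_domains = 3, n_genes = 40,
                       markers_per_domain = 8, seed = 7)
ds <- generate_layered_tissue(spec)
#> spot_dataset: 144 spots x 40 genes (raw counts)
#>   truth labels: 3 domains

cfg <- spadom_config(n_clusters = 3, target_k = 3, hidden_dims = c(64, 16),
                     epochs_pre = 200, epochs_joint = 150, refresh_every = 50,
                     lr = 1e-3, r_refine = 1.5, seed = 7)
res <- run_pipeline(ds, cfg, output_dir = file.path(tempdir(), "demo"))
#> [preprocess] 144 spots, 40 genes
#> [graph] building 6-NN spatial graph
#> [fit] pretrain 200 + joint 150 epochs (alpha=0, cost_ssc=0.1)
#> [cluster] method=louvain
#> [refine] neighborhood vote, r=1.5
#> [metrics] computing validity indices
#> [diffexp] ranking marker genes per domain
#> [done] 9.7 s, artifacts in /tmp/.../demo

str(res$metrics)
#> List of 4
#>  $ db   : num 0.494
#>  $ ch   : num 389
#>  $ s_dbw: num 0.136
#>  $ ari  : num 1
```

The three banded domains are recovered exactly (`ari = 1` against the
generator's truth labels); low Davies–Bouldin/S_Dbw and high
Calinski–Harabasz say the embedding separates the domains cleanly. The
top-ranked markers of domain 0 are its planted marker genes:

```r
head(res$markers[res$markers$domain == 0, c("domain","gene","t","p_adj","lfc")], 3)
#>   domain   gene        t        p_adj      lfc
#> 1      0 gene_3 12.65246 2.017324e-21 3.401027
#> 2      0 gene_5 12.56241 2.017324e-21 3.473948
#> 3      0 gene_6 12.38045 2.017324e-21 3.199133
```

`run_pipeline()` writes `labels.csv`, `embeddings.csv`, `loss_log.csv`,
`metrics.json`, `markers.csv` and a `config.json` echo to the output
directory. A command-line front end with `simulate` / `run` / `metrics` /
`de` subcommands lives at `inst/scripts/spadom-cli.R`, and preset
configurations for typical array geometries are in
`inst/extdata/presets/`.

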