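# scatacounts

Quantitative modeling of single-cell ATAC-seq fragment counts in R.

## The problem

scATAC-seq pipelines commonly (i) count *reads* — deduplicated fragment
ends — per peak per cell, and (ii) binarize the resulting matrix into an
open/closed indicator before modeling. Both steps damage the data. Reads
come in pairs (one Tn5 fragment contributes two ends), so read counts are
predominantly even and their variance is about **twice** their mean,
incompatible with any standard count distribution. Binarization then throws
away the quantitative accessibility signal that remains. Fragment counts,
in contrast, are approximately Poisson across cells (variance ≈ mean) and
carry usable biology: promoter accessibility correlates with gene
expression, and high-count peaks enrich for promoters of highly expressed
genes and super-enhancers.

`scatacounts` is for analysts who want to work with fragment counts
directly: it converts read matrices to fragment matrices, counts fragments
in peaks from 10x-style fragment files, runs the count-distribution
diagnostics (parity, mean–variance), and fits depth-aware variational
autoencoders with either a Poisson likelihood on fragment counts or a
Bernoulli likelihood on binarized counts, so the two modeling choices can
be compared on equal footing.

## The model

For fragment counts `X` (cells × peaks), batch label `s_c` and
log total fragment count `l_c = log Σ_p x_cp`:

    z_c   ~ Normal(f_mu(x_c), f_sigma(x_c))          # encoder
    rho_cp = g_p(z_c, s_c)                           # decoder + batch
    w_cp  = softmax_p(rho_cp + r_p)                  # per-region bias r_p
    lambda_cp = exp(l_c) * w_cp                      # depth as an offset
    x_cp  ~ Poisson(lambda_cp)

so `Σ_p lambda_cp` equals each cell's observed total exactly. The binary
variant models `y_cp = 1[x_cp > 0]` as
`y_cp ~ Bernoulli(sigmoid(rho_cp + r_p + ltilde_c))` with
`ltilde_c = logit(mean_p y_cp)`. Depth is a precomputed offset in both
models, never a learned factor. Poisson predictions are compared with
binary ones on the binarized reconstruction task via
`theta = 1 - exp(-lambda)` and average precision. Latent spaces are scored
with the standard integration panel (NMI, ARI, silhouettes, isolated-label
scores, graph connectivity, principal-component regression).

The encoder/decoder are two blocks of affine → dropout → layer-norm →
leaky-ReLU with hidden width `sqrt(P)`, trained by Adam (lr 1e-4, weight
decay 1e-3, minibatch 128) with early stopping on validation
reconstruction loss over an 80/10/10 split. The trainer is written in
plain R matrix algebra; gradients are verified against finite differences
in the test suite.

## Worked example

```r
library(scatacounts)

# synthetic fragment counts: 4 cell types, 2 batches, lognormal depth
sim <- simulate_fragments(n_cells = 700, n_peaks = 300,
                          depth_meanlog = log(90), seed = 1)
sim$matrix

# the paired-read artifact and its diagnostics
reads <- fragments_to_reads(sim$matrix, end_loss_prob = 0.1, seed = 1)
count_distribution(reads)$even_odd_ratio
median(mean_variance_profile(reads)$ratio, na.rm = TRUE)
median(mean_variance_profile(sim$matrix)$ratio, na.rm = TRUE)

# fit the Poisson VAE and inspect the latent space
model <- train_vae(sim$matrix, vae_config("poisson", n_latent = 10,
                                          max_epochs = 150, seed = 1))
emb <- get_latent(model, sim$matrix)
lv <- louvain_sweep(emb, sim$truth$cell_type, seed = 1)
ari_score(lv$membership, sim$truth$cell_type)
```

Output from this exact script:

```
#> count_matrix [fragments]: 700 cells x 300 peaks, 46905 nonzero (22.34%)
#>   batches: batch1, batch2
#>   cell types: type1, type2, type3, type4
#> [1] 6.111128          # even/odd parity ratio of the read matrix
#> [1] 2.692689          # median variance/mean of read counts
#> [1] 1.394367          # median variance/mean of fragment counts
#> [1] 0.9100542         # Louvain ARI against the true cell types
```

The read matrix shows a six-fold even-count excess and a variance/mean
ratio about twice that of the fragment matrix (2.69 vs 1.39 — both ratios
are lifted above their single-population values of 2 and 1 because this
dataset mixes four cell types and a spread of depths, which adds real
biological variance on top of the counting noise). Clustering the Poisson
VAE's latent space recovers the planted cell types almost perfectly at
this realistic sparsity.

A command-line wrapper covering the same functionality (simulate, count,
qc, train, embed, eval-recon, eval-embed, enrich, promoter-corr) is
installed at `system.file("cli", "scatac-counts", package = "scatacounts")`.

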