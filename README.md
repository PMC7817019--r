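# scdenoise

Self-supervised denoising of single-cell expression data with weighted
k-nearest-neighbor graphs and graph diffusion.

Single-cell UMI counts are dominated by Poisson sampling noise. A standard
remedy is neighbor averaging: build a kNN graph over cells, normalize it to
a right-stochastic transition matrix **M**, and smooth the expression matrix
**X** (cells × genes) as **MX**, optionally iterating (diffusion). The open
problem is tuning — the number of principal components *d* used for
distances, the number of neighbors *u*, the edge-weight mode, and the
diffusion depth *n* — because too much averaging destroys the biological
variance that downstream clustering, marker detection and network inference
depend on.

`scdenoise` selects all of these hyperparameters with a leave-self-out
objective that needs no ground truth. With

  s(M) = L⁻¹(M − V),  V = diag(M),  L = diag of off-diagonal row sums,

the prediction s(M)X estimates every entry of X from *other* cells only, so

  (d\*, u\*, n\*) = argmin ‖s(M̄ⁿ_{d,u})X − X‖² / (cells · genes),
  M̄₁ = M, M̄ₙ = s(M̄ₙ₋₁)s(M),

is an honest model-selection criterion: the diagonal is re-zeroed at every
diffusion step, so no cell ever predicts itself. The denoised matrix is
X\* = s(M̄ⁿ\*)X. The package also provides the surrounding toolkit:
count preprocessing (filtering, median depth normalization, Freeman-Tukey
transform √x + √(x+1) − 1), molecular cross-validation (binomial count
splitting) for PCA rank selection, singular-value variance diagnostics that
expose oversmoothing, synthetic count generators with known ground truth,
and Matrix Market / delimited / HDF5 readers and writers. It is aimed at
computational biologists tuning kNN/diffusion smoothers rather than
accepting heuristic defaults.

## Worked example

```r
library(scdenoise)

sim <- make_cluster_counts(300, 500, 3, seed = 42)   # known ground truth
x   <- freeman_tukey(median_normalize(sim$counts))

gs <- grid_search(x, pcs_grid = c(3, 10, 30),
                  neighbors_grid = c(5, 10, 25, 50, 100, 150), seed = 42)
gs
#> grid search over 36 point(s); best: mode=connectivities, neighbors=150,
#>   pcs=30, n*=1, MSE=0.880123

m   <- transition_matrix(build_knn(pca_embed(x, gs$best$pcs, seed = 42),
                                   gs$best$neighbors, seed = 42),
                         gs$best$mode)
den <- denoise(x, m)
den
#> denoised 300 x 500 matrix at diffusion depth n = 1 (objective MSE 0.880123)

target <- median(rowSums(sim$counts))
mse_to_truth(x, sim$truth, target_total = target, transform = "ftt")
#> [1] 0.9559661
mse_to_truth(den$denoised, sim$truth, target_total = target, transform = "ftt")
#> [1] 0.07316895
```

The self-supervised optimum uses a single averaging step (no diffusion),
and the denoised matrix sits ~13× closer to the true group means than the
preprocessed data — without the objective ever seeing those means.

A thin command-line front end wraps the same functions
(`inst/cli/scdenoise.R`; subcommands `simulate`, `preprocess`, `graph`,
`search`, `denoise`, `mcv`, `variance`, `eval`).

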