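#' Synthetic count-data generators
#'
#' These generators produce UMI-like count matrices with known ground
#' truth, so denoising, rank selection and correlation metrics can be
#' scored against the truth without external data. All of them sample
#' counts as `Poisson(depth_k * mean_gj)` for cell `k` in group `g`
#' (optionally negative binomial via `dispersion`), with log-normal
#' per-cell depth factors. Fixed seeds give bit-identical output.
#'
#' @name synthetic
NULL

.ground_truth <- function(true_means, labels, depths, params) {
  structure(list(true_means = true_means,
                 group_labels = labels,
                 depth_factors = depths,
                 generator_params = params),
            class = "ground_truth")
}

#' @exportS3Method base::print
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d group(s) x %d gene(s), %d cell(s)\n",
              nrow(x$true_means), ncol(x$true_means),
              length(x$group_labels)))
  invisible(x)
}

.sample_counts <- function(lambda, dispersion = NULL) {
  n <- length(lambda)
  if (is.null(dispersion)) rpois(n, lambda)
  else rnbinom(n, mu = lambda, size = dispersion)
}

.label_matrix <- function(x) {
  rownames(x) <- sprintf("cell%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("gene%04d", seq_len(ncol(x)))
  x
}

#' Clustered count matrix
#'
#' Draws one log-normal mean profile per group, assigns cells to groups
#' round-robin, and samples counts around `depth * group mean`.
#'
#' @param n_cells,n_genes,n_groups dimensions; `n_groups <= n_cells`.
#' @param mean_scale multiplies the group mean profiles; at the default
#'   the expected count per entry is around 2-3, a realistic UMI depth for
#'   moderately expressed genes.
#' @param depth_sigma log-normal sigma of the per-cell depth factors
#'   (default 0.3).
#' @param profile_sigma log-normal sigma of gene means within a profile
#'   (default 1), controlling between-group separation.
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson noise.
#' @param seed integer seed.
#' @return List with `counts` (cells x genes integer matrix) and `truth`
#'   (a `ground_truth`).
#' @export
make_cluster_counts <- function(n_cells, n_genes, n_groups, mean_scale = 2,
                                depth_sigma = 0.3, profile_sigma = 1,
                                dispersion = NULL, seed = 0L) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_groups >= 1, n_groups <= n_cells,
            mean_scale > 0)
  set.seed(as.integer(seed))
  profiles <- matrix(rlnorm(n_groups * n_genes, meanlog = 0,
                            sdlog = profile_sigma),
                     n_groups, n_genes)
  profiles <- profiles / rowMeans(profiles) * mean_scale
  labels <- rep_len(seq_len(n_groups), n_cells)
  depths <- rlnorm(n_cells, meanlog = 0, sdlog = depth_sigma)
  lambda <- depths * profiles[labels, , drop = FALSE]
  counts <- matrix(.sample_counts(lambda, dispersion), n_cells, n_genes)
  counts <- .label_matrix(counts)
  truth <- .ground_truth(profiles, labels, depths,
                         list(n_cells = n_cells, n_genes = n_genes,
                              n_groups = n_groups, mean_scale = mean_scale,
                              depth_sigma = depth_sigma,
                              profile_sigma = profile_sigma,
                              noise = if (is.null(dispersion)) "poisson"
                                      else "nbinom",
                              seed = as.integer(seed)))
  list(counts = counts, truth = truth)
}

#' Mixture-design count matrix
#'
#' Emulates mixture benchmarks in which each group of 'cells' is a known
#' proportion mix of a few pure RNA archetypes: the group mean profile is
#' the proportion-weighted combination of archetype profiles, and any
#' within-group variation is purely technical. Groups with nearby mixing
#' proportions have correlated means, giving the data a simplex structure
#' rather than well-separated clusters.
#'
#' @param n_per_group cells per group.
#' @param proportions groups x archetypes matrix; each row sums to 1.
#' @param archetypes archetypes x genes nonnegative profile matrix, or an
#'   integer number of archetypes to draw log-normally over `n_genes`.
#' @param n_genes required when `archetypes` is an integer count.
#' @param depth expected total counts scale: mean count per entry
#'   (default 2).
#' @param depth_sigma log-normal sigma of per-cell depths (default 0.3).
#' @param dispersion optional negative-binomial size; `NULL` = Poisson.
#' @param seed integer seed.
#' @return List with `counts` and `truth` as in [make_cluster_counts()].
#' @export
make_mixture_counts <- function(n_per_group, proportions, archetypes,
                                n_genes = NULL, depth = 2,
                                depth_sigma = 0.3, dispersion = NULL,
                                seed = 0L) {
  proportions <- as.matrix(proportions)
  if (any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("each row of `proportions` must sum to 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.numeric(archetypes) && length(archetypes) == 1L) {
    stopifnot(!is.null(n_genes))
    archetypes <- matrix(rlnorm(archetypes * n_genes, sdlog = 1),
                         as.integer(archetypes), n_genes)
  }
  archetypes <- as.matrix(archetypes)
  if (ncol(proportions) != nrow(archetypes))
    stop("ncol(proportions) must equal the number of archetype profiles",
         call. = FALSE)
  if (any(archetypes < 0)) stop("archetype profiles must be nonnegative",
                                call. = FALSE)
  means <- proportions %*% archetypes
  means <- means / mean(means) * depth
  n_groups <- nrow(proportions)
  labels <- rep(seq_len(n_groups), each = n_per_group)
  depths <- rlnorm(length(labels), meanlog = 0, sdlog = depth_sigma)
  lambda <- depths * means[labels, , drop = FALSE]
  counts <- matrix(.sample_counts(lambda, dispersion),
                   length(labels), ncol(means))
  counts <- .label_matrix(counts)
  truth <- .ground_truth(means, labels, depths,
                         list(n_per_group = n_per_group,
                              n_groups = n_groups,
                              n_genes = ncol(means), depth = depth,
                              depth_sigma = depth_sigma,
                              noise = if (is.null(dispersion)) "poisson"
                                      else "nbinom",
                              seed = as.integer(seed)))
  list(counts = counts, truth = truth)
}

#' Evenly spread points on the 3-archetype simplex
#'
#' Convenience proportion grid for [make_mixture_counts()]: the three
#' vertices, the three edge midpoints, the centroid, and (for `n = 8`) a
#' near-vertex interior point.
#'
#' @param n number of grid points (up to 8).
#' @return `n x 3` proportion matrix with unit row sums.
#' @export
simplex_proportions <- function(n = 8) {
  grid <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
                c(1, 1, 1) / 3, c(0.7, 0.15, 0.15))
  stopifnot(n >= 1, n <= nrow(grid))
  grid[seq_len(n), , drop = FALSE]
}

#' Low-rank count matrix
#'
#' Poisson counts around an exactly rank-`r` nonnegative mean matrix
#' (`W %*% H` with gamma-distributed factors), the fixture for molecular
#' cross-validation rank recovery.
#'
#' @param n_cells,n_genes dimensions.
#' @param rank true rank `r <= min(n_cells, n_genes)`.
#' @param signal mean count per entry (default 5, a moderate sequencing
#'   depth at which the low-rank structure stands above Poisson noise
#'   without being trivial).
#' @param depth_sigma log-normal sigma of per-cell depths (default 0.3).
#' @param seed integer seed.
#' @return List with `counts` and `truth`; `truth$true_means` is the full
#'   cells x genes rank-`r` mean matrix and `group_labels` is all-ones.
#' @export
make_lowrank_counts <- function(n_cells, n_genes, rank, signal = 5,
                                depth_sigma = 0.3, seed = 0L) {
  stopifnot(rank >= 1, rank <= min(n_cells, n_genes), signal > 0)
  set.seed(as.integer(seed))
  W <- matrix(stats::rgamma(n_cells * rank, shape = 1), n_cells, rank)
  H <- matrix(stats::rgamma(rank * n_genes, shape = 1), rank, n_genes)
  means <- W %*% H
  means <- means / mean(means) * signal
  depths <- rlnorm(n_cells, meanlog = 0, sdlog = depth_sigma)
  lambda <- depths * means
  counts <- matrix(rpois(length(lambda), lambda), n_cells, n_genes)
  counts <- .label_matrix(counts)
  truth <- .ground_truth(means, rep(1L, n_cells), depths,
                         list(n_cells = n_cells, n_genes = n_genes,
                              rank = rank, signal = signal,
                              depth_sigma = depth_sigma, noise = "poisson",
                              seed = as.integer(seed)))
  list(counts = counts, truth = truth)
}
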