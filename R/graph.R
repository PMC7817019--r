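#' PCA embedding for graph construction
#'
#' Computes gene-centered principal-component scores used as the space in
#' which cell-cell distances are measured. With `source = "expression"` the
#' (normalized) expression matrix itself is returned and no projection is
#' done, for graph construction directly on expression values.
#'
#' @param x expression matrix, cells in rows, genes in columns.
#' @param n_components number of components `d`; must not exceed
#'   `min(cells, genes)`.
#' @param seed integer seed (kept for interface stability; the dense solver
#'   used here is deterministic).
#' @param center center gene columns before projection (default `TRUE`).
#' @param source `"pca"` or `"expression"`.
#' @return A dense `cells x d` score matrix with attributes `n_components`
#'   and `source`.
#' @export
pca_embed <- function(x, n_components, seed = 0L, center = TRUE,
                      source = c("pca", "expression")) {
  source <- match.arg(source)
  x <- .as_input_matrix(x)
  if (source == "expression") {
    scores <- .dense(x)
    attr(scores, "n_components") <- ncol(scores)
    attr(scores, "source") <- "expression"
    return(scores)
  }
  d_max <- min(nrow(x), ncol(x))
  if (n_components > d_max)
    stop(sprintf("n_components = %d exceeds min(cells, genes) = %d",
                 n_components, d_max), call. = FALSE)
  xd <- .dense(x)
  if (center) xd <- sweep(xd, 2L, colMeans(xd), "-")
  sv <- svd(xd, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(n_components)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(x)
  attr(scores, "n_components") <- n_components
  attr(scores, "source") <- "pca"
  scores
}

# Brute-force exact kNN: returns list(idx, dist), each cells x u,
# self excluded, distance ties broken by lowest cell index.
.knn_brute <- function(emb, u) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(emb)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  idx <- matrix(0L, n, u)
  dst <- matrix(0, n, u)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))[seq_len(u)]  # secondary key = index
    idx[i, ] <- o
    dst[i, ] <- sqrt(d2[i, o])
  }
  list(idx = idx, dist = dst)
}

# Smooth-kNN calibration of distances to [0, 1] memberships, with per-cell
# bandwidth sigma_i solving sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(u),
# rho_i the distance to the nearest neighbor.
.smooth_knn <- function(dst, target = log2(ncol(dst)), n_iter = 64,
                        tol = 1e-5) {
  n <- nrow(dst)
  u <- ncol(dst)
  p <- matrix(0, n, u)
  for (i in seq_len(n)) {
    d <- dst[i, ]
    rho <- min(d)
    shifted <- pmax(d - rho, 0)
    if (all(shifted == 0)) { p[i, ] <- 1; next }
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in seq_len(n_iter)) {
      val <- sum(exp(-shifted / sigma))
      if (abs(val - target) < tol) break
      if (val > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
    }
    p[i, ] <- exp(-shifted / sigma)
  }
  p
}

#' Build a k-nearest-neighbor graph
#'
#' Finds each cell's `u` nearest neighbors (self excluded) by Euclidean
#' distance in the embedding, and calibrates the distances to `[0, 1]`
#' connectivity weights by a smooth per-cell kernel followed by fuzzy-union
#' symmetrization (`C + C' - C * C'`). Search is exact: brute force for
#' small data, a kd-tree above `brute_max` cells; `exact = TRUE` forces
#' brute force.
#'
#' @param emb embedding matrix from [pca_embed()] (or any cells x d matrix).
#' @param n_neighbors number of neighbors `u`, strictly less than the
#'   number of cells.
#' @param seed integer seed (interface stability; both search routes are
#'   deterministic).
#' @param exact force the brute-force route.
#' @param brute_max cell count up to which brute force is used.
#' @return A list of class `knn_graph` with sparse `distances` and
#'   `connectivities` matrices (cells x cells), `n_neighbors` and `metric`.
#' @export
build_knn <- function(emb, n_neighbors, seed = 0L, exact = FALSE,
                      brute_max = 4096) {
  emb <- .dense(.as_input_matrix(emb, "emb"))
  n <- nrow(emb)
  u <- as.integer(n_neighbors)
  if (u >= n) stop(sprintf("n_neighbors = %d must be < number of cells (%d)",
                           u, n), call. = FALSE)
  if (u < 1L) stop("n_neighbors must be >= 1", call. = FALSE)
  if (exact || n <= brute_max) {
    nn <- .knn_brute(emb, u)
  } else {
    res <- RANN::nn2(emb, emb, k = u + 1L)
    # drop self (always nearest at distance 0 with distinct points)
    idx <- matrix(0L, n, u); dst <- matrix(0, n, u)
    for (i in seq_len(n)) {
      row <- res$nn.idx[i, ]
      dd <- res$nn.dists[i, ]
      keep <- row != i
      idx[i, ] <- row[keep][seq_len(u)]
      dst[i, ] <- dd[keep][seq_len(u)]
    }
    nn <- list(idx = idx, dist = dst)
  }
  ii <- rep(seq_len(n), each = u)
  jj <- as.integer(t(nn$idx))
  dd <- as.numeric(t(nn$dist))
  # guard exact duplicates: Matrix Market/sparse storage drops explicit
  # zeros, so floor stored distances at a tiny positive value
  dd[dd <= 0] <- .Machine$double.xmin
  D <- sparseMatrix(i = ii, j = jj, x = dd, dims = c(n, n))

  P <- .smooth_knn(nn$dist)
  Pm <- sparseMatrix(i = ii, j = jj, x = as.numeric(t(P)), dims = c(n, n))
  C <- Pm + Matrix::t(Pm) - Pm * Matrix::t(Pm)

  structure(list(distances = D, connectivities = C,
                 n_neighbors = u, metric = "euclidean",
                 cell_ids = rownames(emb)),
            class = "knn_graph")
}

#' @exportS3Method base::print
print.knn_graph <- function(x, ...) {
  cat(sprintf("kNN graph: %d cells, %d neighbors, metric = %s\n",
              nrow(x$distances), x$n_neighbors, x$metric))
  invisible(x)
}

#' Exponential decay kernel on kNN distances
#'
#' On the nonzero support of the distance matrix, replaces each distance
#' with `exp(-D_ij / d_bar)^alpha`, where `d_bar` is the mean of the
#' nonzero distances. Off-support entries stay zero; the result is not yet
#' row-stochastic.
#'
#' @param graph a `knn_graph` (or a sparse distance matrix).
#' @param alpha positive decay exponent; larger values downweight distant
#'   neighbors more sharply.
#' @return Sparse nonnegative weight matrix on the same support.
#' @export
kernel_from_distances <- function(graph, alpha = 1) {
  D <- if (inherits(graph, "knn_graph")) graph$distances else
    .as_input_matrix(graph, "graph")
  stopifnot(alpha > 0)
  nz <- if (.is_sparse(D)) D@x[D@x != 0] else D[D != 0]
  if (length(nz) == 0L) stop("distance matrix has no nonzero entries",
                             call. = FALSE)
  d_bar <- mean(nz)
  f <- function(v) exp(-v / d_bar)^alpha
  if (.is_sparse(D)) {
    .map_nonzeros(D, f)
  } else {
    out <- D
    out[D != 0] <- f(D[D != 0])
    out
  }
}

#' Decay kernel on connectivities
#'
#' Raises each connectivity weight (in `[0, 1]`) to the power `alpha`
#' elementwise; zeros are preserved.
#'
#' @param graph a `knn_graph` (or a sparse connectivity matrix).
#' @param alpha positive exponent.
#' @return Sparse weight matrix on the same support.
#' @export
kernel_from_connectivities <- function(graph, alpha = 1) {
  C <- if (inherits(graph, "knn_graph")) graph$connectivities else
    .as_input_matrix(graph, "graph")
  stopifnot(alpha > 0)
  vals <- if (.is_sparse(C)) C@x else C
  if (any(vals < 0 | vals > 1))
    stop("connectivities must lie in [0, 1]", call. = FALSE)
  .map_nonzeros(C, function(v) v^alpha)
}

#' Symmetrize a weight matrix
#'
#' Returns `(M + t(M)) / 2`. Applied to the kernel weights before row
#' normalization, so that the support becomes the union of in- and
#' out-edges and the subsequent transition matrix is better conditioned.
#'
#' @param m square weight matrix.
#' @return Symmetric matrix of the same storage class.
#' @export
symmetrize <- function(m) {
  m <- .as_input_matrix(m, "m")
  stopifnot(nrow(m) == ncol(m))
  (m + Matrix::t(m)) / 2
}

#' Row-normalize to a right-stochastic matrix
#'
#' Divides every row by its sum, so each row becomes a probability
#' distribution over cells and the matrix acts as a weighted-averaging
#' operator.
#'
#' @param m square nonnegative matrix with strictly positive row sums.
#' @return Right-stochastic matrix (rows sum to 1 within 1e-10).
#' @export
row_normalize <- function(m) {
  m <- .as_input_matrix(m, "m")
  rs <- as.numeric(if (.is_sparse(m)) Matrix::rowSums(m) else rowSums(m))
  bad <- which(rs <= 0)
  if (length(bad))
    stop(sprintf("row(s) %s have zero sum: isolated cell(s) with no usable neighbors",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  .scale_rows(m, 1 / rs)
}

#' Leave-self-out mapping s(.)
#'
#' Removes the diagonal of a right-stochastic matrix and renormalizes each
#' row: `s(M) = L^-1 (M - V)` with `V = diag(M)` and `L` the diagonal
#' matrix of off-diagonal row sums. The result predicts every cell from
#' other cells only (zero diagonal), which is what makes the downstream
#' mean-squared-error objective self-supervised rather than trivially
#' minimized by the identity. `s` is idempotent: applying it to its own
#' output changes nothing.
#'
#' @param m square right-stochastic matrix in which every row has at least
#'   one off-diagonal nonzero.
#' @return Right-stochastic matrix with exactly zero diagonal.
#' @export
deself <- function(m) {
  m <- .as_input_matrix(m, "m")
  stopifnot(nrow(m) == ncol(m))
  diag(m) <- 0
  if (.is_sparse(m)) m <- Matrix::drop0(m)
  rs <- as.numeric(if (.is_sparse(m)) Matrix::rowSums(m) else rowSums(m))
  bad <- which(rs <= 0)
  if (length(bad))
    stop(sprintf("cell(s) %s carry all transition mass on the diagonal; no usable neighbors",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  .scale_rows(m, 1 / rs)
}

#' Build the symmetrized right-stochastic transition matrix
#'
#' Convenience chain `kernel -> symmetrize -> row_normalize` on a kNN
#' graph: the canonical construction of the averaging operator `M` used by
#' [diffuse_objective()] and [denoise()]. The leave-self-out mapping
#' [deself()] is applied later, at each diffusion step.
#'
#' @param graph a `knn_graph` from [build_knn()].
#' @param mode `"distances"` (decay kernel on distances) or
#'   `"connectivities"` (power kernel on fuzzy connectivities).
#' @param alpha positive decay exponent (default 1).
#' @return Sparse right-stochastic matrix.
#' @export
transition_matrix <- function(graph, mode = c("distances", "connectivities"),
                              alpha = 1) {
  mode <- match.arg(mode)
  K <- if (mode == "distances") kernel_from_distances(graph, alpha)
       else kernel_from_connectivities(graph, alpha)
  row_normalize(symmetrize(K))
}
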