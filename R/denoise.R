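#' Leave-self-out neighbor prediction
#'
#' Computes `P %*% X`: entry `(k, j)` is the weighted average of gene `j`
#' over all cells except `k`, the invariant prediction of cell `k`'s
#' expression from its graph neighborhood. `P` must have an exactly zero
#' diagonal (apply [deself()] first) — otherwise a cell would contribute to
#' its own prediction and the self-supervised objective would be biased.
#'
#' @param p zero-diagonal right-stochastic cells x cells matrix.
#' @param x expression matrix, cells in rows.
#' @param check verify the zero-diagonal / stochasticity contract
#'   (default `TRUE`).
#' @return Dense predicted expression matrix, same dimensions as `x`.
#' @export
knn_predict <- function(p, x, check = TRUE) {
  p <- .as_input_matrix(p, "p")
  x <- .as_input_matrix(x, "x")
  if (nrow(p) != ncol(p) || ncol(p) != nrow(x))
    stop("`p` must be cells x cells and conformable with `x`", call. = FALSE)
  if (check) .check_invariant_operator(p)
  out <- .dense(p %*% x)
  dimnames(out) <- dimnames(x)
  out
}

.check_invariant_operator <- function(p, tol = 1e-10) {
  dg <- if (.is_sparse(p)) Matrix::diag(p) else diag(p)
  if (any(dg != 0))
    stop("transition matrix has nonzero diagonal; leave-self-out invariance violated",
         call. = FALSE)
  rs <- as.numeric(if (.is_sparse(p)) Matrix::rowSums(p) else rowSums(p))
  if (any(abs(rs - 1) > tol))
    stop("transition matrix rows do not sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' Mean squared error between two matrices
#'
#' Squared Frobenius norm of the difference divided by the number of
#' entries, so values are comparable across matrix sizes.
#'
#' @param x_hat,x matrices of identical dimensions.
#' @return Nonnegative scalar.
#' @export
mse <- function(x_hat, x) {
  x_hat <- .as_input_matrix(x_hat, "x_hat")
  x <- .as_input_matrix(x, "x")
  if (!all(dim(x_hat) == dim(x)))
    stop("dimension mismatch between `x_hat` and `x`", call. = FALSE)
  d <- x_hat - x
  sum(if (.is_sparse(d)) d@x^2 else d^2) / prod(dim(x))
}

#' Self-supervised diffusion objective
#'
#' Iterates the diffusion `B_1 = M`, `B_n = s(B_{n-1}) s(M)`, resetting the
#' diagonal to zero and renormalizing (the mapping `s`, [deself()]) at
#' every step so each step remains an invariant prediction, and records
#' `MSE_n = mse(s(B_n) X, X)` — the leave-self-out prediction error after
#' `n` steps of neighborhood averaging.
#'
#' Under `stop_rule = "run2best"` the iteration stops one step after the
#' first local minimum of the trace (the first `n` with
#' `MSE_{n+1} > MSE_n`); exact plateaus continue. Under `"full_scan"` it
#' always runs to `max_iterations`. If the leave-self-out mapping becomes
#' undefined at some step `n >= 2` (a row with all mass on the diagonal,
#' e.g. a two-cell graph whose second power is the identity) the trace is
#' truncated there.
#'
#' @param m right-stochastic transition matrix from [transition_matrix()].
#' @param x expression matrix the objective is evaluated on (the normalized
#'   expression values, not PC scores).
#' @param max_iterations cap on diffusion steps (default 20).
#' @param stop_rule `"run2best"` (default) or `"full_scan"`.
#' @return An `objective_trace`: list with `mse` (per-iteration trace),
#'   `optimal_iteration` (first argmin), and `stop_rule`.
#' @export
diffuse_objective <- function(m, x, max_iterations = 20,
                              stop_rule = c("run2best", "full_scan")) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(max_iterations >= 1)
  m <- .as_input_matrix(m, "m")
  x <- .as_input_matrix(x, "x")
  A <- deself(m)                 # s(M); errors if undefined at step 1
  sB <- A                        # s(B_1)
  trace <- mse(knn_predict(sB, x, check = FALSE), x)
  n <- 1L
  while (n < max_iterations) {
    B_next <- sB %*% A           # B_{n+1} = s(B_n) s(M)
    sB_next <- tryCatch(deself(B_next), error = function(e) NULL)
    if (is.null(sB_next)) break  # s undefined: trace ends here
    mse_next <- mse(knn_predict(sB_next, x, check = FALSE), x)
    trace <- c(trace, mse_next)
    n <- n + 1L
    sB <- sB_next
    if (stop_rule == "run2best" && mse_next > trace[n - 1L]) break
  }
  structure(list(mse = trace,
                 optimal_iteration = which.min(trace),
                 stop_rule = stop_rule,
                 max_iterations = max_iterations),
            class = "objective_trace")
}

#' @exportS3Method base::print
print.objective_trace <- function(x, ...) {
  cat(sprintf("objective trace (%s): %d step(s), optimal n* = %d, MSE* = %.6g\n",
              x$stop_rule, length(x$mse), x$optimal_iteration,
              min(x$mse)))
  invisible(x)
}

# s(B_n) for a given n, recomputed from M by the same recursion.
.invariant_operator_at <- function(m, n) {
  A <- deself(m)
  sB <- A
  if (n > 1L) for (k in 2:n) sB <- deself(sB %*% A)
  sB
}

#' Denoise an expression matrix
#'
#' Applies the invariant operator at the optimal diffusion depth:
#' `X* = s(B_{n*}) X`. When `trace` is omitted it is computed by
#' [diffuse_objective()]. `n_force` overrides the optimum, e.g. to produce
#' a deliberately oversmoothed matrix for diagnostics.
#'
#' @param x expression matrix, cells in rows.
#' @param m right-stochastic transition matrix.
#' @param trace an `objective_trace` for `(m, x)`, or `NULL` to compute it.
#' @param n_force force this diffusion depth instead of the trace optimum.
#' @param ... passed to [diffuse_objective()] when `trace` is `NULL`.
#' @return A `denoise_result`: list with dense `denoised` matrix, `trace`,
#'   `transition` (the input `m`) and `iteration` actually applied.
#' @export
denoise <- function(x, m, trace = NULL, n_force = NULL, ...) {
  x <- .as_input_matrix(x, "x")
  m <- .as_input_matrix(m, "m")
  if (is.null(trace)) trace <- diffuse_objective(m, x, ...)
  n_star <- if (!is.null(n_force)) as.integer(n_force) else
    trace$optimal_iteration
  op <- .invariant_operator_at(m, n_star)
  structure(list(denoised = knn_predict(op, x, check = FALSE),
                 trace = trace, transition = m, iteration = n_star),
            class = "denoise_result")
}

#' @exportS3Method base::print
print.denoise_result <- function(x, ...) {
  cat(sprintf("denoised %d x %d matrix at diffusion depth n = %d (objective MSE %.6g)\n",
              nrow(x$denoised), ncol(x$denoised), x$iteration,
              x$trace$mse[min(x$iteration, length(x$trace$mse))]))
  invisible(x)
}

#' Self-supervised hyperparameter grid search
#'
#' Evaluates the diffusion objective over a grid of principal-component
#' counts, neighbor counts and edge-weight modes, and returns the
#' configuration minimizing the leave-self-out MSE. For each number of
#' components the embedding is computed once; for each `(d, u)` the kNN
#' graph is built once and shared across modes. Ties are broken toward
#' fewer components, then fewer neighbors, then `"distances"` mode.
#' Infeasible grid points (e.g. `u >= cells`, `d > min(dim)`) are recorded
#' as skipped with a reason, never silently dropped.
#'
#' @param x normalized expression matrix, cells in rows.
#' @param pcs_grid integer vector of component counts `d`.
#' @param neighbors_grid integer vector of neighbor counts `u`.
#' @param modes subset of `c("distances", "connectivities")`.
#' @param alpha decay exponent passed to the kernel (default 1).
#' @param seed integer seed for the embedding / graph build.
#' @param max_iterations,stop_rule passed to [diffuse_objective()].
#' @param verbose print each grid point's optimum as it is evaluated.
#' @return A `grid_search_result`: list with `records` (one row per grid
#'   point: mode, neighbors, pcs, iteration, mse, status), `best` (the
#'   winning row), and `best_trace`.
#' @export
grid_search <- function(x, pcs_grid, neighbors_grid,
                        modes = c("distances", "connectivities"),
                        alpha = 1, seed = 0L, max_iterations = 20,
                        stop_rule = c("run2best", "full_scan"),
                        verbose = FALSE) {
  stop_rule <- match.arg(stop_rule)
  modes <- match.arg(modes, several.ok = TRUE)
  x <- .as_input_matrix(x, "x")
  stopifnot(length(pcs_grid) > 0, length(neighbors_grid) > 0)
  n_cells <- nrow(x)
  d_max <- min(dim(x))

  rows <- list()
  traces <- list()
  for (d in sort(unique(as.integer(pcs_grid)))) {
    if (d > d_max) {
      for (u in neighbors_grid) for (mode in modes)
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, neighbors = u, pcs = d, iteration = NA_integer_,
          mse = NA_real_, status = sprintf("skipped: pcs > min(dim) = %d", d_max))
      next
    }
    emb <- pca_embed(x, d, seed = seed)
    for (u in sort(unique(as.integer(neighbors_grid)))) {
      if (u >= n_cells) {
        for (mode in modes)
          rows[[length(rows) + 1L]] <- data.frame(
            mode = mode, neighbors = u, pcs = d, iteration = NA_integer_,
            mse = NA_real_, status = sprintf("skipped: neighbors >= cells = %d", n_cells))
        next
      }
      graph <- build_knn(emb, u, seed = seed)
      for (mode in modes) {
        m <- transition_matrix(graph, mode = mode, alpha = alpha)
        tr <- diffuse_objective(m, x, max_iterations = max_iterations,
                                stop_rule = stop_rule)
        key <- sprintf("%s|%d|%d", mode, u, d)
        traces[[key]] <- tr
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, neighbors = u, pcs = d,
          iteration = tr$optimal_iteration,
          mse = min(tr$mse), status = "ok")
        if (verbose)
          message(sprintf("mode=%s u=%d d=%d -> n*=%d MSE=%.6g",
                          mode, u, d, tr$optimal_iteration, min(tr$mse)))
      }
    }
  }
  records <- do.call(rbind, rows)
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("no feasible grid point", call. = FALSE)
  ord <- order(ok$mse, ok$pcs, ok$neighbors,
               match(ok$mode, c("distances", "connectivities")))
  best <- ok[ord[1L], , drop = FALSE]
  structure(list(records = records, best = best,
                 best_trace = traces[[sprintf("%s|%d|%d", best$mode,
                                              best$neighbors, best$pcs)]],
                 alpha = alpha, seed = seed, stop_rule = stop_rule),
            class = "grid_search_result")
}

#' @exportS3Method base::print
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search over %d point(s); best: mode=%s, neighbors=%d, pcs=%d, n*=%d, MSE=%.6g\n",
              nrow(x$records), x$best$mode, x$best$neighbors, x$best$pcs,
              x$best$iteration, x$best$mse))
  invisible(x)
}

#' Diffusion without the per-step diagonal reset (diagnostic)
#'
#' Runs the same objective but with plain powers of `s(M)`: the diagonal is
#' zeroed once at the first step and never reset afterwards. From the
#' second step on, powers of `s(M)` accumulate diagonal mass, so each cell
#' increasingly predicts itself and the apparent MSE keeps dropping — a
#' self-referential overfit, not denoising. This variant exists only to
#' demonstrate that failure mode; it must never be used for model
#' selection.
#'
#' @param m right-stochastic transition matrix.
#' @param x expression matrix.
#' @param n_max number of steps to record.
#' @return An `objective_trace` (with `stop_rule = "no_reset"`).
#' @export
no_reset_variant <- function(m, x, n_max = 5) {
  m <- .as_input_matrix(m, "m")
  x <- .as_input_matrix(x, "x")
  A <- deself(m)
  P <- A
  trace <- mse(knn_predict(P, x, check = FALSE), x)
  for (n in seq_len(n_max - 1L)) {
    P <- P %*% A
    trace <- c(trace, mse(.dense(P %*% x), x))
  }
  structure(list(mse = trace, optimal_iteration = which.min(trace),
                 stop_rule = "no_reset", max_iterations = n_max),
            class = "objective_trace")
}
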