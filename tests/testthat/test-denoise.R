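test_that("knn_predict is the leave-self-out weighted average", {
  P <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3, byrow = TRUE)
  X <- matrix(c(1, 0, 2, 2, 3, 4), 3, 2, byrow = TRUE)
  expect_equal(knn_predict(P, X),
               matrix(c(2.5, 3, 2, 2, 1.5, 1), 3, 2, byrow = TRUE))
  expect_equal(mse(knn_predict(P, X), X), 3.75)

  # constant gene is predicted exactly
  Xc <- matrix(7, 3, 1)
  expect_equal(knn_predict(P, Xc), Xc)

  # random instance vs explicit double-loop oracle
  set.seed(20)
  P30 <- as.matrix(deself(rand_stochastic(30, 21)))
  X30 <- matrix(rnorm(30 * 5), 30, 5)
  expect_equal(knn_predict(P30, X30), predict_oracle(P30, X30),
               tolerance = 1e-10)

  expect_error(knn_predict(rand_stochastic(3, 1), X), "diagonal")
})

test_that("mse is the entry-mean squared Frobenius norm", {
  a <- matrix(rnorm(12), 3, 4)
  expect_identical(mse(a, a), 0)
  b <- a + 1
  expect_equal(mse(b, a), 1)
  expect_equal(mse(a + 2 * (b - a), a), 4 * mse(b, a))
  expect_error(mse(a, t(a)), "dimension")
})

test_that("diffusion trace matches the naive dense recomputation oracle", {
  for (seed in c(30, 31, 32)) {
    M <- rand_stochastic(40, seed)
    X <- matrix(rnorm(40 * 6), 40, 6)
    tr <- diffuse_objective(M, X, max_iterations = 5, stop_rule = "full_scan")
    expect_equal(tr$mse, diffusion_trace_oracle(M, X, 5), tolerance = 1e-9)
  }
})

test_that("every applied operator is zero-diagonal and right-stochastic", {
  M <- transition_matrix(build_knn(pca_embed(cluster_fixture(50, 60)$x, 5),
                                   6), "distances")
  for (n in 1:4) {
    op <- scdenoise:::.invariant_operator_at(M, n)
    expect_true(all(Matrix::diag(op) == 0))
    expect_true(all(abs(Matrix::rowSums(op) - 1) < 1e-10))
    expect_true(all((if (methods::is(op, "sparseMatrix")) op@x else op) >= 0))
  }
})

test_that("run2best stops one step past the first local minimum", {
  fx <- cluster_fixture(n_cells = 90, n_genes = 120)
  M <- transition_matrix(build_knn(pca_embed(fx$x, 5), 8), "distances")
  full <- diffuse_objective(M, fx$x, max_iterations = 10,
                            stop_rule = "full_scan")
  early <- diffuse_objective(M, fx$x, max_iterations = 10,
                             stop_rule = "run2best")
  # prefix property
  expect_equal(early$mse, full$mse[seq_along(early$mse)])
  # n* equals the full scan's first local minimum
  d <- diff(full$mse)
  first_min <- if (any(d > 0)) which(d > 0)[1] else length(full$mse)
  expect_equal(early$optimal_iteration, first_min)
  expect_equal(which.min(early$mse), early$optimal_iteration)
})

test_that("degenerate graphs truncate the trace instead of failing", {
  # two-cell toy: B2 is the identity, s undefined, trace stops at step 1
  M2 <- matrix(0.5, 2, 2)
  X2 <- matrix(c(0, 1), 2, 1)
  tr <- diffuse_objective(M2, X2, max_iterations = 5)
  expect_equal(tr$mse, 1)
  expect_equal(tr$optimal_iteration, 1L)

  # constant expression: stochastic rows average a constant exactly, so the
  # trace is zero up to floating rounding of the row renormalizations
  Xc <- matrix(3, 4, 2)
  M4 <- rand_stochastic(4, 33)
  trc <- diffuse_objective(M4, Xc, max_iterations = 4,
                           stop_rule = "full_scan")
  expect_true(all(trc$mse < 1e-20))
  expect_equal(which.min(trc$mse), trc$optimal_iteration)
})

test_that("denoise applies the operator at the trace optimum", {
  fx <- cluster_fixture(n_cells = 60, n_genes = 80)
  M <- transition_matrix(build_knn(pca_embed(fx$x, 5), 10), "distances")
  tr <- diffuse_objective(M, fx$x)
  res <- denoise(fx$x, M, trace = tr)
  if (tr$optimal_iteration == 1L)
    expect_identical(res$denoised, knn_predict(deself(M), fx$x))
  # recomputing from stored components reproduces the result exactly
  res2 <- denoise(fx$x, res$transition, trace = res$trace)
  expect_identical(res$denoised, res2$denoised)
  # forced oversmoothing runs deeper
  res4 <- denoise(fx$x, M, trace = tr, n_force = 4)
  expect_equal(res4$iteration, 4L)
  expect_false(identical(res4$denoised, res$denoised))
})

test_that("grid_search records the full grid and finds the exhaustive best", {
  fx <- cluster_fixture(n_cells = 70, n_genes = 90)
  gs <- grid_search(fx$x, pcs_grid = c(3, 6), neighbors_grid = c(5, 10, 80),
                    seed = 2)
  # infeasible u = 80 >= 70 recorded as skipped, not dropped
  skipped <- gs$records[gs$records$status != "ok", ]
  expect_equal(nrow(skipped), 4)
  expect_match(skipped$status[1], "neighbors >= cells")

  # best matches an independent exhaustive re-evaluation
  ok <- gs$records[gs$records$status == "ok", ]
  redo <- mapply(function(mode, u, d) {
    m <- transition_matrix(build_knn(pca_embed(fx$x, d, seed = 2), u,
                                     seed = 2), mode)
    min(diffuse_objective(m, fx$x)$mse)
  }, ok$mode, ok$neighbors, ok$pcs)
  expect_equal(min(redo), gs$best$mse, tolerance = 1e-12)
  expect_equal(ok$mse, unname(redo), tolerance = 1e-12)

  # one-point grid returns that point
  gs1 <- grid_search(fx$x, 3, 5, modes = "distances", seed = 2)
  expect_equal(nrow(gs1$records), 1)
  expect_equal(gs1$best$mse, min(gs1$best_trace$mse))

  # determinism
  gs2 <- grid_search(fx$x, pcs_grid = c(3, 6), neighbors_grid = c(5, 10, 80),
                     seed = 2)
  expect_identical(gs$records, gs2$records)
})

test_that("denoising at the grid optimum recovers the group means", {
  fx <- cluster_fixture(n_cells = 120, n_genes = 200, seed = 5)
  gs <- grid_search(fx$x, pcs_grid = c(3, 10), neighbors_grid = c(10, 30),
                    seed = 5)
  m <- transition_matrix(build_knn(pca_embed(fx$x, gs$best$pcs, seed = 5),
                                   gs$best$neighbors, seed = 5),
                         gs$best$mode)
  den <- denoise(fx$x, m)
  target <- median(rowSums(fx$sim$counts))
  err_raw <- mse_to_truth(fx$x, fx$sim$truth, target_total = target,
                          transform = "ftt")
  err_den <- mse_to_truth(den$denoised, fx$sim$truth, target_total = target,
                          transform = "ftt")
  expect_lt(err_den, err_raw)
})

test_that("skipping the diagonal reset turns diffusion self-referential", {
  fx <- cluster_fixture(n_cells = 120, n_genes = 200, seed = 5)
  M <- transition_matrix(build_knn(pca_embed(fx$x, 5, seed = 5), 10,
                                   seed = 5), "distances")
  reset <- diffuse_objective(M, fx$x, max_iterations = 5,
                             stop_rule = "full_scan")
  noreset <- no_reset_variant(M, fx$x, n_max = 5)
  # identical first step, then the self-referential trace dips below
  expect_equal(noreset$mse[1], reset$mse[1])
  expect_true(all(noreset$mse[2:5] < reset$mse[2:5]))
})
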