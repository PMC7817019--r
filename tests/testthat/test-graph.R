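test_that("pca_embed reproduces exact subspaces and conserves variance", {
  set.seed(10)
  # points exactly in a 2-D plane inside R^5
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  x <- matrix(rnorm(60), 30, 2) %*% t(basis)
  e <- pca_embed(x, 2)
  xc <- sweep(x, 2, colMeans(x))
  recon_err <- sum((xc - e %*% solve(crossprod(e), crossprod(e, xc)))^2)
  expect_lt(recon_err, 1e-18)

  # full-rank scores conserve total centered variance
  y <- matrix(rnorm(50 * 8), 50, 8)
  ef <- pca_embed(y, 8)
  expect_equal(sum(ef^2), sum(sweep(y, 2, colMeans(y))^2))

  # matches a dense SVD oracle up to column sign
  z <- matrix(rnorm(50 * 20), 50, 20)
  ez <- pca_embed(z, 5)
  sv <- svd(sweep(z, 2, colMeans(z)))
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  for (j in 1:5) {
    agree <- min(max(abs(ez[, j] - oracle[, j])),
                 max(abs(ez[, j] + oracle[, j])))
    expect_lt(agree, 1e-8)
  }

  expect_error(pca_embed(y, 9), "exceeds")
  # expression passthrough
  expect_equal(unname(pca_embed(y, 3, source = "expression")), y,
               ignore_attr = TRUE)
})

test_that("build_knn finds exact neighbors with index tie-breaks", {
  e <- matrix(c(0, 1, 10), 3, 1)
  g <- build_knn(e, 1)
  d <- as.matrix(g$distances)
  expect_equal(which(d[1, ] > 0), c("2" = 2L), ignore_attr = TRUE)
  expect_equal(which(d[2, ] > 0), 1L, ignore_attr = TRUE)
  expect_equal(which(d[3, ] > 0), 2L, ignore_attr = TRUE)
  expect_equal(d[3, 2], 9)

  # u = cells - 1 gives the complete graph minus the diagonal
  set.seed(11)
  e2 <- matrix(rnorm(12 * 3), 12, 3)
  g2 <- build_knn(e2, 11)
  expect_equal(Matrix::nnzero(g2$distances), 12 * 11)
  expect_true(all(Matrix::diag(g2$distances) == 0))

  # connectivity weights lie in [0, 1] and cover the distance support
  expect_true(all(g2$connectivities@x >= 0 & g2$connectivities@x <= 1))
  expect_true(all(as.matrix(g2$connectivities)[as.matrix(g2$distances) > 0] > 0))

  expect_error(build_knn(e, 3), "must be <")
})

test_that("kd-tree and brute-force search routes agree", {
  set.seed(12)
  e <- matrix(rnorm(500 * 5), 500, 5)
  g_brute <- build_knn(e, 10, exact = TRUE)
  g_tree <- build_knn(e, 10, brute_max = 0)
  overlap <- sum((g_brute$distances > 0) & (g_tree$distances > 0)) /
    Matrix::nnzero(g_brute$distances)
  expect_gte(overlap, 0.95)
})

test_that("distance kernel follows the mean-scaled exponential decay", {
  D <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 1), x = c(1, 2, 3))
  K <- kernel_from_distances(D, alpha = 1)   # d_bar = 2
  expect_equal(sort(K@x, decreasing = TRUE),
               c(exp(-0.5), exp(-1), exp(-1.5)))
  K2 <- kernel_from_distances(D, alpha = 2)
  expect_equal(K2@x, K@x^2)
  # support never enlarged, weights decreasing in distance
  expect_equal(which(as.matrix(K) != 0), which(as.matrix(D) != 0))

  Deq <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(4, 4))
  expect_equal(kernel_from_distances(Deq, alpha = 3)@x, rep(exp(-3), 2))

  expect_error(kernel_from_distances(Matrix::sparseMatrix(i = 1, j = 1,
                                                          x = 0,
                                                          dims = c(2, 2))),
               "no nonzero")
})

test_that("connectivity kernel is an elementwise power", {
  C <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.5, 1))
  expect_equal(kernel_from_connectivities(C, 1)@x, C@x)
  expect_equal(as.matrix(kernel_from_connectivities(C, 2)),
               as.matrix(C)^2, ignore_attr = TRUE)
  bad <- Matrix::sparseMatrix(i = 1, j = 2, x = 1.5, dims = c(2, 2))
  expect_error(kernel_from_connectivities(bad, 1), "\\[0, 1\\]")
})

test_that("symmetrize averages with the transpose", {
  M <- matrix(0, 2, 2); M[1, 2] <- 0.8
  S <- as.matrix(symmetrize(M))
  expect_equal(S[1, 2], 0.4)
  expect_equal(S[2, 1], 0.4)
  sym <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_equal(as.matrix(symmetrize(sym)), sym)
  # support is the union of M and t(M) supports
  Ms <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = c(1, 1),
                             dims = c(3, 3))
  expect_equal(which(as.matrix(symmetrize(Ms)) != 0),
               which((as.matrix(Ms) + t(as.matrix(Ms))) != 0))
})

test_that("row_normalize yields right-stochastic rows and flags isolates", {
  expect_equal(unname(as.matrix(row_normalize(matrix(c(1, 3), 1, 2)))),
               matrix(c(0.25, 0.75), 1))
  st <- rand_stochastic(5, 13)
  expect_equal(as.matrix(row_normalize(st)), st, tolerance = 1e-15)
  z <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_error(row_normalize(z), "2")
})

test_that("deself implements the leave-self-out mapping exactly", {
  expect_equal(as.matrix(deself(matrix(0.5, 2, 2))),
               matrix(c(0, 1, 1, 0), 2, 2))
  M <- matrix(c(0.5, 0.25, 0.25, 0.2, 0.6, 0.2, 0.3, 0.3, 0.4), 3, 3,
              byrow = TRUE)
  expect_equal(as.matrix(deself(M)),
               matrix(c(0, 0.5, 0.5, 0.5, 0, 0.5, 0.5, 0.5, 0), 3, 3,
                      byrow = TRUE))
  expect_error(deself(diag(3)), "diagonal")
})

test_that("deself matches the literal normalizer-matrix oracle and is idempotent", {
  for (seed in 1:20) {
    n <- sample(3:30, 1)
    M <- rand_stochastic(n, seed)
    S <- as.matrix(deself(M))
    expect_equal(S, deself_oracle(M), tolerance = 1e-12)
    expect_true(all(diag(S) == 0))
    expect_true(all(abs(rowSums(S) - 1) < 1e-10))
    expect_true(all(S >= 0))
    # idempotence: s(s(M)) = s(M)
    expect_equal(as.matrix(deself(S)), S, tolerance = 1e-12)
  }
})

test_that("graph pipeline is deterministic for fixed inputs", {
  fx <- cluster_fixture(n_cells = 60, n_genes = 80)
  m1 <- transition_matrix(build_knn(pca_embed(fx$x, 5, seed = 1), 8,
                                    seed = 1), "distances")
  m2 <- transition_matrix(build_knn(pca_embed(fx$x, 5, seed = 1), 8,
                                    seed = 1), "distances")
  expect_identical(as.matrix(m1), as.matrix(m2))
  expect_true(all(abs(Matrix::rowSums(m1) - 1) < 1e-10))
})
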