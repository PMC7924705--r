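test_that("one-level DWT meets the dimensional contract", {
  x <- matrix(runif(60 * 300), 60, 300)
  sb <- dwt_level1(x, "haar")
  for (band in c("LL", "LH", "HL", "HH"))
    expect_equal(dim(sb[[band]]), c(30L, 150L))
  # odd dimensions are extended, shapes are ceilings
  sbo <- dwt_level1(matrix(runif(7 * 9), 7, 9), "haar")
  expect_equal(dim(sbo$LL), c(4L, 5L))
  expect_true(sbo$meta$padded)
  expect_equal(dim(idwt_level1(sbo)), c(7L, 9L))
})

test_that("Haar sub-bands: constants and the 2x2 block oracle", {
  cst <- dwt_level1(matrix(7, 10, 12), "haar")
  expect_equal(max(abs(cst$LH)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cst$HL)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cst$HH)), 0, tolerance = 1e-12)
  expect_equal(as.vector(cst$LL), rep(14, 30), tolerance = 1e-12)

  set.seed(12)
  for (dims in list(c(4, 4), c(6, 8), c(60, 300))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    sb <- dwt_level1(x, "haar")
    oracle <- haar_block_oracle(x)
    for (band in c("LL", "LH", "HL", "HH"))
      expect_lt(max(abs(sb[[band]] - oracle[[band]])), 1e-10)
  }
})

test_that("orthonormal wavelets conserve energy and invert exactly", {
  set.seed(3)
  for (wav in c("haar", "db2", "db4")) {
    x <- matrix(rnorm(24 * 32, 128, 40), 24, 32)
    sb <- dwt_level1(x, wav)
    e_in <- sum(x^2)
    e_out <- sum(sb$LL^2) + sum(sb$LH^2) + sum(sb$HL^2) + sum(sb$HH^2)
    expect_lt(abs(e_in - e_out) / e_in, 1e-6)
    expect_lt(max(abs(idwt_level1(sb) - x)), 1e-8)
  }
  expect_error(dwt_level1(matrix(1, 4, 4), "coif1"), "unsupported")
})

test_that("PCA on a rank-1 configuration gives the hand-derived eigenpair", {
  v <- c(3, 4, 0)
  X <- rbind(v, -v)               # mean 0; scatter = 2 v v'
  m <- pca_fit(X, k = 2)
  expect_equal(m$mean, c(0, 0, 0))
  expect_equal(m$eigenvalues[1], 2 * sum(v^2), tolerance = 1e-10)
  expect_true(length(m$eigenvalues) == 1L ||
                max(abs(m$eigenvalues[-1])) < 1e-8)
  expect_equal(abs(m$eigenvectors[, 1]), abs(v / sqrt(sum(v^2))),
               tolerance = 1e-10)
  # sign convention: largest-magnitude entry positive
  expect_gt(m$eigenvectors[which.max(abs(m$eigenvectors[, 1])), 1], 0)
  # k = 1 projection of a training vector: +-|v| up to the sign convention
  f <- pca_project(m, v, k = 1)
  expect_equal(abs(f), sqrt(sum(v^2)), tolerance = 1e-10)
})

test_that("3x3 eigenvalues match the characteristic-polynomial oracle", {
  set.seed(8)
  X <- matrix(rnorm(3 * 3, 0, 2), 3, 3)
  m <- pca_fit(X, k = 3)
  C <- crossprod(sweep(X, 2, colMeans(X)))
  expect_equal(m$eigenvalues, eig3_charpoly(C), tolerance = 1e-8)
})

test_that("degenerate training sets are handled", {
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  m <- pca_fit(X)
  expect_true(all(m$eigenvalues == 0))
  expect_equal(m$k, 0L)
  expect_length(pca_project(m, c(1, 2, 3)), 0L)
  expect_error(pca_fit(matrix(1, 1, 5)), "at least 2")
})

test_that("the Gram-matrix route agrees with the direct route", {
  set.seed(21)
  X <- matrix(rnorm(10 * 50), 10, 50)           # d > N: Gram route
  m <- pca_fit(X, k = 9)
  Xz <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xz)
  direct <- eigen(C, symmetric = TRUE)
  expect_equal(m$eigenvalues[1:9], direct$values[1:9], tolerance = 1e-8)
  # eigenvectors agree up to the pinned sign convention
  for (i in 1:9) {
    e_d <- direct$vectors[, i]
    j <- which.max(abs(e_d)); if (e_d[j] < 0) e_d <- -e_d
    expect_lt(max(abs(m$eigenvectors[, i] - e_d)), 1e-8)
  }
  # orthonormality and the eigen-equation residual
  G <- crossprod(m$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(m$eigenvectors)))), 1e-8)
  nC <- norm(C, "F")
  for (i in seq_len(m$k)) {
    resid <- sqrt(sum((C %*% m$eigenvectors[, i] -
                         m$eigenvalues[i] * m$eigenvectors[, i])^2))
    expect_lt(resid, 1e-6 * nC)
  }
})

test_that("projection centers, truncates, and reconstructs at full rank", {
  set.seed(33)
  X <- matrix(rnorm(8 * 20), 8, 20)
  m <- pca_fit(X, k = 7)
  expect_equal(max(abs(pca_project(m, m$mean))), 0, tolerance = 1e-12)
  expect_length(pca_project(m, X[1, ], k = 3), 3L)
  # full-rank reconstruction of a training vector
  f <- pca_project(m, X[2, ], k = 7)
  rec <- m$mean + m$eigenvectors[, 1:7] %*% f
  expect_lt(max(abs(rec - X[2, ])), 1e-6)
  expect_error(pca_project(m, numeric(5)), "shape error")
  # retained dimension never exceeds N - 1
  expect_lte(m$k, 7L)
  m95 <- pca_fit(X, k = 0.95)
  expect_lte(m95$k, 7L)
  expect_gte(sum(m95$eigenvalues[seq_len(m95$k)]) / sum(m95$eigenvalues), 0.95)
})

test_that("extract_features is deterministic and separates subjects", {
  coh <- make_cohort(4, 2, 77, noise_sigma = 6)
  tpls <- lapply(coh$truths, function(g)
    rubber_sheet(g$image, list(pupil = g$spec$pupil, iris = g$spec$iris)))
  lls <- lapply(tpls, irispipe:::ll_vector)
  m <- pca_fit(do.call(rbind, lls))
  f1 <- extract_features(tpls[[1]], m)
  expect_identical(f1, extract_features(tpls[[1]], m))
  expect_length(f1, m$k)
  ids <- coh$manifest$subject_id
  same <- sqrt(sum((extract_features(tpls[[1]], m) -
                      extract_features(tpls[[2]], m))^2))
  cross <- sqrt(sum((extract_features(tpls[[1]], m) -
                       extract_features(tpls[[3]], m))^2))
  expect_equal(ids[1], ids[2])
  expect_false(ids[1] == ids[3])
  expect_lt(same, cross)
})
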