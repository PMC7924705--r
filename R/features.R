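# Feature extraction: one-level 2-D discrete wavelet transform of the
# normalized template, LL sub-band selection, then PCA projection. This is
# the compression chain that shrinks a 60x300 template to a feature vector
# of at most N (training-set size) components.

# Orthonormal analysis low-pass filters; the high-pass is the quadrature
# mirror g[n] = (-1)^n h[L-1-n] (0-based).
wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.83651630373746899,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stop("unsupported wavelet: ", name))
  L <- length(h)
  g <- rev(h) * (-1)^(0:(L - 1))
  list(h = h, g = g)
}

# Periodized one-level analysis of an even-length vector:
# a[k] = sum_m f[m] x[(2k + m) mod N], k = 0 .. N/2-1 (0-based).
dwt1d <- function(x, f) {
  N <- length(x); L <- length(f)
  k <- 0:(N / 2 - 1)
  out <- numeric(N / 2)
  for (m in 0:(L - 1)) out <- out + f[m + 1] * x[((2 * k + m) %% N) + 1]
  out
}

# Matching synthesis: x[n] = sum_k a[k] h[(n-2k) mod N] + d[k] g[(n-2k) mod N].
idwt1d <- function(a, d, flt) {
  N <- 2L * length(a); L <- length(flt$h)
  x <- numeric(N)
  for (k in 0:(length(a) - 1)) {
    n <- ((2 * k + 0:(L - 1)) %% N) + 1
    x[n] <- x[n] + a[k + 1] * flt$h + d[k + 1] * flt$g
  }
  x
}

#' One-level 2-D discrete wavelet decomposition
#'
#' Separable periodized transform: rows and columns are each split into
#' low- and high-pass halves, yielding the approximation LL and the detail
#' sub-bands LH, HL, HH, each of shape `(ceiling(m/2), ceiling(n/2))` for an
#' m x n input. Odd dimensions are first extended by replicating the last
#' row/column (recorded in `meta$padded`). For orthonormal wavelets on even
#' dimensions the transform conserves energy and [idwt_level1()] inverts it
#' exactly.
#'
#' @param x numeric matrix (a `polar_template` or any matrix with >= 2 rows
#'   and columns).
#' @param wavelet `"haar"`, `"db2"` or `"db4"`.
#' @return list of class `subband_set`: `LL`, `LH`, `HL`, `HH`, `wavelet`,
#'   `meta` (original dimensions, padding flag). `LH` carries the
#'   horizontal-detail (row low-pass, column high-pass) band.
#' @export
dwt_level1 <- function(x, wavelet = "haar") {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  flt <- wavelet_filters(wavelet)
  m0 <- nrow(x); n0 <- ncol(x)
  padded <- FALSE
  if (m0 %% 2L == 1L) { x <- rbind(x, x[m0, ]); padded <- TRUE }
  if (n0 %% 2L == 1L) { x <- cbind(x, x[, n0]); padded <- TRUE }
  # columns first: each column -> (approx; detail) halves
  col_txf <- function(m, f) matrix(apply(m, 2, dwt1d, f = f), ncol = ncol(m))
  row_txf <- function(m, f) {
    r <- apply(m, 1, dwt1d, f = f)
    if (is.matrix(r)) t(r) else matrix(r, nrow = nrow(m))
  }
  lo_c <- col_txf(x, flt$h)
  hi_c <- col_txf(x, flt$g)
  LL <- row_txf(lo_c, flt$h)
  LH <- row_txf(lo_c, flt$g)
  HL <- row_txf(hi_c, flt$h)
  HH <- row_txf(hi_c, flt$g)
  structure(list(LL = LL, LH = LH, HL = HL, HH = HH, wavelet = wavelet,
                 meta = list(input_dim = c(m0, n0), padded = padded)),
            class = "subband_set")
}

#' Inverse of [dwt_level1()]
#'
#' @param sb a `subband_set`.
#' @return matrix of the original dimensions (padding, if any, is cropped).
#' @export
idwt_level1 <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  flt <- wavelet_filters(sb$wavelet)
  lo_c <- t(apply(cbind(sb$LL, sb$LH), 1, function(v) {
    half <- length(v) / 2
    idwt1d(v[1:half], v[(half + 1):(2 * half)], flt)
  }))
  hi_c <- t(apply(cbind(sb$HL, sb$HH), 1, function(v) {
    half <- length(v) / 2
    idwt1d(v[1:half], v[(half + 1):(2 * half)], flt)
  }))
  n <- ncol(lo_c)
  x <- sapply(seq_len(n), function(j)
    idwt1d(lo_c[, j], hi_c[, j], flt))
  x[seq_len(sb$meta$input_dim[1]), seq_len(sb$meta$input_dim[2]), drop = FALSE]
}

# Flatten the LL sub-band row-major (the pinned convention for all feature
# vectors).
ll_vector <- function(template, wavelet = "haar") {
  as.vector(t(dwt_level1(template, wavelet)$LL))
}

#' Fit a PCA model on training LL vectors
#'
#' The mean vector is subtracted from every sample and the eigenpairs of
#' the unnormalized scatter matrix `C = Xz' Xz` are computed (the scaling
#' carries no information: eigenvectors are scale-invariant and eigenvalues
#' are reported unnormalized). When the dimension d exceeds the sample
#' count N, the N x N Gram matrix `Xz Xz'` is diagonalized instead and its
#' eigenvectors mapped back through `Xz` and renormalized (the eigen-iris
#' identity), so the cost is O(N^2 d) rather than O(d^3). Eigenvector signs
#' are fixed by making each vector's largest-magnitude entry positive.
#'
#' @param X N x d numeric matrix (rows are samples), or a list of equal
#'   length vectors; N >= 2.
#' @param k retained components: a positive integer, or a fraction in
#'   (0, 1) giving the eigenvalue mass to retain (default 0.95). Always
#'   capped at N-1 and at the number of available eigenpairs.
#' @return `pca_model`: `mean` (length d), `eigenvalues` (non-increasing),
#'   `eigenvectors` (d x n_eig, orthonormal columns), `k`.
#' @export
pca_fit <- function(X, k = 0.95) {
  if (is.list(X) && !is.data.frame(X)) X <- do.call(rbind, X)
  stopifnot(is.matrix(X))
  N <- nrow(X); d <- ncol(X)
  if (N < 2L) stop("PCA fit needs at least 2 training vectors")
  xm <- colMeans(X)
  Xz <- sweep(X, 2, xm)
  if (d <= N) {
    C <- crossprod(Xz)                      # d x d scatter, no 1/N
    eg <- eigen(C, symmetric = TRUE)
    keep <- seq_len(d)
    ev <- eg$values[keep]
    vec <- eg$vectors[, keep, drop = FALSE]
  } else {
    G <- tcrossprod(Xz)                     # N x N Gram
    eg <- eigen(G, symmetric = TRUE)
    tol <- max(eg$values, 0) * 1e-12
    keep <- which(eg$values > tol)
    ev <- eg$values[keep]
    vec <- crossprod(Xz, eg$vectors[, keep, drop = FALSE])
    if (length(keep))
      vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")   # renormalize
  }
  ev[ev < 0 & ev > -1e-9] <- 0
  # deterministic sign: largest-|entry| positive
  if (ncol(vec) > 0) {
    for (j in seq_len(ncol(vec))) {
      i <- which.max(abs(vec[, j]))
      if (vec[i, j] < 0) vec[, j] <- -vec[, j]
    }
  }
  total <- sum(ev)
  k_eff <- if (total <= 0) {
    0L
  } else if (k < 1) {
    as.integer(which(cumsum(ev) >= k * total)[1])
  } else {
    as.integer(k)
  }
  k_eff <- min(k_eff, N - 1L, length(ev))
  structure(list(mean = xm, eigenvalues = ev, eigenvectors = vec,
                 k = max(k_eff, 0L)),
            class = "pca_model")
}

#' Project a vector onto the retained principal components
#'
#' `f = E_k' (v - mean)`: center on the training mean, then take the first
#' `k` eigenvector coordinates.
#'
#' @param model a `pca_model`.
#' @param v numeric vector of the training dimension.
#' @param k number of components (default: the model's `k`).
#' @return length-`k` feature vector.
#' @export
pca_project <- function(model, v, k = model$k) {
  stopifnot(inherits(model, "pca_model"))
  if (length(v) != length(model$mean))
    stop("shape error: vector length ", length(v),
         " does not match model dimension ", length(model$mean))
  k <- min(k, ncol(model$eigenvectors))
  if (k == 0L) return(numeric(0))
  drop(crossprod(model$eigenvectors[, seq_len(k), drop = FALSE],
                 v - model$mean))
}

#' Full feature extraction for one template
#'
#' One-level DWT, LL sub-band flattened row-major, PCA projection — the
#' composition that turns a normalized iris into its compact feature
#' vector.
#'
#' @param template a `polar_template` (radial_res x angular_res matrix).
#' @param model a fitted `pca_model`.
#' @param wavelet wavelet name (must match the one used in training).
#' @return length-k numeric feature vector.
#' @export
extract_features <- function(template, model, wavelet = "haar") {
  pca_project(model, ll_vector(template, wavelet))
}
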