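# Independent oracles used by the tests. These re-derive expected values by
# brute force or closed form and must stay independent of the package's own
# implementation paths.

# Brute-force circular Hough voter: for every integer center and radius,
# count the edge pixels whose rounded euclidean distance to the center
# equals the radius. O(h * w * n_radii * n_edge); keep inputs <= 64x64.
brute_hough <- function(mask, radii) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask != 0)
  ey <- (idx - 1L) %% h
  ex <- (idx - 1L) %/% h
  acc <- array(0L, c(h, w, length(radii)))
  for (ir in seq_along(radii)) {
    for (xc in 0:(w - 1)) {
      for (yc in 0:(h - 1)) {
        d <- round(sqrt((ey - yc)^2 + (ex - xc)^2))
        acc[yc + 1L, xc + 1L, ir] <- sum(d == radii[ir])
      }
    }
  }
  acc
}

# Rasterize the circle of radius r centered at 0-based (yc, xc) under the
# same membership rule the voter uses.
circle_mask <- function(h, w, yc, xc, r) {
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  m <- matrix(0L, h, w)
  m[round(sqrt((ys - yc)^2 + (xs - xc)^2)) == r] <- 1L
  m
}

# Explicit 2x2-block Haar oracle for a one-level 2-D decomposition of an
# even-dimension matrix: sums/differences of each 2x2 block, scaled by 1/2.
haar_block_oracle <- function(x) {
  m <- nrow(x) / 2; n <- ncol(x) / 2
  LL <- LH <- HL <- HH <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      a <- x[2 * i - 1, 2 * j - 1]; b <- x[2 * i - 1, 2 * j]
      c <- x[2 * i, 2 * j - 1];     d <- x[2 * i, 2 * j]
      LL[i, j] <- (a + b + c + d) / 2
      LH[i, j] <- (a - b + c - d) / 2   # column high-pass (angular detail)
      HL[i, j] <- (a + b - c - d) / 2   # row high-pass (radial detail)
      HH[i, j] <- (a - b - c + d) / 2
    }
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# Eigenvalues of a 3x3 symmetric matrix via its characteristic cubic,
# solved with polyroot (independent of eigen()).
eig3_charpoly <- function(C) {
  stopifnot(all(dim(C) == c(3, 3)))
  tr <- sum(diag(C))
  m2 <- sum(diag(C)^2)
  s2 <- (tr^2 - sum(C * C)) / 2          # sum of 2x2 principal minors
  dt <- det(C)
  # det(C - lambda I) = -lambda^3 + tr lambda^2 - s2 lambda + det
  roots <- polyroot(c(dt, -s2, tr, -1))
  sort(Re(roots), decreasing = TRUE)
}

# Render a clean, concentric synthetic eye for geometry tests.
clean_eye <- function(subject_id = 1L, noise_sigma = 0,
                      center = c(160, 140), pr = 25, ir = 70) {
  spec <- eye_spec(subject_id,
                   pupil = circle(center[1], center[2], pr),
                   iris = circle(center[1], center[2], ir),
                   noise_sigma = noise_sigma)
  render_eye(spec)
}
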