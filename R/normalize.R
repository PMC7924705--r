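# Rubber-sheet normalization: unwrap the iris annulus between the pupil and
# limbic circles to a fixed-size rectangular (r, theta) grid, so templates
# from different captures of one iris are directly comparable.

#' Unwrap a segmented iris to a polar template
#'
#' For column j, `theta_j = 2*pi*j/angular_res` (half-open grid,
#' j = 0 ... angular_res-1; theta = 0 on the positive x-axis, increasing
#' with the rotation that carries +x onto +y, i.e. downward in image
#' coordinates). For row i, `t_i = i/(radial_res-1)` runs inclusively from
#' the pupil boundary (row 0) to the limbic boundary (last row). The sample
#' point is the per-angle linear blend
#' `(1-t) * P(theta) + t * L(theta)` of the pupil-circle point `P` and
#' iris-circle point `L`, which handles non-concentric circles. Intensity
#' is bilinear-interpolated; samples falling outside the image are clamped
#' to the border and counted in `meta$clamped`.
#'
#' @param image numeric matrix, values 0--255.
#' @param seg a `segmentation_result` (or any list with `pupil` and `iris`
#'   [circle()]s, 0-based centers).
#' @param radial_res,angular_res template rows / columns.
#' @return `polar_template`: a radial_res x angular_res numeric matrix with
#'   attribute `meta` (source circles, resolutions, clamp counter).
#' @export
rubber_sheet <- function(image, seg, radial_res = 60L, angular_res = 300L) {
  stopifnot(is.matrix(image))
  p <- seg$pupil; l <- seg$iris
  stopifnot(inherits(p, "iris_circle"), inherits(l, "iris_circle"))
  nr <- as.integer(radial_res); na <- as.integer(angular_res)
  if (nr < 2L || na < 8L) stop("template resolution too small")
  theta <- 2 * pi * (0:(na - 1)) / na
  t_i <- (0:(nr - 1)) / (nr - 1)
  px <- p$xc + p$r * cos(theta); py <- p$yc + p$r * sin(theta)
  lx <- l$xc + l$r * cos(theta); ly <- l$yc + l$r * sin(theta)
  # nr x na sample grids
  sx <- outer(1 - t_i, px) + outer(t_i, lx)
  sy <- outer(1 - t_i, py) + outer(t_i, ly)
  bi <- bilinear_sample(image, sy, sx)
  vals <- matrix(bi$values, nr, na)
  structure(vals, class = c("polar_template", "matrix", "array"),
            meta = list(pupil = p, iris = l, radial_res = nr,
                        angular_res = na, clamped = bi$clamped))
}

# Bilinear interpolation at continuous 0-based (y, x); out-of-range samples
# are clamped to the border and counted.
bilinear_sample <- function(image, y, x) {
  h <- nrow(image); w <- ncol(image)
  y <- as.vector(y); x <- as.vector(x)
  clamped <- sum(y < 0 | y > h - 1 | x < 0 | x > w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x <- pmin(pmax(x, 0), w - 1)
  y0 <- pmin(floor(y), h - 2); x0 <- pmin(floor(x), w - 2)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  v <- (1 - fy) * (1 - fx) * image[i00] + (1 - fy) * fx * image[i01] +
    fy * (1 - fx) * image[i10] + fy * fx * image[i11]
  list(values = v, clamped = clamped)
}

#' Circularly shift a polar template along the angular axis
#'
#' A shift of `s` columns corresponds to an in-plane eye rotation of
#' `2*pi*s/angular_res`; column j of the result is column `(j - s) mod
#' angular_res` of the input.
#'
#' @param template a `polar_template` (or any matrix).
#' @param shift integer column shift; taken modulo `angular_res`, so a
#'   full-period shift is the identity.
#' @return shifted template, same shape and attributes.
#' @export
rotate_template <- function(template, shift) {
  na <- ncol(template)
  s <- ((shift %% na) + na) %% na
  if (s == 0) return(template)
  out <- template[, c((na - s + 1):na, 1:(na - s)), drop = FALSE]
  attributes(out) <- attributes(template)
  out
}
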