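# Pupil and limbic boundary localization: gradient edge map + circular
# Hough voting.
#
# The accumulator geometry is pinned so results are exactly reproducible:
# an edge pixel votes for integer center (yc, xc) at radius r iff the
# rounded euclidean distance between them equals r; peak ties are broken by
# smallest radius, then row-major center order. Coordinates are 0-based
# (row = y downward, col = x rightward).

#' Gradient edge map
#'
#' Smooths the image with a 3x3 box filter, takes centered finite
#' differences, and thresholds the combined gradient magnitude at a
#' quantile of its nonzero values. `vertical_weight` multiplies the
#' x-derivative — the detector of vertically oriented edges — so that, for
#' the limbic (iris--sclera) pass, horizontally aligned eyelid edges fall
#' below the threshold while the left/right arcs of the boundary survive.
#' The pupil pass uses weight 1.
#'
#' @param image numeric matrix (values 0--255), at least 16 x 16.
#' @param thresh_quantile fraction in (0, 1); quantile of the nonzero
#'   gradient magnitudes used as threshold.
#' @param vertical_weight multiplier (>= 1) on the x-derivative component.
#' @param thresh_value optional absolute magnitude threshold overriding the
#'   quantile (used by the segmentation retry).
#' @return list of class `edge_map`: `mask` (0/1 integer matrix),
#'   `magnitude` (numeric matrix), `threshold`, and the coordinate
#'   convention note.
#' @export
edge_map <- function(image, thresh_quantile = 0.97, vertical_weight = 1,
                     thresh_value = NULL) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("image too small for edge mapping (need >= 16x16)")
  sm <- box3(image)
  h <- nrow(sm); w <- ncol(sm)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  mag <- sqrt((vertical_weight * gx)^2 + gy^2)
  nz <- mag[mag > 0]
  thr <- if (!is.null(thresh_value)) thresh_value
         else if (length(nz) == 0L) Inf
         else stats::quantile(nz, thresh_quantile, names = FALSE)
  mask <- matrix(0L, h, w)
  mask[mag > thr] <- 1L
  structure(list(mask = mask, magnitude = mag, threshold = thr,
                 orientation = "gx = d/dx (columns), gy = d/dy (rows); 0-based (row=y, col=x)"),
            class = "edge_map")
}

# 3x3 box smoothing with edge replication
box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, 1:h, h), c(1, 1:w, w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + p[(1 + dy):(h + dy), (1 + dx):(w + dx)]
  acc / 9
}

#' Circular Hough transform
#'
#' Each edge pixel votes for every integer center at each radius in
#' `r_range`; the accumulator maximum gives the circle. Ties are broken by
#' smallest radius, then smallest row, then smallest column.
#'
#' @param edges an [edge_map()] (or a 0/1 matrix, taken as the mask).
#' @param r_range integer `c(lo, hi)` radius interval in pixels.
#' @param center_constraint optional list `(yc, xc, max_dist)`: only centers
#'   within `max_dist` pixels of `(yc, xc)` are eligible for the peak.
#' @param thin keep every `thin`-th edge pixel (1 = all; the voting set can
#'   be subsampled without losing the peak).
#' @return list of class `hough_result`: `circle` (peak [circle()],
#'   0-based center coordinates), `votes` (peak count), `accumulator`
#'   (h x w x n_radii integer array), `radii`.
#' @export
hough_circles <- function(edges, r_range, center_constraint = NULL, thin = 1L) {
  mask <- if (inherits(edges, "edge_map")) edges$mask else edges
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  radii <- as.integer(r_range[1]):as.integer(r_range[2])
  if (max(radii) >= max(h, w)) stop("radius range exceeds image size")
  idx <- which(mask != 0)
  if (length(idx) < 8L)
    stop("segmentation failure: fewer than 8 edge pixels")
  ey <- (idx - 1L) %% h          # 0-based row
  ex <- (idx - 1L) %/% h         # 0-based col
  if (thin > 1L) {
    keep <- seq(1L, length(ey), by = as.integer(thin))
    ey <- ey[keep]; ex <- ex[keep]
  }
  acc <- hough_accumulate_cpp(ey, ex, h, w, radii)
  search <- acc
  if (!is.null(center_constraint)) {
    cc <- center_constraint
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    far <- sqrt((ys - cc$yc)^2 + (xs - cc$xc)^2) > cc$max_dist
    search[rep(as.vector(far), length(radii))] <- -1L
  }
  peak <- max(search)
  if (peak <= 0L) stop("segmentation failure: no votes in the search region")
  cand <- which(search == peak)
  ir <- (cand - 1L) %/% (h * w)
  rem <- (cand - 1L) %% (h * w)
  yc <- rem %% h
  xc <- rem %/% h
  o <- order(ir, yc, xc)[1]      # smallest radius, then row-major
  structure(list(circle = circle(xc[o], yc[o], radii[ir[o] + 1L]),
                 votes = peak, accumulator = acc, radii = radii),
            class = "hough_result")
}

#' Segment the pupil and limbic boundaries of an eye image
#'
#' Two Hough passes: first the pupil (unweighted gradients, pupil radius
#' window), then the limbic boundary (x-derivative weighted by
#' `vertical_weight` to suppress horizontal eyelid edges, iris radius
#' window, center constrained within 15 px of the pupil center). If the
#' result violates pupil-inside-iris, one retry is made with the edge
#' magnitude threshold halved; an unresolvable geometry raises a
#' segmentation-failure error carrying both candidate circles.
#'
#' @param image numeric matrix, values 0--255.
#' @param hough list of Hough parameters (see [pipeline_config()]); a full
#'   `pipeline_config` is also accepted.
#' @return list of class `segmentation_result`: `pupil`, `iris`
#'   ([circle()]s, 0-based), `pupil_votes`, `iris_votes`, `retried`.
#' @export
segment_iris <- function(image, hough = pipeline_config()$hough) {
  if (inherits(hough, "pipeline_config")) hough <- hough$hough
  q <- hough$edge_thresh_quantile
  attempt <- function(pup_thr = NULL, iri_thr = NULL) {
    ep <- edge_map(image, q, vertical_weight = 1, thresh_value = pup_thr)
    pup <- hough_circles(ep, hough$pupil_r_range)
    ei <- edge_map(image, q, vertical_weight = hough$vertical_weight,
                   thresh_value = iri_thr)
    iri <- hough_circles(ei, hough$iris_r_range,
                         center_constraint = list(yc = pup$circle$yc,
                                                  xc = pup$circle$xc,
                                                  max_dist = 15))
    list(pup = pup, iri = iri,
         pthr = ep$threshold, ithr = ei$threshold)
  }
  a <- attempt()
  ok <- function(a) {
    dc <- sqrt((a$pup$circle$xc - a$iri$circle$xc)^2 +
                 (a$pup$circle$yc - a$iri$circle$yc)^2)
    dc + a$pup$circle$r < a$iri$circle$r
  }
  retried <- FALSE
  if (!ok(a)) {
    retried <- TRUE
    a2 <- tryCatch(attempt(a$pthr / 2, a$ithr / 2), error = function(e) NULL)
    if (!is.null(a2) && ok(a2)) {
      a <- a2
    } else {
      stop(sprintf(paste0("segmentation failure: pupil not inside iris after retry ",
                          "(pupil xc=%.0f yc=%.0f r=%.0f; iris xc=%.0f yc=%.0f r=%.0f)"),
                   a$pup$circle$xc, a$pup$circle$yc, a$pup$circle$r,
                   a$iri$circle$xc, a$iri$circle$yc, a$iri$circle$r))
    }
  }
  structure(list(pupil = a$pup$circle, iris = a$iri$circle,
                 pupil_votes = a$pup$votes, iris_votes = a$iri$votes,
                 retried = retried),
            class = "segmentation_result")
}
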