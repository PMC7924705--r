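# Synthetic eye-image generator with known ground-truth geometry.
#
# Every downstream stage (segmentation, normalization, feature extraction,
# matching) is exercised against images rendered here, for which the true
# pupil and limbic circles are known exactly.

#' Construct a circle (pixel coordinates)
#'
#' @param xc column coordinate of the center (0-based pixels).
#' @param yc row coordinate of the center (0-based pixels).
#' @param r radius in pixels, must be positive.
#' @return An object of class `iris_circle`.
#' @export
circle <- function(xc, yc, r) {
  stopifnot(is.numeric(xc), is.numeric(yc), is.numeric(r), length(r) == 1L)
  if (r <= 0) stop("circle radius must be positive")
  structure(list(xc = as.numeric(xc), yc = as.numeric(yc), r = as.numeric(r)),
            class = "iris_circle")
}

#' @export
print.iris_circle <- function(x, ...) {
  cat(sprintf("circle(xc = %.2f, yc = %.2f, r = %.2f)\n", x$xc, x$yc, x$r))
  invisible(x)
}

#' Specify a synthetic eye
#'
#' Defines the geometry, texture identity and degradation of one synthetic
#' eye image: a dark near-circular pupil inside a textured iris annulus
#' inside a bright sclera.
#'
#' @param subject_id integer identity label; drives the iris texture.
#' @param pupil,iris `iris_circle` objects (pixel units). The pupil must lie
#'   strictly inside the iris and the iris fully inside the image.
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param texture_seed integer; together with `subject_id` it determines the
#'   procedural iris texture.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise on
#'   the 0--255 intensity scale; must be non-negative.
#' @param occlusion_fraction fraction in \[0, 0.4\] of the iris vertical
#'   extent covered by bright horizontal bands at the top and bottom,
#'   mimicking eyelid occlusion.
#' @return An object of class `eye_spec`.
#' @export
eye_spec <- function(subject_id, pupil, iris,
                     image_size = c(280L, 320L),
                     texture_seed = 1L,
                     noise_sigma = 0,
                     occlusion_fraction = 0) {
  stopifnot(inherits(pupil, "iris_circle"), inherits(iris, "iris_circle"),
            length(image_size) == 2L)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (occlusion_fraction < 0 || occlusion_fraction > 0.4)
    stop("occlusion_fraction must lie in [0, 0.4]")
  dc <- sqrt((pupil$xc - iris$xc)^2 + (pupil$yc - iris$yc)^2)
  if (dc + pupil$r >= iris$r)
    stop("geometry error: pupil circle must lie strictly inside the iris circle")
  h <- image_size[1]; w <- image_size[2]
  if (iris$xc - iris$r < 0 || iris$xc + iris$r > w - 1 ||
      iris$yc - iris$r < 0 || iris$yc + iris$r > h - 1)
    stop("geometry error: iris circle must lie fully inside the image bounds")
  structure(list(subject_id = as.integer(subject_id), pupil = pupil, iris = iris,
                 image_size = as.integer(image_size),
                 texture_seed = as.integer(texture_seed),
                 noise_sigma = as.numeric(noise_sigma),
                 occlusion_fraction = as.numeric(occlusion_fraction)),
            class = "eye_spec")
}

# Deterministic per-subject texture parameters. A small local RNG stream is
# derived from (subject_id, texture_seed) without disturbing the caller's
# .Random.seed.
subject_texture_params <- function(subject_id, texture_seed, n_waves = 5L) {
  seed <- (as.numeric(texture_seed) * 1000003 + as.numeric(subject_id) * 7919) %%
    2147483647
  with_local_seed(as.integer(seed), {
    list(
      amp   = stats::runif(n_waves, 15, 35),
      m_ang = sample(3:16, n_waves, replace = TRUE),   # angular harmonic
      n_rad = sample(1:5, n_waves, replace = TRUE),    # radial half-waves
      ph_a  = stats::runif(n_waves, 0, 2 * pi),
      ph_r  = stats::runif(n_waves, 0, 2 * pi)
    )
  })
}

# Evaluate the band-limited procedural texture at normalized annulus
# position rho (0 at the pupil boundary, 1 at the limbus) and angle theta.
# Sum of radial/angular sinusoids; modulated radially so the pattern is not
# separable in theta alone.
texture_value <- function(rho, theta, par) {
  v <- 0
  for (j in seq_along(par$amp)) {
    v <- v + par$amp[j] *
      cos(par$m_ang[j] * theta + par$ph_a[j]) *
      cos(par$n_rad[j] * pi * rho + par$ph_r[j])
  }
  v
}

#' Render a synthetic eye image
#'
#' Produces an 8-bit grayscale matrix: bright sclera (~220), textured iris
#' annulus (procedural texture deterministic in `subject_id` and
#' `texture_seed`, evaluated in polar coordinates relative to the two
#' circles), dark pupil (~30). Gaussian noise of sd `noise_sigma` is added
#' and the result clipped to \[0, 255\] and rounded. If
#' `occlusion_fraction > 0`, bright horizontal bands cover that fraction of
#' the iris at top and bottom.
#'
#' Rendering is bit-reproducible: the same spec always yields the same
#' matrix (the noise stream is seeded from the spec fields).
#'
#' @param spec an [eye_spec()].
#' @return list of class `ground_truth` with elements `spec` and `image`
#'   (height x width integer matrix, values 0--255).
#' @export
render_eye <- function(spec) {
  stopifnot(inherits(spec, "eye_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  # pixel-center coordinates, 0-based: row y, col x
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)

  dpx <- xs - spec$pupil$xc; dpy <- ys - spec$pupil$yc
  dix <- xs - spec$iris$xc;  diy <- ys - spec$iris$yc
  rp <- sqrt(dpx^2 + dpy^2)       # distance to pupil center
  ri <- sqrt(dix^2 + diy^2)       # distance to iris center

  img <- matrix(220, h, w)                         # sclera
  in_pupil <- rp <= spec$pupil$r
  in_iris  <- ri <= spec$iris$r & !in_pupil

  if (any(in_iris)) {
    par <- subject_texture_params(spec$subject_id, spec$texture_seed)
    theta <- atan2(diy[in_iris], dix[in_iris])
    # normalized annulus position along the ray from the pupil boundary to
    # the limbus (matches the rubber-sheet parameterization)
    px <- spec$pupil$xc + spec$pupil$r * cos(theta)
    py <- spec$pupil$yc + spec$pupil$r * sin(theta)
    lx <- spec$iris$xc + spec$iris$r * cos(theta)
    ly <- spec$iris$yc + spec$iris$r * sin(theta)
    span <- sqrt((lx - px)^2 + (ly - py)^2)
    dist_p <- sqrt((xs[in_iris] - px)^2 + (ys[in_iris] - py)^2)
    rho <- pmin(pmax(dist_p / span, 0), 1)
    img[in_iris] <- 120 + texture_value(rho, theta, par)
  }
  img[in_pupil] <- 30

  if (spec$occlusion_fraction > 0) {
    band <- spec$occlusion_fraction / 2 * (2 * spec$iris$r)
    top_lim <- spec$iris$yc - spec$iris$r + band
    bot_lim <- spec$iris$yc + spec$iris$r - band
    occ <- (ys <= top_lim | ys >= bot_lim) & ri <= spec$iris$r
    img[occ] <- 205
  }

  if (spec$noise_sigma > 0) {
    nseed <- (as.numeric(spec$texture_seed) * 2654435 +
                as.numeric(spec$subject_id) * 40503 +
                round(spec$pupil$xc * 131 + spec$pupil$yc * 137 +
                        spec$iris$xc * 139 + spec$iris$yc * 149)) %% 2147483647
    noise <- with_local_seed(as.integer(nseed),
                             stats::rnorm(h * w, 0, spec$noise_sigma))
    img <- img + matrix(noise, h, w)
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  structure(list(spec = spec, image = img), class = "ground_truth")
}

#' Generate a reproducible multi-subject cohort
#'
#' Renders `images_per_subject` captures for each of `n_subjects` synthetic
#' subjects. Captures of one subject share the texture (identity) but differ
#' in noise realization and in a small (<= 3 px) center jitter, emulating
#' repeated acquisitions of the same eye.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param images_per_subject captures per subject.
#' @param master_seed integer; the whole cohort is a deterministic function
#'   of it.
#' @param image_size `c(height, width)` pixels.
#' @param noise_sigma per-capture Gaussian noise sd (0--255 scale).
#' @param occlusion_fraction eyelid-band occlusion fraction (see
#'   [eye_spec()]).
#' @param dir optional directory; when given, images are written as PNG and
#'   a `manifest.csv` with header `path,subject_id` is created there.
#' @return list with `truths` (list of `ground_truth`) and `manifest`
#'   (data.frame with columns `path`, `subject_id`; `path` is `NA` when no
#'   `dir` was given).
#' @export
make_cohort <- function(n_subjects, images_per_subject, master_seed,
                        image_size = c(280L, 320L), noise_sigma = 8,
                        occlusion_fraction = 0, dir = NULL) {
  if (n_subjects < 2) stop("make_cohort needs n_subjects >= 2")
  h <- image_size[1]; w <- image_size[2]
  draws <- with_local_seed(as.integer(master_seed %% 2147483647), {
    lapply(seq_len(n_subjects), function(s) {
      # per-subject nominal geometry
      pr <- stats::runif(1, 15, 35)
      ir <- stats::runif(1, max(55, pr + 22), 90)
      cx <- stats::runif(1, ir + 4, w - 1 - ir - 4)
      cy <- stats::runif(1, ir + 4, h - 1 - ir - 4)
      jit <- matrix(stats::runif(2 * images_per_subject, -3, 3),
                    ncol = 2)                       # capture center jitter
      poff <- matrix(sample(-1:1, 2 * images_per_subject, replace = TRUE),
                     ncol = 2)                      # pupil-center offset
      nsub <- sample.int(2^20, images_per_subject)  # noise stream ids
      list(pr = pr, ir = ir, cx = cx, cy = cy, jit = jit, poff = poff,
           nsub = nsub)
    })
  })
  truths <- list(); rows <- list(); k <- 0L
  for (s in seq_len(n_subjects)) {
    d <- draws[[s]]
    for (i in seq_len(images_per_subject)) {
      cx <- d$cx + d$jit[i, 1]; cy <- d$cy + d$jit[i, 2]
      # texture_seed depends only on the cohort, never on the capture index:
      # all captures of subject s share one texture
      sp <- eye_spec(
        subject_id = s,
        pupil = circle(cx + d$poff[i, 1], cy + d$poff[i, 2], d$pr),
        iris  = circle(cx, cy, d$ir),
        image_size = image_size,
        texture_seed = as.integer((master_seed %% 2^20) + 1L),
        noise_sigma = noise_sigma,
        occlusion_fraction = occlusion_fraction)
      gt <- render_eye_jittered(sp, noise_stream = d$nsub[i])
      k <- k + 1L
      truths[[k]] <- gt
      rows[[k]] <- data.frame(path = NA_character_, subject_id = s,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (k in seq_along(truths)) {
      p <- file.path(dir, sprintf("eye_s%03d_i%03d.png",
                                  manifest$subject_id[k],
                                  ((k - 1L) %% images_per_subject) + 1L))
      write_gray(truths[[k]]$image, p)
      manifest$path[k] <- p
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(truths = truths, manifest = manifest)
}

# Render with an explicit noise stream id so same-subject captures share the
# texture but differ in noise.
render_eye_jittered <- function(spec, noise_stream) {
  base <- spec; base$noise_sigma <- 0
  gt <- render_eye(base)
  img <- gt$image
  if (spec$noise_sigma > 0) {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    nseed <- (as.numeric(spec$texture_seed) * 48271 +
                as.numeric(noise_stream) * 16807) %% 2147483647
    noise <- with_local_seed(as.integer(nseed),
                             stats::rnorm(h * w, 0, spec$noise_sigma))
    img <- round(pmin(pmax(img + matrix(noise, h, w), 0), 255))
    storage.mode(img) <- "integer"
  }
  structure(list(spec = spec, image = img), class = "ground_truth")
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
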