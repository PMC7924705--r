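# Readers and writers: grayscale images (PNG/JPEG/PGM), dataset manifests,
# serialized templates / feature matrices / fitted models, and the pipeline
# configuration.

#' Read an image as an 8-bit grayscale matrix
#'
#' PNG and JPEG go through EBImage; PGM (both ASCII `P2` and binary `P5`)
#' is parsed directly. Color inputs are converted to luminance with the
#' ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param path image file (.png, .jpg/.jpeg, .pgm).
#' @return height x width numeric matrix with values in 0--255;
#'   `mat[row, col]` where row indexes y (top to bottom) and col indexes x.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- EBImage::imageData(img)      # dims (x, y[, channel]), values 0..1
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  t(a) * 255
}

#' Write a grayscale matrix as an image file
#'
#' @param mat height x width matrix, values 0--255.
#' @param path destination; format chosen by extension (.png or .pgm).
#' @return `path`, invisibly.
#' @export
write_gray <- function(mat, path) {
  stopifnot(is.matrix(mat))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(mat, path))
  png::writePNG(pmin(pmax(mat, 0), 255) / 255, path)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  toks <- character(0)
  # header: width height maxval, '#' comments allowed
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!nzchar(ch) || !grepl("[0-9]", ch)) break
        num <- paste0(num, ch)
      }
      toks <- c(toks, num)
    }
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); mx <- as.integer(toks[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]])
    if (length(vals) < w * h) stop("truncated PGM data: ", path)
    vals <- vals[seq_len(w * h)]
  }
  matrix(vals * (255 / mx), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(mat, path, ascii = TRUE) {
  m <- round(pmin(pmax(mat, 0), 255))
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
    writeBin(as.raw(as.vector(t(m))), con)
  }
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with header `path,subject_id` mapping image files to
#' integer subject identities. Paths must be unique.
#'
#' @param path CSV file.
#' @return data.frame with columns `path` (character) and `subject_id`
#'   (integer).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "subject_id") %in% names(df)))
    stop("manifest must have columns 'path' and 'subject_id': ", path)
  if (anyDuplicated(df$path)) stop("manifest paths are not unique: ", path)
  df$subject_id <- as.integer(df$subject_id)
  df[c("path", "subject_id")]
}

#' @rdname read_manifest
#' @param manifest data.frame with columns `path`, `subject_id`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "subject_id") %in% names(manifest)))
  utils::write.csv(manifest[c("path", "subject_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- array / model serialization --------------------------------------------
#
# Container format: a JSON header (shape, dtype, field names) followed by the
# data as little-endian float64, one file per object, extension .irt. Chosen
# for portability and exact round-tripping of doubles.

write_array_block <- function(con, a) {
  writeBin(as.numeric(a), con, size = 8L, endian = "little")
}

#' Save / load a template or numeric array
#'
#' `save_template()` writes any numeric vector/matrix/array (a polar
#' template, a feature matrix, ...) with a JSON header recording its shape
#' and named metadata; `load_template()` restores it exactly (float64
#' round-trip).
#'
#' @param x numeric array with finite values.
#' @param path destination file.
#' @param meta optional named list of scalar metadata stored in the header.
#' @return `load_template()` returns the array with a `meta` attribute.
#' @export
save_template <- function(x, path, meta = list()) {
  if (length(x) == 0L) stop("refusing to save an empty array")
  if (!all(is.finite(x))) stop("array contains non-finite values")
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  hdr <- jsonlite::toJSON(list(magic = "irispipe-array", version = 1L,
                               shape = as.integer(shape), meta = meta),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(hdr, "\n"), con, eos = NULL)
  write_array_block(con, x)
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr_chars <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!nzchar(ch)) stop("format error: missing header in ", path)
    if (ch == "\n") break
    hdr_chars <- c(hdr_chars, ch)
  }
  hdr <- tryCatch(jsonlite::fromJSON(paste(hdr_chars, collapse = "")),
                  error = function(e) stop("format error: bad header in ", path))
  if (!identical(hdr$magic, "irispipe-array"))
    stop("format error: not an irispipe array file: ", path)
  n <- prod(hdr$shape)
  vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(vals) != n) stop("format error: truncated data block in ", path)
  x <- if (length(hdr$shape) > 1L) array(vals, dim = hdr$shape) else vals
  attr(x, "meta") <- hdr$meta
  x
}

#' Save / load a fitted PCA model
#'
#' Serializes the mean vector, eigenvalues, eigenvector matrix and retained
#' component count; the round trip reproduces every component to float64
#' precision.
#'
#' @param model a `pca_model` from [pca_fit()].
#' @param path destination file.
#' @export
save_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  hdr <- jsonlite::toJSON(list(magic = "irispipe-pca", version = 1L,
                               d = length(model$mean),
                               n_eig = length(model$eigenvalues),
                               k = model$k),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(hdr, "\n"), con, eos = NULL)
  write_array_block(con, model$mean)
  write_array_block(con, model$eigenvalues)
  write_array_block(con, model$eigenvectors)
  invisible(path)
}

#' @rdname save_pca_model
#' @export
load_pca_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr_chars <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!nzchar(ch)) stop("format error: missing header in ", path)
    if (ch == "\n") break
    hdr_chars <- c(hdr_chars, ch)
  }
  hdr <- jsonlite::fromJSON(paste(hdr_chars, collapse = ""))
  if (!identical(hdr$magic, "irispipe-pca"))
    stop("format error: not a PCA model file: ", path)
  d <- hdr$d; ne <- hdr$n_eig
  mean <- readBin(con, "numeric", n = d, size = 8L, endian = "little")
  ev <- readBin(con, "numeric", n = ne, size = 8L, endian = "little")
  vec <- readBin(con, "numeric", n = d * ne, size = 8L, endian = "little")
  if (length(vec) != d * ne) stop("format error: truncated data block in ", path)
  structure(list(mean = mean, eigenvalues = ev,
                 eigenvectors = matrix(vec, d, ne), k = hdr$k),
            class = "pca_model")
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Defaults: a 60 x 300 normalized template (radial x angular resolution)
#' whose one-level wavelet decomposition gives 30 x 150 sub-bands; Haar
#' wavelet; PCA components retaining 95% of total eigenvalue mass; linear
#' SVM with soft-margin penalty 1. Hough search ranges default to the
#' synthetic-generator geometry and should be set to the expected pupil and
#' iris radii of the data at hand.
#'
#' @param radial_res template rows (samples from pupil to limbus), >= 2.
#' @param angular_res template columns (samples around 2*pi), >= 8.
#' @param wavelet `"haar"`, `"db2"` or `"db4"`.
#' @param pca_components positive integer count, or a fraction in (0, 1)
#'   interpreted as the eigenvalue mass to retain.
#' @param svm_c soft-margin penalty, > 0.
#' @param hough list: `pupil_r_range`, `iris_r_range` (integer px intervals,
#'   pupil max < iris min), `edge_thresh_quantile` (fraction),
#'   `vertical_weight` (>= 1, x-derivative multiplier for the limbic pass).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(radial_res = 60L, angular_res = 300L,
                            wavelet = "haar", pca_components = 0.95,
                            svm_c = 1.0,
                            hough = list()) {
  hdef <- list(pupil_r_range = c(15L, 35L), iris_r_range = c(55L, 90L),
               edge_thresh_quantile = 0.985, vertical_weight = 4)
  hdef[names(hough)] <- hough
  cfg <- list(radial_res = as.integer(radial_res),
              angular_res = as.integer(angular_res),
              wavelet = wavelet, pca_components = pca_components,
              svm_c = svm_c, hough = hdef)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$radial_res < 2L) stop("radial_res must be >= 2")
  if (cfg$angular_res < 8L) stop("angular_res must be >= 8")
  if (!cfg$wavelet %in% c("haar", "db2", "db4"))
    stop("unsupported wavelet: ", cfg$wavelet)
  if (cfg$svm_c <= 0) stop("svm_c must be positive")
  h <- cfg$hough
  if (length(h$pupil_r_range) != 2L || length(h$iris_r_range) != 2L ||
      h$pupil_r_range[1] > h$pupil_r_range[2] ||
      h$iris_r_range[1] > h$iris_r_range[2])
    stop("radius ranges must be non-empty [lo, hi] intervals")
  if (h$pupil_r_range[2] >= h$iris_r_range[1])
    stop("pupil radius maximum must be below iris radius minimum")
  if (h$edge_thresh_quantile <= 0 || h$edge_thresh_quantile >= 1)
    stop("edge_thresh_quantile must lie in (0, 1)")
  if (h$vertical_weight < 1) stop("vertical_weight must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' `read_config()` merges the file's entries over the package defaults, so a
#' partial YAML is valid; `write_config()` dumps the full configuration.
#' Parse-dump-parse is a fixed point.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  args <- y[intersect(names(y), c("radial_res", "angular_res", "wavelet",
                                  "pca_components", "svm_c", "hough"))]
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
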