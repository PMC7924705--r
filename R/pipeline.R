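# End-to-end pipeline: read eye images -> segment -> normalize -> DWT+PCA
# features -> train or evaluate the SVM matcher, with per-image status
# tracking, stage timings and seeded reproducibility.

#' Save / load a trained SVM matcher
#'
#' JSON serialization of the per-subject hyperplanes (full double
#' precision).
#'
#' @param model an `iris_svm`.
#' @param path destination file.
#' @export
save_svm_model <- function(model, path) {
  stopifnot(inherits(model, "iris_svm"))
  obj <- list(magic = "irispipe-svm", version = 1L,
              subjects = model$subjects, W = model$W, b = model$b,
              c = model$c, kernel = model$kernel,
              threshold = model$threshold)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_svm_model
#' @export
load_svm_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$magic, "irispipe-svm"))
    stop("format error: not an SVM model file: ", path)
  structure(list(subjects = as.integer(obj$subjects),
                 W = matrix(obj$W, ncol = length(obj$subjects)),
                 b = as.numeric(obj$b), c = obj$c, kernel = obj$kernel,
                 threshold = obj$threshold),
            class = "iris_svm")
}

# segment + normalize + LL vector for one image, with timing accumulation
process_image <- function(img, cfg, timings) {
  t0 <- proc.time()[["elapsed"]]
  seg <- segment_iris(img, cfg$hough)
  t1 <- proc.time()[["elapsed"]]
  tpl <- rubber_sheet(img, seg, cfg$radial_res, cfg$angular_res)
  t2 <- proc.time()[["elapsed"]]
  v <- ll_vector(tpl, cfg$wavelet)
  t3 <- proc.time()[["elapsed"]]
  timings$segment <- timings$segment + (t1 - t0)
  timings$normalize <- timings$normalize + (t2 - t1)
  timings$extract <- timings$extract + (t3 - t2)
  list(seg = seg, template = tpl, ll = v, timings = timings)
}

#' Run the full pipeline over a manifest
#'
#' In `enroll` mode every image is segmented, normalized and reduced to its
#' LL vector; a PCA model is fitted on the enrollment vectors, features are
#' projected, one SVM per subject is trained, and all models are written to
#' `model_dir`. In `test` mode the models are loaded, every test image is
#' reduced to its feature vector, and verification performance (accuracy,
#' FAR, FRR) is evaluated under the seeded claim protocol.
#'
#' Per-image failures (e.g. segmentation) are recorded and skipped; the run
#' aborts only if more than 20% of images fail.
#'
#' @param manifest data.frame with columns `path`, `subject_id`, or the
#'   path of a manifest CSV.
#' @param config a [pipeline_config()].
#' @param mode `"enroll"` or `"test"`.
#' @param model_dir directory for model artifacts (written in enroll mode,
#'   read in test mode).
#' @param seed integer driving the evaluation claim protocol.
#' @param threshold decision threshold used in test mode.
#' @return list of class `run_record`: `mode`, `config`, `timings`
#'   (seconds per stage), `status` (data.frame: path, subject_id, status,
#'   message), `outputs` (paths written), and in test mode `report` (an
#'   `eval_report`).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         mode = c("enroll", "test"),
                         model_dir, seed = 1L, threshold = 0) {
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  stopifnot(inherits(config, "pipeline_config"))
  n <- nrow(manifest)
  status <- data.frame(path = manifest$path,
                       subject_id = manifest$subject_id,
                       status = rep("ok", n), message = rep("", n),
                       stringsAsFactors = FALSE)
  timings <- list(segment = 0, normalize = 0, extract = 0, classify = 0)
  lls <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- read_gray(manifest$path[i])
      process_image(img, config, timings)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status$status[i] <- "segmentation-failure"
      status$message[i] <- conditionMessage(res)
    } else {
      lls[[i]] <- res$ll
      timings <- res$timings
    }
  }
  okay <- status$status == "ok"
  if (sum(!okay) > 0.2 * n)
    stop("pipeline failure: ", sum(!okay), " of ", n, " images failed")
  X <- do.call(rbind, lls[okay])
  ids <- manifest$subject_id[okay]
  outputs <- character(0)

  if (mode == "enroll") {
    pca <- pca_fit(X, k = config$pca_components)
    feats <- t(apply(X, 1, function(v) pca_project(pca, v)))
    if (pca$k == 1L) feats <- matrix(as.vector(feats), ncol = 1L)
    svm <- svm_train(feats, ids, c = config$svm_c)
    if (!dir.exists(model_dir)) dir.create(model_dir, recursive = TRUE)
    p1 <- file.path(model_dir, "pca.irt")
    p2 <- file.path(model_dir, "svm.json")
    p3 <- file.path(model_dir, "config.yaml")
    save_pca_model(pca, p1)
    save_svm_model(svm, p2)
    write_config(config, p3)
    outputs <- c(p1, p2, p3)
    report <- NULL
  } else {
    pca <- load_pca_model(file.path(model_dir, "pca.irt"))
    svm <- load_svm_model(file.path(model_dir, "svm.json"))
    feats <- t(apply(X, 1, function(v) pca_project(pca, v)))
    if (pca$k == 1L) feats <- matrix(as.vector(feats), ncol = 1L)
    report <- evaluate(svm, feats, ids, protocol_seed = seed,
                       threshold = threshold)
    timings$classify <- report$classification_time
  }
  structure(list(mode = mode, config = unclass(config), timings = timings,
                 status = status, outputs = outputs, report = report,
                 seed = as.integer(seed)),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  n_ok <- sum(x$status$status == "ok")
  cat(sprintf("irispipe run (%s): %d/%d images ok\n", x$mode, n_ok,
              nrow(x$status)))
  cat(sprintf("  timings (s): segment %.2f, normalize %.2f, extract %.2f, classify %.3f\n",
              x$timings$segment, x$timings$normalize, x$timings$extract,
              x$timings$classify))
  if (!is.null(x$report)) print(x$report)
  if (length(x$outputs)) cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Repeated-timing benchmark of the classification stage
#'
#' Runs the scoring stage of [evaluate()] `attempts` times over the same
#' feature set and reports each elapsed time with its mean and median.
#' Timings are informational only (hardware-dependent); nothing in the
#' package asserts on them.
#'
#' @param model an `iris_svm`.
#' @param features M x k test feature matrix.
#' @param true_ids length-M subject ids.
#' @param attempts repetitions (default 8).
#' @param protocol_seed claim-protocol seed.
#' @return list: `times` (seconds per attempt), `mean`, `median`.
#' @export
bench_classification <- function(model, features, true_ids, attempts = 8L,
                                 protocol_seed = 1L) {
  times <- vapply(seq_len(attempts), function(a) {
    evaluate(model, features, true_ids,
             protocol_seed = protocol_seed)$classification_time
  }, numeric(1))
  list(times = times, mean = mean(times), median = stats::median(times))
}
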