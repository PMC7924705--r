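# Verification: one linear soft-margin SVM per enrolled subject
# (one-vs-rest), accept/reject decisions on a claimed identity, and
# accuracy / FAR / FRR reporting.

#' Train per-subject verification SVMs
#'
#' Fits one linear soft-margin machine per enrolled subject against the
#' pooled features of all other subjects and stores each separating
#' hyperplane as an explicit `(w, b)` pair, oriented so that positive
#' scores `w . f + b` favor the subject. Training is deterministic given
#' the input order and penalty.
#'
#' @param features N x k numeric matrix of feature vectors (rows).
#' @param subject_ids length-N integer labels; at least 2 distinct
#'   subjects, each with at least one vector.
#' @param c soft-margin penalty (> 0).
#' @param tolerance optimizer termination tolerance; the tight default
#'   makes the recovered hyperplane reproducible to ~1e-6.
#' @return `iris_svm`: `subjects`, `W` (k x S matrix of weight vectors),
#'   `b` (length S), `c`, `kernel`, `threshold` (decision threshold on the
#'   signed score, default 0).
#' @export
svm_train <- function(features, subject_ids, c = 1.0, tolerance = 1e-6) {
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  stopifnot(is.matrix(features), nrow(features) == length(subject_ids))
  subjects <- sort(unique(as.integer(subject_ids)))
  if (length(subjects) < 2L)
    stop("training error: need at least 2 distinct subjects")
  if (c <= 0) stop("svm penalty c must be positive")
  k <- ncol(features)
  W <- matrix(0, k, length(subjects))
  b <- numeric(length(subjects))
  for (si in seq_along(subjects)) {
    y <- factor(ifelse(subject_ids == subjects[si], "pos", "neg"),
                levels = c("pos", "neg"))
    fit <- e1071::svm(features, y, type = "C-classification",
                      kernel = "linear", cost = c, scale = FALSE,
                      tolerance = tolerance)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b0 <- -fit$rho
    # orient so positive class scores higher
    sc <- features %*% w + b0
    if (mean(sc[y == "pos"]) < mean(sc[y == "neg"])) { w <- -w; b0 <- -b0 }
    W[, si] <- w; b[si] <- b0
  }
  structure(list(subjects = subjects, W = W, b = b, c = c,
                 kernel = "linear", threshold = 0),
            class = "iris_svm")
}

#' Score a feature vector against a claimed identity
#'
#' @param model an `iris_svm`.
#' @param f feature vector.
#' @param claimed_subject subject id to verify against; must be enrolled.
#' @param threshold decision threshold (default: the model's). The claim is
#'   accepted iff the signed score strictly exceeds it.
#' @return list of class `iris_decision`: `claimed_subject`, `accepted`,
#'   `score`.
#' @export
verify <- function(model, f, claimed_subject, threshold = model$threshold) {
  stopifnot(inherits(model, "iris_svm"))
  si <- match(as.integer(claimed_subject), model$subjects)
  if (is.na(si)) stop("lookup error: subject ", claimed_subject,
                      " is not enrolled")
  if (length(f) != nrow(model$W))
    stop("shape error: feature length ", length(f),
         " does not match model dimension ", nrow(model$W))
  score <- drop(crossprod(model$W[, si], f)) + model$b[si]
  structure(list(claimed_subject = as.integer(claimed_subject),
                 accepted = score > threshold, score = score),
            class = "iris_decision")
}

#' Verification metrics from confusion counts
#'
#' `FAR = IA / (IA + IR) * 100`, `FRR = GR / (GA + GR) * 100`,
#' `accuracy = (GA + IR) / (GA + GR + IA + IR) * 100`, where GA/GR are
#' genuine claims accepted/rejected and IA/IR impostor claims
#' accepted/rejected. With no impostor trials FAR is `NA`; with no genuine
#' trials FRR is `NA`.
#'
#' @param genuine_accept,genuine_reject,impostor_accept,impostor_reject
#'   trial counts.
#' @return list of class `eval_report` with `accuracy`, `far`, `frr`
#'   (percentages) and `counts`.
#' @export
metrics_from_counts <- function(genuine_accept, genuine_reject,
                                impostor_accept, impostor_reject) {
  ga <- genuine_accept; gr <- genuine_reject
  ia <- impostor_accept; ir <- impostor_reject
  total <- ga + gr + ia + ir
  if (total == 0) stop("no trials")
  far <- if (ia + ir > 0) ia / (ia + ir) * 100 else NA_real_
  frr <- if (ga + gr > 0) gr / (ga + gr) * 100 else NA_real_
  structure(list(accuracy = (ga + ir) / total * 100, far = far, frr = frr,
                 counts = list(genuine_accept = ga, genuine_reject = gr,
                               impostor_accept = ia, impostor_reject = ir)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  FAR %.2f%%  FRR %.2f%%\n",
              x$accuracy, x$far, x$frr))
  cat(sprintf("  genuine: %d accepted / %d rejected; impostor: %d accepted / %d rejected\n",
              x$counts$genuine_accept, x$counts$genuine_reject,
              x$counts$impostor_accept, x$counts$impostor_reject))
  invisible(x)
}

#' Evaluate verification performance on a test set
#'
#' Protocol: every test vector makes one genuine claim (its true identity)
#' and, when `impostor_trials > 0`, one impostor claim of a seeded wrong
#' identity. The wrong identity is drawn once per true subject from the
#' other enrolled subjects (seeded by `protocol_seed`), which makes the
#' report invariant to the order of the test vectors.
#'
#' @param model an `iris_svm`.
#' @param features M x k matrix of test feature vectors.
#' @param true_ids length-M true subject ids.
#' @param protocol_seed integer seed for the impostor-identity draw.
#' @param threshold decision threshold.
#' @param impostor_trials impostor claims per test vector (0 or 1).
#' @return `eval_report` (see [metrics_from_counts()]) with an additional
#'   `classification_time` field: elapsed seconds spent scoring.
#' @export
evaluate <- function(model, features, true_ids, protocol_seed = 1L,
                     threshold = model$threshold, impostor_trials = 1L) {
  stopifnot(inherits(model, "iris_svm"))
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  m <- nrow(features)
  if (m == 0L || length(true_ids) != m) stop("empty or mismatched test set")
  true_ids <- as.integer(true_ids)
  subj <- sort(unique(true_ids))
  wrong <- with_local_seed(as.integer(protocol_seed %% 2147483647), {
    vapply(subj, function(s) {
      pool <- setdiff(model$subjects, s)
      if (length(pool) == 0L) stop("cannot form impostor trials with one subject")
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
  })
  names(wrong) <- as.character(subj)
  ga <- gr <- ia <- ir <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(m)) {
    dg <- verify(model, features[i, ], true_ids[i], threshold)
    if (dg$accepted) ga <- ga + 1L else gr <- gr + 1L
    if (impostor_trials > 0L) {
      di <- verify(model, features[i, ], wrong[[as.character(true_ids[i])]],
                   threshold)
      if (di$accepted) ia <- ia + 1L else ir <- ir + 1L
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  rep <- metrics_from_counts(ga, gr, ia, ir)
  rep$classification_time <- elapsed
  rep
}
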