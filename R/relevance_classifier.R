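# Single-trial relevance classification: spatio-temporal window-mean
# features, regularized LDA with Ledoit-Wolf covariance shrinkage, a strict
# confidence gate, and the cross-task training-set assembly rule.

#' Extract spatio-temporal window-mean features from epochs
#'
#' Divides the post-stimulus interval (default 50-800 ms) into `n_windows`
#' equal-length half-open sub-intervals and takes the mean amplitude per
#' channel per sub-interval. Features are concatenated channel-major: all
#' windows of channel 1 first, then channel 2, and so on, giving
#' `n_channels * n_windows` features per epoch (224 for the default
#' 32-channel, 7-window configuration).
#'
#' @param epochs An `epoch_set`.
#' @param interval_ms Feature interval, half-open (default `c(50, 800)`).
#' @param n_windows Number of equidistant windows (default 7).
#' @return Numeric matrix, one row per epoch, with names
#'   `<channel>.w<window>`.
#' @export
extract_features <- function(epochs, interval_ms = c(50, 800), n_windows = 7) {
  stopifnot(inherits(epochs, "epoch_set"))
  times <- epochs$times
  if (interval_ms[1] < min(times) || interval_ms[2] > max(times) + 1000 / epochs$rate)
    stop("feature interval lies outside the epoch window", call. = FALSE)
  edges <- seq(interval_ms[1], interval_ms[2], length.out = n_windows + 1)
  win <- findInterval(times, edges, rightmost.closed = FALSE)
  win[times >= interval_ms[2]] <- 0L  # half-open right edge
  if (any(tabulate(win, n_windows) == 0))
    stop("a feature window contains no samples at this sampling rate",
         call. = FALSE)
  n_ep <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  out <- matrix(NA_real_, nrow = n_ep, ncol = nch * n_windows)
  for (w in seq_len(n_windows)) {
    idx <- which(win == w)
    m <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
    out[, (seq_len(nch) - 1L) * n_windows + w] <- m
  }
  colnames(out) <- as.vector(t(outer(epochs$channels,
                                     paste0("w", seq_len(n_windows)),
                                     paste, sep = ".")))
  out
}

#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Computes the analytically optimal convex combination of the empirical
#' covariance `S` (maximum-likelihood, 1/n convention) and the scaled
#' identity target `nu * I` with `nu = trace(S) / d`:
#' `Sigma = (1 - lambda) * S + lambda * nu * I`, with the shrinkage
#' intensity `lambda` estimated from the data and clipped to `[0, 1]`. The
#' estimate is positive-definite whenever the data are not identically
#' constant, which makes linear discriminants computable even when features
#' outnumber samples.
#'
#' @param x Numeric matrix, samples in rows (at least 2).
#' @param center Subtract column means first (default `TRUE`); pass `FALSE`
#'   for pre-centred residuals.
#' @return List with `sigma` (d x d shrunk covariance), `lambda` and `nu`.
#' @export
ledoit_wolf <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (center) x <- sweep(x, 2, colMeans(x))
  s <- crossprod(x) / n
  nu <- sum(diag(s)) / d
  # squared deviations use the dimension-normalised Frobenius norm
  d2 <- sum((s - diag(nu, d))^2) / d
  if (d2 <= .Machine$double.eps * nu^2) {
    lambda <- 0
  } else {
    sq_norms <- rowSums(x^2)
    b2bar <- (sum(sq_norms^2) / n^2 - sum(s^2) / n) / d
    lambda <- min(b2bar, d2) / d2
    lambda <- min(max(lambda, 0), 1)
  }
  sigma <- (1 - lambda) * s + diag(lambda * nu, d)
  dimnames(sigma) <- list(colnames(x), colnames(x))
  list(sigma = sigma, lambda = lambda, nu = nu)
}

#' Train the regularized LDA relevance classifier
#'
#' Fits `f: S -> Y` on feature vectors with binary relevance labels: class
#' means, pooled within-class covariance shrunk by [ledoit_wolf()], weights
#' `w = Sigma^-1 (mu1 - mu0)` and a bias placing the decision score on a
#' log-posterior-odds scale with empirical class priors. The confidence
#' score reported at prediction time is the logistic transform of that
#' score, i.e. a two-class posterior probability for the relevant class; a
#' prediction is positive only when it strictly exceeds `threshold`.
#'
#' @param x Feature matrix (epochs x features).
#' @param y Binary labels, 1 = relevant/target, 0 = irrelevant.
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`, overriding
#'   the Ledoit-Wolf estimate.
#' @param threshold Confidence gate (default 0.7, strict).
#' @param tasks_used Optional character vector recorded as training
#'   metadata.
#' @return A `relevance_model`.
#' @export
train_relevance <- function(x, y, lambda = NULL, threshold = 0.7,
                            tasks_used = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("one label per feature row required", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0 || n1 == 0)
    stop("both classes must be present in the training data", call. = FALSE)
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  resid <- x - rbind(mu0, mu1)[y + 1L, , drop = FALSE]
  lw <- ledoit_wolf(resid, center = FALSE)
  if (!is.null(lambda)) {
    if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
    s <- crossprod(resid) / nrow(resid)
    lw$sigma <- (1 - lambda) * s + diag(lambda * lw$nu, ncol(s))
    lw$lambda <- lambda
  }
  w <- tryCatch(solve(lw$sigma, mu1 - mu0),
                error = function(e) stop(
                  "shrunk covariance is singular (degenerate input)",
                  call. = FALSE))
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  structure(list(w = as.numeric(w), b = b, mu0 = as.numeric(mu0),
                 mu1 = as.numeric(mu1), sigma = lw$sigma,
                 lambda = lw$lambda, nu = lw$nu, threshold = threshold,
                 d = ncol(x), priors = c(irrelevant = n0, relevant = n1) /
                   (n0 + n1),
                 feature_names = colnames(x),
                 tasks_used = tasks_used),
            class = "relevance_model")
}

#' @export
print.relevance_model <- function(x, ...) {
  cat(sprintf("<relevance_model> d = %d, lambda = %.4f, threshold = %g\n",
              x$d, x$lambda, x$threshold))
  invisible(x)
}

#' Predict relevance labels with a confidence gate
#'
#' Computes the linear discriminant score and its logistic confidence for
#' the relevant class; an epoch is labelled relevant (`label = 1`) only
#' when the confidence strictly exceeds the model's threshold.
#'
#' @param object A `relevance_model`.
#' @param newdata Feature matrix (epochs x features) or single feature
#'   vector.
#' @param ... Unused.
#' @return Data frame with `score`, `confidence` and `label` per epoch.
#' @export
predict.relevance_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(x) != object$d)
    stop("feature dimension does not match the model", call. = FALSE)
  score <- drop(x %*% object$w) + object$b
  confidence <- stats::plogis(score)
  data.frame(score = score, confidence = confidence,
             label = as.integer(confidence > object$threshold))
}

#' Assemble the cross-task training set for a target task
#'
#' Pools each task's epochs labelled by that task's own a-priori relevance,
#' excluding the target task's reverse task entirely (its stimuli are the
#' target task's test stimuli) and excluding the target task's own held-out
#' test portion (the last `1 - train_fraction` of its epochs in
#' presentation order).
#'
#' @param features_by_task Named list of per-task feature matrices, rows in
#'   presentation order.
#' @param labels_by_task Named list of per-task 0/1 label vectors (1 =
#'   relevant under that task's own category).
#' @param target_task Name of the task whose classifier is being trained.
#' @param reverse Named character vector mapping each task to its reverse
#'   task (see [reverse_pairs()]).
#' @param train_fraction Ordered split fraction for the target task's own
#'   data (default 0.8).
#' @param include_target_train Include the target task's training portion
#'   (default `TRUE`).
#' @return List with `x` (pooled features), `y` (pooled labels) and
#'   `tasks_used`.
#' @export
assemble_training_set <- function(features_by_task, labels_by_task,
                                  target_task, reverse,
                                  train_fraction = 0.8,
                                  include_target_train = TRUE) {
  tasks <- names(features_by_task)
  if (!target_task %in% tasks) stop("unknown target task", call. = FALSE)
  excluded <- unname(reverse[[target_task]])
  use <- setdiff(tasks, c(excluded, target_task))
  xs <- list(); ys <- list()
  for (task in use) {
    xs[[task]] <- features_by_task[[task]]
    ys[[task]] <- labels_by_task[[task]]
  }
  if (include_target_train) {
    xt <- features_by_task[[target_task]]
    k <- floor(nrow(xt) * train_fraction)
    if (k > 0) {
      xs[[target_task]] <- xt[seq_len(k), , drop = FALSE]
      ys[[target_task]] <- labels_by_task[[target_task]][seq_len(k)]
      use <- c(use, target_task)
    }
  }
  if (!length(xs)) stop("empty training pool", call. = FALSE)
  x <- do.call(rbind, xs)
  y <- unlist(ys, use.names = FALSE)
  if (length(unique(y)) < 2)
    stop("training pool does not contain both classes", call. = FALSE)
  list(x = x, y = y, tasks_used = use)
}

#' Serialize a relevance model to JSON
#'
#' Full-precision JSON document (means, covariance, shrinkage intensity,
#' threshold, metadata) that round-trips exactly through [read_model()].
#'
#' @param model A `relevance_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "relevance_model"))
  doc <- unclass(model)
  doc$sigma <- as.numeric(doc$sigma)  # stored flat, column-major
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a relevance model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `relevance_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$sigma <- matrix(doc$sigma, nrow = doc$d, ncol = doc$d,
                      dimnames = list(doc$feature_names, doc$feature_names))
  doc$priors <- stats::setNames(as.numeric(doc$priors),
                                c("irrelevant", "relevant"))
  structure(doc[c("w", "b", "mu0", "mu1", "sigma", "lambda", "nu",
                  "threshold", "d", "priors", "feature_names",
                  "tasks_used")],
            class = "relevance_model")
}
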