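# The intention model h: Z, Y -> Z — the mean of positively-labelled latent
# vectors (a special case of the Rocchio relevance-feedback update) — plus
# the positive/negative/random feedback modes and checkpointed trajectories.

#' Update the intention estimate from labelled latent vectors
#'
#' Computes `h(Z, y) = sum(y_i * z_i) / sum(y_i)`: the unweighted arithmetic
#' mean of the latent vectors whose epochs were classified relevant. The
#' estimate always lies in the convex hull of the positively labelled
#' vectors and is invariant to any joint permutation of rows and labels.
#'
#' @param z Latent matrix (`latent_batch` or plain matrix), one vector per
#'   presented stimulus.
#' @param y Binary 0/1 vector, one label per row of `z`.
#' @return Numeric vector: the updated intention estimate.
#' @section Degenerate input: when no label is positive the update is
#'   undefined; an error of class `"no_positive_feedback"` is signalled and
#'   the caller decides the fallback (study runners record an undefined
#'   marker).
#' @export
update_intention <- function(z, y) {
  z <- as.matrix(z)
  y <- as.integer(y)
  if (length(y) != nrow(z))
    stop("`y` must have one label per latent vector", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  k <- sum(y)
  if (k == 0)
    stop(errorCondition("no positively labelled latent vectors: intention update undefined",
                        class = c("no_positive_feedback", "error", "condition")))
  colSums(z[y == 1L, , drop = FALSE]) / k
}

#' Derive feedback labels for the three generative feedback models
#'
#' - `positive`: the classifier's predictions as-is (latent vectors of
#'   epochs classified relevant drive the update);
#' - `negative`: the complement (only vectors classified irrelevant);
#' - `random`: a uniformly random permutation of the positive-mode labels,
#'   so exactly the same amount of feedback is given as in the positive
#'   model but detached from the stimuli.
#'
#' @param labels Binary 0/1 predictions in presentation order, or a
#'   prediction data frame from [predict.relevance_model()].
#' @param mode One of `"positive"`, `"negative"`, `"random"`.
#' @param seed Optional integer seed for the random mode.
#' @return Binary 0/1 vector of feedback labels.
#' @export
apply_feedback_mode <- function(labels, mode = c("positive", "negative", "random"),
                                seed = NULL) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.integer(labels)
  if (!length(labels)) stop("`labels` must be non-empty", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  mode <- match.arg(mode)
  switch(mode,
         positive = labels,
         negative = 1L - labels,
         random = if (is.null(seed)) sample(labels) else
           with_seed(seed, sample(labels)))
}

#' Checkpointed intention-estimate trajectory
#'
#' Recomputes the intention estimate from the first `n` presentations only,
#' for each checkpoint `n`, mimicking online execution in which feedback
#' arrives in presentation order. Checkpoints whose prefix contains no
#' positive label are emitted as undefined markers (`NA` rows), not errors.
#'
#' @param z Latent matrix, rows in presentation order.
#' @param y Binary 0/1 labels, same order.
#' @param checkpoints Increasing integer vector of prefix lengths, each at
#'   most `nrow(z)`.
#' @return An `intention_trajectory`: list with `n` (checkpoints), `zhat`
#'   (checkpoints x m matrix, `NA` rows where undefined), `defined` and
#'   `n_positive` per checkpoint.
#' @export
trajectory <- function(z, y, checkpoints) {
  z <- as.matrix(z)
  y <- as.integer(y)
  if (length(y) != nrow(z)) stop("`y` must match rows of `z`", call. = FALSE)
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("`checkpoints` must be strictly increasing", call. = FALSE)
  if (any(checkpoints < 1L) || any(checkpoints > nrow(z)))
    stop("checkpoints must lie in 1..nrow(z)", call. = FALSE)
  zhat <- matrix(NA_real_, nrow = length(checkpoints), ncol = ncol(z))
  npos <- integer(length(checkpoints))
  for (i in seq_along(checkpoints)) {
    n <- checkpoints[i]
    npos[i] <- sum(y[seq_len(n)])
    if (npos[i] > 0)
      zhat[i, ] <- update_intention(z[seq_len(n), , drop = FALSE],
                                    y[seq_len(n)])
  }
  structure(list(n = checkpoints, zhat = zhat, defined = npos > 0,
                 n_positive = npos),
            class = "intention_trajectory")
}

#' @export
print.intention_trajectory <- function(x, ...) {
  cat(sprintf("<intention_trajectory> %d checkpoints (n = %s), m = %d\n",
              length(x$n), paste(x$n, collapse = ", "), ncol(x$zhat)))
  invisible(x)
}

#' Write a trajectory as tab-separated text
#'
#' One row per checkpoint: `n`, `n_positive`, then the latent coordinates
#' (`NA` where the estimate is undefined).
#'
#' @param traj An `intention_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "intention_trajectory"))
  df <- data.frame(n = traj$n, n_positive = traj$n_positive, traj$zhat)
  names(df)[-(1:2)] <- paste0("z", seq_len(ncol(traj$zhat)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
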