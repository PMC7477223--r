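# Classifier evaluation (ROC AUC, label-permutation test), the
# grand-average ERP difference analysis, and the simulation study comparing
# the positive / random / negative feedback models end to end.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(score+ > score-) + 0.5 * P(tie)`, computed from midranks, equal to the
#' normalised Mann-Whitney U statistic.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary 0/1 labels (1 = positive class); both classes must
#'   be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Label-permutation significance test for a trained classifier
#'
#' Re-runs the full train-and-score pipeline `k` times with the training
#' labels randomly permuted while the ordered test split is held fixed, and
#' compares the observed test AUC with the permutation distribution. The
#' p-value convention is `max(#{permuted AUC >= observed}, 1) / k`, so the
#' minimum attainable p at `k = 100` is exactly 0.01.
#'
#' @param train_x,train_y Training features and 0/1 labels.
#' @param test_x,test_y Held-out test features and labels (fixed across
#'   permutations).
#' @param k Number of permutations (default 100).
#' @param trainer Function `(x, y) -> model` (default [train_relevance()]).
#' @param scorer Function `(model, x) -> scores` (default the LDA decision
#'   score).
#' @param seed Optional integer seed for the permutations.
#' @return A `permutation_result`: list with `observed`, `permuted`
#'   (length-`k` vector) and `p_value`.
#' @export
permutation_test <- function(train_x, train_y, test_x, test_y, k = 100,
                             trainer = train_relevance,
                             scorer = function(model, x) predict(model, x)$score,
                             seed = NULL) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  train_y <- as.integer(train_y); test_y <- as.integer(test_y)
  if (length(unique(train_y)) < 2 || length(unique(test_y)) < 2)
    stop("both classes must be present in train and test labels", call. = FALSE)
  if (!is.null(seed)) return(with_seed(seed, permutation_test(
    train_x, train_y, test_x, test_y, k, trainer, scorer, seed = NULL)))
  observed <- auc(scorer(trainer(train_x, train_y), test_x), test_y)
  permuted <- vapply(seq_len(k), function(i) {
    py <- sample(train_y)
    auc(scorer(trainer(train_x, py), test_x), test_y)
  }, numeric(1))
  p <- max(sum(permuted >= observed), 1) / k
  structure(list(observed = observed, permuted = permuted, p_value = p,
                 k = k),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed AUC = %.3f, k = %d, p = %.4g\n",
              x$observed, x$k, x$p_value))
  invisible(x)
}

#' Grand-average relevant-minus-irrelevant difference wave
#'
#' For one channel, the pointwise mean difference between retained relevant
#' and irrelevant epochs with its standard error, and the positive peak
#' within a search window (default 250-600 ms, the classic late-positivity
#' interval).
#'
#' @param epochs An `epoch_set` whose events carry a `relevance` column.
#' @param channel Channel label (default `"Pz"` if present, else the first
#'   channel).
#' @param search_window_ms Peak search window (default `c(250, 600)`).
#' @return A `difference_wave`: list with `channel`, `times`, `mean`, `se`,
#'   `peak_latency_ms`, `peak_amplitude`, `peak_se` and the class counts.
#' @export
grand_average_difference <- function(epochs, channel = NULL,
                                     search_window_ms = c(250, 600)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(channel))
    channel <- if ("Pz" %in% epochs$channels) "Pz" else epochs$channels[1]
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  keep <- epochs$retained
  rel <- keep & epochs$events$relevance == "relevant"
  irr <- keep & epochs$events$relevance == "irrelevant"
  if (!any(rel) || !any(irr))
    stop("both relevance classes must be present among retained epochs",
         call. = FALSE)
  xr <- epochs$data[rel, ch, , drop = FALSE]
  xi <- epochs$data[irr, ch, , drop = FALSE]
  dim(xr) <- c(sum(rel), dim(epochs$data)[3])
  dim(xi) <- c(sum(irr), dim(epochs$data)[3])
  mr <- colMeans(xr); mi <- colMeans(xi)
  se <- sqrt(apply(xr, 2, stats::var) / nrow(xr) +
               apply(xi, 2, stats::var) / nrow(xi))
  dif <- mr - mi
  win <- which(epochs$times >= search_window_ms[1] &
                 epochs$times <= search_window_ms[2])
  if (!length(win)) stop("empty peak search window", call. = FALSE)
  pk <- win[which.max(dif[win])]
  structure(list(channel = channel, times = epochs$times, mean = dif,
                 se = se, peak_latency_ms = epochs$times[pk],
                 peak_amplitude = dif[pk], peak_se = se[pk],
                 n_relevant = nrow(xr), n_irrelevant = nrow(xi),
                 search_window_ms = search_window_ms),
            class = "difference_wave")
}

#' @export
print.difference_wave <- function(x, ...) {
  cat(sprintf(paste0("<difference_wave> %s: peak %.2f uV (SE %.2f) at %g ms ",
                     "(%d relevant / %d irrelevant epochs)\n"),
              x$channel, x$peak_amplitude, x$peak_se, x$peak_latency_ms,
              x$n_relevant, x$n_irrelevant))
  invisible(x)
}

#' Write a difference wave as CSV
#'
#' Columns `time_ms`, `mean_uv`, `se_uv`.
#'
#' @param wave A `difference_wave`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_difference_wave <- function(wave, path) {
  stopifnot(inherits(wave, "difference_wave"))
  utils::write.csv(data.frame(time_ms = wave$times, mean_uv = wave$mean,
                              se_uv = wave$se),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study configuration with scaled-down defaults
#'
#' Bundles every knob of the simulated closed-loop study. The defaults are
#' deliberately desk-scale (4 tasks forming two reverse pairs, 16 channels
#' at 250 Hz, an 8-dimensional latent space) so that a full participant
#' runs in about two seconds while the classifier stays in the realistic
#' operating regime (held-out AUC around 0.75, a handful of confident
#' positive predictions per task); the acquisition-scale values (8 tasks,
#' 32 channels at 1000 Hz, m = 512) are reached by overriding `pairs`, `m`
#' and `sim`.
#'
#' @param n_participants Simulated participants (default 1).
#' @param m Latent dimensionality (default 8).
#' @param pairs Task pairs as `"task|reverse"` (default two pairs,
#'   male/female and young/old).
#' @param n_latents Size of the latent stimulus library (default 400).
#' @param blocks_per_task,trials_per_block,n_rel,n_irr Session structure
#'   (defaults 1, 6, 20, 50; the acquisition design uses 4 trials per
#'   block, the scaled default uses 6 to keep the per-task training pool
#'   in the paradigm's operating regime).
#' @param sim A [sim_config()]; default 16 channels at 250 Hz with the
#'   standard effect morphology.
#' @param train_fraction Ordered split fraction (default 0.8).
#' @param reject_fraction Artifact rejection fraction (default 0.11).
#' @param decimation Decimation factor (default 4).
#' @param feature_interval_ms,n_windows Feature extraction settings
#'   (defaults `c(50, 800)` and 7).
#' @param confidence_threshold Positive-prediction gate (default 0.7).
#' @param perm_k Permutations per task for the significance test (default
#'   0 = skip; the acquisition-scale value is 100).
#' @param checkpoints Trajectory checkpoints over the test prefix (default
#'   `c(5, 10, 25, 50)`, truncated to the test size at run time).
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 1, m = 8,
                         pairs = c("male|female", "young|old"),
                         n_latents = 400, blocks_per_task = 1,
                         trials_per_block = 6, n_rel = 20, n_irr = 50,
                         sim = sim_config(n_channels = 16, rate = 250),
                         train_fraction = 0.8, reject_fraction = 0.11,
                         decimation = 4,
                         feature_interval_ms = c(50, 800), n_windows = 7,
                         confidence_threshold = 0.7, perm_k = 0,
                         checkpoints = c(5, 10, 25, 50)) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(n_participants = n_participants, m = m, pairs = pairs,
                 n_latents = n_latents, blocks_per_task = blocks_per_task,
                 trials_per_block = trials_per_block, n_rel = n_rel,
                 n_irr = n_irr, sim = sim, train_fraction = train_fraction,
                 reject_fraction = reject_fraction, decimation = decimation,
                 feature_interval_ms = feature_interval_ms,
                 n_windows = n_windows,
                 confidence_threshold = confidence_threshold,
                 perm_k = perm_k, checkpoints = checkpoints),
            class = "study_config")
}

#' Run the simulated closed-loop study
#'
#' For every simulated participant and task: simulate the RSVP session and
#' recording, preprocess, split the task's epochs 80/20 in presentation
#' order, assemble the cross-task training set, train the shrinkage-LDA
#' classifier, (optionally) permutation-test it, classify the held-out test
#' epochs, derive positive / negative / random feedback labels, update the
#' intention estimate per mode, and measure the cosine similarity of each
#' final estimate to the task's true category direction.
#'
#' @param config A [study_config()].
#' @param seed Master seed; the entire study is reproducible bit-for-bit
#'   given the same seed and configuration.
#' @return A `study_report`: list with `report` (one row per participant x
#'   task: AUC, permutation p, positive-prediction count, per-mode cosine
#'   similarities), `trajectories` (positive-mode similarity per checkpoint)
#'   and the `config`.
#' @export
run_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  tasks <- default_tasks(config$m, config$pairs)
  rev_map <- reverse_pairs(tasks)
  rows <- list()
  traj_rows <- list()
  for (p in seq_len(config$n_participants)) {
    latents <- sample_latents(config$n_latents, config$m)
    plan <- build_session(tasks, latents,
                          blocks_per_task = config$blocks_per_task,
                          trials_per_block = config$trials_per_block,
                          n_rel = config$n_rel, n_irr = config$n_irr,
                          period_ms = 500)
    rec <- simulate_recording(plan, config$sim)
    ep <- preprocess(rec, reject_fraction = config$reject_fraction,
                     decimation = config$decimation)
    ep <- retained_epochs(ep)
    feats <- extract_features(ep, config$feature_interval_ms,
                              config$n_windows)
    task_idx <- split(seq_len(nrow(ep$events)), ep$events$task)
    features_by_task <- lapply(task_idx, function(i) feats[i, , drop = FALSE])
    labels_by_task <- lapply(task_idx, function(i)
      as.integer(ep$events$relevance[i] == "relevant"))
    for (task in names(tasks)) {
      own_idx <- task_idx[[task]]
      n_own <- length(own_idx)
      k_train <- floor(n_own * config$train_fraction)
      test_local <- (k_train + 1):n_own
      pool <- assemble_training_set(features_by_task, labels_by_task, task,
                                    rev_map, config$train_fraction)
      model <- train_relevance(pool$x, pool$y,
                               threshold = config$confidence_threshold,
                               tasks_used = pool$tasks_used)
      test_x <- features_by_task[[task]][test_local, , drop = FALSE]
      test_y <- labels_by_task[[task]][test_local]
      pred <- predict(model, test_x)
      # a degenerate single-class test split (possible at toy scale) yields
      # an undefined AUC rather than an error
      auc_obs <- if (length(unique(test_y)) < 2) NA_real_ else
        auc(pred$score, test_y)
      p_value <- NA_real_
      if (config$perm_k > 0 && length(unique(test_y)) >= 2) {
        pr <- permutation_test(pool$x, pool$y, test_x, test_y,
                               k = config$perm_k,
                               trainer = function(x, y) train_relevance(
                                 x, y, threshold = config$confidence_threshold))
        p_value <- pr$p_value
      }
      z_test <- unclass(latents)[ep$events$latent_id[own_idx][test_local], ,
                                 drop = FALSE]
      dvec <- tasks[[task]]$d
      sims <- c(positive = NA_real_, random = NA_real_, negative = NA_real_)
      y_modes <- list(
        positive = apply_feedback_mode(pred$label, "positive"),
        random = apply_feedback_mode(pred$label, "random"),
        negative = apply_feedback_mode(pred$label, "negative"))
      for (mode in names(y_modes)) {
        zhat <- tryCatch(update_intention(z_test, y_modes[[mode]]),
                         no_positive_feedback = function(e) NULL)
        if (!is.null(zhat)) sims[[mode]] <- cosine_similarity(zhat, dvec)
      }
      cps <- config$checkpoints[config$checkpoints <= length(test_local)]
      if (length(cps) == 0 || max(cps) < length(test_local))
        cps <- c(cps, length(test_local))
      tr <- trajectory(z_test, y_modes$positive, cps)
      sim_traj <- vapply(seq_along(tr$n), function(i)
        if (tr$defined[i]) cosine_similarity(tr$zhat[i, ], dvec) else NA_real_,
        numeric(1))
      traj_rows[[length(traj_rows) + 1L]] <-
        data.frame(participant = p, task = task, n = tr$n,
                   n_positive = tr$n_positive, similarity = sim_traj)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, task = task,
        n_train = length(pool$y), n_test = length(test_y),
        n_positive_pred = sum(pred$label), lambda = model$lambda,
        auc = auc_obs, p_value = p_value,
        sim_positive = sims[["positive"]],
        sim_random = sims[["random"]],
        sim_negative = sims[["negative"]])
    }
  }
  structure(list(report = do.call(rbind, rows),
                 trajectories = do.call(rbind, traj_rows),
                 config = config, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d participant-task cells (seed %d)\n",
              nrow(x$report), x$seed))
  print(x$report, digits = 3)
  invisible(x)
}

#' Write a study report (TSV table plus JSON document)
#'
#' @param study A `study_report`.
#' @param path Base output path: `<path>.tsv` holds the per-cell table,
#'   `<path>.json` the full machine-readable report.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(study, path) {
  stopifnot(inherits(study, "study_report"))
  utils::write.table(study$report, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  doc <- list(seed = study$seed, report = study$report,
              trajectories = study$trajectories)
  jsonlite::write_json(doc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(path)
}
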