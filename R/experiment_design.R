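# RSVP session design: oddball sequencing constraints, block/trial structure,
# the ordered train/test split, and the tab-separated event-log contract.

EVENT_LOG_COLUMNS <- c("stimulus_id", "latent_id", "onset_ms", "relevance",
                       "trial", "block", "task")

#' Build one RSVP trial satisfying the oddball sequencing constraints
#'
#' Samples `n_rel` relevant and `n_irr` irrelevant stimulus ids (without
#' replacement within the trial) and orders them so that no relevant
#' stimulus immediately follows another relevant stimulus and every run of
#' five consecutive stimuli contains at least one relevant stimulus.
#'
#' The sequence is found by rejection sampling on the gaps between relevant
#' stimuli (irrelevant runs of length 1-4 between relevant stimuli, 0-4 at
#' the edges), retried up to `max_tries` times.
#'
#' @param relevant_pool,irrelevant_pool Character vectors of candidate
#'   latent/stimulus ids per class.
#' @param n_rel,n_irr Number of relevant / irrelevant presentations
#'   (defaults 20 and 50).
#' @param max_tries Rejection-sampling retry cap; exceeded means the
#'   constraints are infeasible for the requested class ratio.
#' @return A data frame with columns `latent_id` and `relevance`, one row
#'   per presentation in order.
#' @export
build_trial <- function(relevant_pool, irrelevant_pool, n_rel = 20, n_irr = 50,
                        max_tries = 1000) {
  if (n_rel < 1 || n_irr < 0) stop("need n_rel >= 1 and n_irr >= 0", call. = FALSE)
  if (length(relevant_pool) < n_rel || length(irrelevant_pool) < n_irr)
    stop("stimulus pools are smaller than the requested trial counts", call. = FALSE)
  # Feasibility: n_rel relevants induce n_rel+1 irrelevant gaps; the n_rel-1
  # internal gaps must be 1..4, the two edge gaps 0..4.
  if (n_irr < n_rel - 1 || n_irr > 4 * (n_rel + 1))
    stop("constraint-infeasible: class ratio admits no valid sequence",
         call. = FALSE)
  gaps <- NULL
  for (i in seq_len(max_tries)) {
    cand <- c(sample(0:4, 1), if (n_rel > 1) sample(1:4, n_rel - 1, replace = TRUE),
              sample(0:4, 1))
    if (sum(cand) == n_irr) { gaps <- cand; break }
  }
  if (is.null(gaps))
    stop("constraint-infeasible: no valid sequence found within retry cap",
         call. = FALSE)
  is_rel <- logical(0)
  for (i in seq_len(n_rel)) {
    is_rel <- c(is_rel, rep(FALSE, gaps[i]), TRUE)
  }
  is_rel <- c(is_rel, rep(FALSE, gaps[n_rel + 1]))
  ids <- character(length(is_rel))
  ids[is_rel] <- sample(relevant_pool, n_rel)
  ids[!is_rel] <- sample(irrelevant_pool, n_irr)
  data.frame(latent_id = ids,
             relevance = ifelse(is_rel, "relevant", "irrelevant"),
             stringsAsFactors = FALSE)
}

#' Verify RSVP sequencing constraints by brute-force scan
#'
#' Independent checker used in tests and by [build_session()]: scans a
#' relevance sequence for (a) adjacent relevant pairs and (b) windows of
#' five consecutive stimuli without a relevant stimulus.
#'
#' @param relevance Character or logical vector in presentation order
#'   (`"relevant"` / TRUE marks a relevant stimulus).
#' @return `TRUE` when both constraints hold, else `FALSE`.
#' @export
check_trial_constraints <- function(relevance) {
  r <- if (is.logical(relevance)) relevance else relevance == "relevant"
  n <- length(r)
  if (n >= 2) {
    for (i in 2:n) if (r[i] && r[i - 1]) return(FALSE)
  }
  if (n >= 5) {
    for (i in 1:(n - 4)) if (!any(r[i:(i + 4)])) return(FALSE)
  }
  TRUE
}

#' Build a full RSVP session plan
#'
#' Lays out blocks (one task each, task order randomised), trials and
#' stimulus events with onsets at a constant presentation pace. Relevant
#' stimuli are drawn from the task's own category pool; irrelevant stimuli
#' from the complementary (reverse-task) category pool. Ids are sampled
#' without replacement within a trial and with replacement across trials.
#'
#' @param tasks Named list of `category_direction` objects (see
#'   [default_tasks()]).
#' @param latents A `latent_batch` providing the stimulus library.
#' @param blocks_per_task Blocks per task (default 1, giving 8 blocks for
#'   the default 8 tasks).
#' @param trials_per_block RSVP trials per block (default 4).
#' @param n_rel,n_irr Relevant / irrelevant stimuli per trial (defaults
#'   20 and 50).
#' @param period_ms Presentation period; default 500 ms (2 Hz pace).
#' @param inter_trial_ms Gap between consecutive trials (default 1000 ms).
#' @param inter_block_ms Gap between consecutive blocks (default 2000 ms).
#' @param start_ms Onset of the first stimulus (default 2000 ms, leaving
#'   room for the epoch baseline and filter edges).
#' @param seed Optional integer seed for reproducible plans.
#' @return A `session_plan`: list with the event data frame (`events`,
#'   columns `stimulus_id, latent_id, onset_ms, relevance, trial, block,
#'   task`), the task list and the timing parameters.
#' @export
build_session <- function(tasks, latents, blocks_per_task = 1,
                          trials_per_block = 4, n_rel = 20, n_irr = 50,
                          period_ms = 500, inter_trial_ms = 1000,
                          inter_block_ms = 2000, start_ms = 2000,
                          seed = NULL) {
  if (length(tasks) == 0) stop("`tasks` must be non-empty", call. = FALSE)
  stopifnot(inherits(latents, "latent_batch"))
  if (!is.null(seed)) return(with_seed(seed, build_session(
    tasks, latents, blocks_per_task, trials_per_block, n_rel, n_irr,
    period_ms, inter_trial_ms, inter_block_ms, start_ms, seed = NULL)))

  pools <- lapply(tasks, function(d) {
    rel <- rownames(latents)[assign_relevance(latents, d) == "relevant"]
    irr <- rownames(latents)[assign_relevance(latents, reverse_direction(d)) == "relevant"]
    list(relevant = rel, irrelevant = irr)
  })
  task_order <- sample(rep(names(tasks), blocks_per_task))
  events <- vector("list", length(task_order) * trials_per_block)
  clock <- start_ms
  k <- 0L
  ev_counter <- 0L
  for (b in seq_along(task_order)) {
    task <- task_order[[b]]
    for (tr in seq_len(trials_per_block)) {
      trial <- build_trial(pools[[task]]$relevant, pools[[task]]$irrelevant,
                           n_rel = n_rel, n_irr = n_irr)
      stopifnot(check_trial_constraints(trial$relevance))
      n_ev <- nrow(trial)
      trial$stimulus_id <- sprintf("s%06d", ev_counter + seq_len(n_ev))
      trial$onset_ms <- clock + period_ms * (seq_len(n_ev) - 1L)
      trial$trial <- tr
      trial$block <- b
      trial$task <- task
      ev_counter <- ev_counter + n_ev
      clock <- clock + period_ms * n_ev + inter_trial_ms
      k <- k + 1L
      events[[k]] <- trial
    }
    clock <- clock + inter_block_ms
  }
  events <- do.call(rbind, events)
  events <- events[, EVENT_LOG_COLUMNS]
  rownames(events) <- NULL
  structure(list(events = events, tasks = tasks, period_ms = period_ms,
                 n_rel = n_rel, n_irr = n_irr),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<session_plan> %d events, %d blocks, tasks: %s\n",
              nrow(ev), max(ev$block), paste(unique(ev$task), collapse = ", ")))
  invisible(x)
}

#' Ordered train/test split
#'
#' Splits rows in presentation order: the first `floor(n * train_fraction)`
#' rows form the training set, the remainder the test set, both preserving
#' order. This mimics online execution, in which feedback arrives in the
#' order the stimuli were seen.
#'
#' @param x Data frame (or matrix) whose rows are ordered events/epochs.
#' @param train_fraction Fraction assigned to training; default 0.8,
#'   strictly between 0 and 1.
#' @return List with elements `train` and `test`.
#' @export
split_ordered <- function(x, train_fraction = 0.8) {
  n <- nrow(x)
  if (is.null(n) || n < 2) stop("need at least two rows to split", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  k <- floor(n * train_fraction)
  list(train = x[seq_len(k), , drop = FALSE],
       test = x[setdiff(seq_len(n), seq_len(k)), , drop = FALSE])
}

#' Write an event log as tab-separated text
#'
#' Fixed-header TSV (`stimulus_id, latent_id, onset_ms, relevance, trial,
#' block, task`): the contract between the session builder, the simulator,
#' preprocessing and the classifier.
#'
#' @param events Event data frame (e.g. `plan$events`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(EVENT_LOG_COLUMNS, names(events))
  if (length(missing_cols))
    stop("event log misses columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.table(events[, EVENT_LOG_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event log written by [write_events()]
#'
#' @param path TSV path.
#' @return Event data frame with the fixed column set.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_LOG_COLUMNS, names(ev))
  if (length(missing_cols))
    stop("not an event log: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ev[, EVENT_LOG_COLUMNS]
}
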