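# Shared fixtures: tiny synthetic objects built in code.

# A quiet, small simulation configuration for fast structural tests.
tiny_sim <- function(n_channels = 4, rate = 250, blink_rate_per_min = 0, ...) {
  sim_config(n_channels = n_channels, rate = rate,
             blink_rate_per_min = blink_rate_per_min, ...)
}

# Minimal event data frame at the standard 2 Hz pace.
make_event_df <- function(relevance, period_ms = 500, start_ms = 2000,
                          task = "young") {
  n <- length(relevance)
  data.frame(stimulus_id = sprintf("s%06d", seq_len(n)),
             latent_id = sprintf("z%05d", seq_len(n)),
             onset_ms = start_ms + period_ms * (seq_len(n) - 1),
             relevance = relevance,
             trial = 1L, block = 1L, task = task,
             stringsAsFactors = FALSE)
}

# Wrap a channels x samples matrix as a recording.
make_recording <- function(data, rate = 250,
                           channels = default_channels(nrow(data)),
                           events = NULL) {
  rownames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels,
                 events = events),
            class = "eeg_recording")
}

# Build an epoch_set directly from an epochs x channels x samples array.
make_epoch_set <- function(data, rate = 250, window_ms = c(-200, 900),
                           relevance = rep("relevant", dim(data)[1]),
                           channels = default_channels(dim(data)[2])) {
  times <- window_ms[1] + (seq_len(dim(data)[3]) - 1) * 1000 / rate
  structure(list(data = data, times = times, rate = rate,
                 channels = channels,
                 events = make_event_df(relevance),
                 retained = rep(TRUE, dim(data)[1]),
                 window_ms = window_ms, baseline_ms = c(-200, 0)),
            class = "epoch_set")
}

# A small preprocessed session used by several classifier tests.
small_session_epochs <- function(seed = 42, pairs = "young|old",
                                 trials_per_block = 2, n_channels = 8,
                                 m = 4, n_latents = 150) {
  set.seed(seed)
  tasks <- default_tasks(m, pairs)
  lat <- sample_latents(n_latents, m)
  plan <- build_session(tasks, lat, trials_per_block = trials_per_block)
  rec <- simulate_recording(plan, tiny_sim(n_channels = n_channels))
  list(epochs = retained_epochs(preprocess(rec)), latents = lat,
       tasks = tasks)
}
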