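# Synthetic multichannel EEG-like recordings for a session plan: 1/f + white
# background noise, a stimulus-evoked response common to all events, a
# parietal relevance positivity for relevant events only, and frontal blink
# transients. Every injected quantity is known, so downstream stages have
# ground truth.

# Approximate 2D scalp positions (x: left -> right, y: posterior -> anterior)
# for a 32-electrode 10/20-style montage; used only to derive smooth spatial
# topographies, not for source modelling.
CHANNEL_POSITIONS <- local({
  p <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    AF3 = c(-0.35, 0.82), AF4 = c(0.35, 0.82),
    F7 = c(-0.81, 0.59), F3 = c(-0.50, 0.60), Fz = c(0, 0.60),
    F4 = c(0.50, 0.60), F8 = c(0.81, 0.59),
    FC5 = c(-0.77, 0.30), FC1 = c(-0.30, 0.32), FC2 = c(0.30, 0.32),
    FC6 = c(0.77, 0.30),
    T7 = c(-1, 0), C3 = c(-0.55, 0), Cz = c(0, 0), C4 = c(0.55, 0),
    T8 = c(1, 0),
    CP5 = c(-0.77, -0.30), CP1 = c(-0.30, -0.32), CP2 = c(0.30, -0.32),
    CP6 = c(0.77, -0.30),
    P7 = c(-0.81, -0.59), P3 = c(-0.50, -0.60), Pz = c(0, -0.60),
    P4 = c(0.50, -0.60), P8 = c(0.81, -0.59),
    PO9 = c(-0.59, -0.85), O1 = c(-0.31, -0.95), Oz = c(0, -1),
    O2 = c(0.31, -0.95), PO10 = c(0.59, -0.85))
  colnames(p) <- c("x", "y")
  p
})

#' Default channel labels for an n-channel montage
#'
#' For 32 channels, the full 10/20-style montage; for fewer, a spatially
#' spread subset that always includes the parietal midline (Pz).
#'
#' @param n Number of channels (1-32).
#' @return Character vector of channel labels.
#' @export
default_channels <- function(n = 32) {
  if (n < 1 || n > nrow(CHANNEL_POSITIONS))
    stop("supported montages have 1-32 channels", call. = FALSE)
  preference <- c("Pz", "Cz", "Fz", "Oz", "P3", "P4", "Fp1", "Fp2",
                  "C3", "C4", "O1", "O2", "F3", "F4", "CP1", "CP2",
                  "FC1", "FC2", "P7", "P8", "T7", "T8", "CP5", "CP6",
                  "FC5", "FC6", "F7", "F8", "AF3", "AF4", "PO9", "PO10")
  lab <- preference[seq_len(n)]
  rownames(CHANNEL_POSITIONS)[rownames(CHANNEL_POSITIONS) %in% lab]
}

#' Spatial topography weights centred on a scalp location
#'
#' Gaussian fall-off of component amplitude with scalp distance from a
#' centre electrode (or explicit x/y position), normalised to a maximum
#' weight of 1.
#'
#' @param channels Channel labels (subset of the built-in 32).
#' @param center Electrode label (e.g. `"Pz"`) or numeric `c(x, y)`.
#' @param sigma Spatial spread of the Gaussian (head units; default 0.5).
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
scalp_topography <- function(channels, center = "Pz", sigma = 0.5) {
  unknown <- setdiff(channels, rownames(CHANNEL_POSITIONS))
  if (length(unknown))
    stop("unknown channels: ", paste(unknown, collapse = ", "), call. = FALSE)
  ctr <- if (is.character(center)) CHANNEL_POSITIONS[center, ] else center
  pos <- CHANNEL_POSITIONS[channels, , drop = FALSE]
  d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  w / max(w)
}

#' Simulation configuration for synthetic EEG recordings
#'
#' Defaults emulate the acquisition and grand-average effect structure of a
#' 2 Hz RSVP oddball study: 32 channels at 1000 Hz; a relevance-evoked
#' parietal positivity peaking 464 ms after stimulus onset with a 2.36 uV
#' amplitude difference; an earlier occipital response common to all
#' stimuli; 1/f-shaped plus white background noise; and sporadic frontal
#' blink artifacts of around 500 uV.
#'
#' @param n_channels Number of channels (default 32).
#' @param rate Sampling rate in Hz (default 1000).
#' @param channels Channel labels; default [default_channels()] of
#'   `n_channels`.
#' @param erp_latency_ms Peak latency of the relevance positivity (ms after
#'   onset; default 464).
#' @param erp_amplitude Peak amplitude difference between relevant and
#'   irrelevant stimuli in uV (default 2.36).
#' @param erp_width_ms Full width at half maximum of the Gaussian component
#'   (default 150 ms).
#' @param erp_center,erp_sigma Topography centre and spatial spread of the
#'   relevance component (default parietal maximum at Pz).
#' @param vep_amplitude,vep_latency_ms,vep_width_ms,vep_center The common
#'   stimulus-evoked response injected for every event (default 1.5 uV
#'   occipital response at 120 ms).
#' @param noise_pink_sd Standard deviation of the 1/f-shaped noise per
#'   channel in uV (default 6).
#' @param noise_white_sd Standard deviation of the broadband white noise per
#'   channel in uV (default 3).
#' @param noise_alpha Spectral exponent of the pink component (default 1;
#'   power ~ 1/f^alpha).
#' @param blink_rate_per_min Blink artifact rate (default 5 per minute,
#'   reflecting suppressed blinking during RSVP).
#' @param blink_amplitude Blink peak amplitude in uV (default 500).
#' @param blink_width_ms Blink FWHM (default 150 ms).
#' @param per_task_latency_shift_ms Named numeric vector of per-task offsets
#'   added to `erp_latency_ms` (default none).
#' @param extra_components Optional list of additional components, each a
#'   list with `latency_ms`, `width_ms`, `amplitude`, `center`, `sigma` and
#'   `condition` (`"all"`, `"relevant"` or `"irrelevant"`).
#' @param post_ms Silence appended after the last event (default 2000 ms).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_channels = 32, rate = 1000,
                       channels = default_channels(n_channels),
                       erp_latency_ms = 464, erp_amplitude = 2.36,
                       erp_width_ms = 150, erp_center = "Pz",
                       erp_sigma = 0.5,
                       vep_amplitude = 1.5, vep_latency_ms = 120,
                       vep_width_ms = 80, vep_center = "Oz",
                       noise_pink_sd = 6, noise_white_sd = 3,
                       noise_alpha = 1,
                       blink_rate_per_min = 5, blink_amplitude = 500,
                       blink_width_ms = 150,
                       per_task_latency_shift_ms = NULL,
                       extra_components = NULL,
                       post_ms = 2000) {
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (length(channels) != n_channels)
    stop("`channels` must have length `n_channels`", call. = FALSE)
  if (erp_amplitude < 0 || vep_amplitude < 0 || blink_amplitude < 0 ||
      noise_pink_sd < 0 || noise_white_sd < 0)
    stop("amplitudes and noise levels must be non-negative", call. = FALSE)
  if (blink_rate_per_min < 0) stop("blink rate must be >= 0", call. = FALSE)
  cfg <- list(n_channels = n_channels, rate = rate, channels = channels,
              erp_latency_ms = erp_latency_ms, erp_amplitude = erp_amplitude,
              erp_width_ms = erp_width_ms, erp_center = erp_center,
              erp_sigma = erp_sigma,
              vep_amplitude = vep_amplitude, vep_latency_ms = vep_latency_ms,
              vep_width_ms = vep_width_ms, vep_center = vep_center,
              noise_pink_sd = noise_pink_sd, noise_white_sd = noise_white_sd,
              noise_alpha = noise_alpha,
              blink_rate_per_min = blink_rate_per_min,
              blink_amplitude = blink_amplitude,
              blink_width_ms = blink_width_ms,
              per_task_latency_shift_ms = per_task_latency_shift_ms,
              extra_components = extra_components,
              post_ms = post_ms)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d ch @ %g Hz; relevance ERP %.2f uV @ ",
                     "%g ms (FWHM %g ms); noise pink %g + white %g uV; ",
                     "blinks %g/min @ %g uV\n"),
              x$n_channels, x$rate, x$erp_amplitude, x$erp_latency_ms,
              x$erp_width_ms, x$noise_pink_sd, x$noise_white_sd,
              x$blink_rate_per_min, x$blink_amplitude))
  invisible(x)
}

# FWHM -> Gaussian standard deviation.
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Add a Gaussian-windowed component into `data` (channels x samples). The
# single-channel waveform carrying every occurrence is accumulated first,
# then spread over channels by the topography in one outer product.
add_component <- function(data, rate, onset_ms, latency_ms, width_ms,
                          amplitude, topo) {
  if (amplitude == 0 || length(onset_ms) == 0) return(data)
  sd_s <- fwhm_to_sd(width_ms) / 1000 * rate
  half <- ceiling(4 * sd_s)
  n_samp <- ncol(data)
  wave <- numeric(n_samp)
  for (on in onset_ms) {
    mu <- on / 1000 * rate + latency_ms / 1000 * rate + 1
    idx <- max(1L, floor(mu - half)):min(n_samp, ceiling(mu + half))
    wave[idx] <- wave[idx] + amplitude * exp(-((idx - mu)^2) / (2 * sd_s^2))
  }
  data + outer(topo, wave)
}

# 1/f^alpha-shaped Gaussian noise, one column per channel, each column
# standardised to unit SD. Spectral shaping of white noise via the FFT.
pink_noise <- function(n, rate, alpha = 1, n_channels = 1) {
  n2 <- stats::nextn(max(n, 2L), c(2, 3, 5))
  w <- matrix(stats::rnorm(n2 * n_channels), n2, n_channels)
  sp <- stats::mvfft(w)
  k <- seq_len(n2) - 1
  f <- pmin(k, n2 - k) * rate / n2
  shape <- 1 / pmax(f, 0.1)^(alpha / 2)
  shape[1] <- 0  # no DC drift term
  x <- Re(stats::mvfft(sp * shape, inverse = TRUE)) / n2
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate a continuous multichannel recording for a session plan
#'
#' Produces background noise on all channels and injects, at each event
#' onset, the common stimulus-evoked response; relevant events additionally
#' receive the relevance positivity. Blink artifacts are added as frontal
#' high-amplitude transients at the configured Poisson rate. The result is
#' fully reproducible given `seed`.
#'
#' @param plan A `session_plan` or an event data frame with at least
#'   `onset_ms`, `relevance` and (optionally) `task` columns.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   uV), `rate`, `channels` and the linked `events` data frame.
#' @export
simulate_recording <- function(plan, cfg = sim_config(), seed = NULL) {
  events <- if (inherits(plan, "session_plan")) plan$events else plan
  if (!is.data.frame(events) || nrow(events) == 0)
    stop("`plan` must contain at least one event", call. = FALSE)
  if (!all(c("onset_ms", "relevance") %in% names(events)))
    stop("events need `onset_ms` and `relevance` columns", call. = FALSE)
  if (!is.null(seed)) return(with_seed(seed, simulate_recording(plan, cfg, seed = NULL)))

  rate <- cfg$rate
  n_samp <- ceiling((max(events$onset_ms) + cfg$post_ms) / 1000 * rate)
  if (any(events$onset_ms < 0))
    stop("event onsets must be non-negative", call. = FALSE)
  nch <- cfg$n_channels

  data <- matrix(0, nrow = nch, ncol = n_samp,
                 dimnames = list(cfg$channels, NULL))
  if (cfg$noise_pink_sd > 0)
    data <- data + cfg$noise_pink_sd *
      t(pink_noise(n_samp, rate, cfg$noise_alpha, n_channels = nch))
  if (cfg$noise_white_sd > 0)
    data <- data + matrix(stats::rnorm(nch * n_samp, sd = cfg$noise_white_sd),
                          nch, n_samp)

  vep_topo <- scalp_topography(cfg$channels, cfg$vep_center, 0.6)
  data <- add_component(data, rate, events$onset_ms, cfg$vep_latency_ms,
                        cfg$vep_width_ms, cfg$vep_amplitude, vep_topo)

  erp_topo <- scalp_topography(cfg$channels, cfg$erp_center, cfg$erp_sigma)
  rel <- events[events$relevance == "relevant", , drop = FALSE]
  shifts <- cfg$per_task_latency_shift_ms
  if (is.null(shifts) || !("task" %in% names(rel))) {
    data <- add_component(data, rate, rel$onset_ms, cfg$erp_latency_ms,
                          cfg$erp_width_ms, cfg$erp_amplitude, erp_topo)
  } else {
    for (task in unique(rel$task)) {
      sh <- if (task %in% names(shifts)) shifts[[task]] else 0
      data <- add_component(data, rate,
                            rel$onset_ms[rel$task == task],
                            cfg$erp_latency_ms + sh,
                            cfg$erp_width_ms, cfg$erp_amplitude, erp_topo)
    }
  }

  for (comp in cfg$extra_components) {
    sel <- switch(comp$condition %||% "all",
                  all = events,
                  relevant = events[events$relevance == "relevant", ],
                  irrelevant = events[events$relevance == "irrelevant", ])
    topo <- scalp_topography(cfg$channels, comp$center %||% "Cz",
                             comp$sigma %||% 0.5)
    data <- add_component(data, rate, sel$onset_ms, comp$latency_ms,
                          comp$width_ms, comp$amplitude, topo)
  }

  if (cfg$blink_rate_per_min > 0 && cfg$blink_amplitude > 0) {
    dur_min <- n_samp / rate / 60
    n_blinks <- stats::rpois(1, cfg$blink_rate_per_min * dur_min)
    if (n_blinks > 0) {
      blink_ms <- sort(stats::runif(n_blinks, 0, n_samp / rate * 1000))
      blink_topo <- scalp_topography(cfg$channels, c(0, 1.05), 0.45)
      data <- add_component(data, rate, blink_ms, 0, cfg$blink_width_ms,
                            cfg$blink_amplitude, blink_topo)
    }
  }

  structure(list(data = data, rate = rate, channels = cfg$channels,
                 events = events, config = cfg),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  invisible(x)
}

#' Inject high-amplitude transients into a fraction of epochs
#'
#' Contaminates `round(fraction * n_events)` randomly chosen events with a
#' large frontal transient centred inside the upcoming epoch window,
#' returning the ground-truth list of contaminated event ids. Provides an
#' oracle for threshold-based artifact rejection.
#'
#' @param recording An `eeg_recording`.
#' @param fraction Fraction of events to contaminate, in `[0, 1)`.
#' @param amplitude Transient peak amplitude in uV (default 500).
#' @param width_ms Transient FWHM (default 100 ms).
#' @param center_ms Transient centre relative to event onset (default
#'   350 ms, inside a -200..900 ms epoch).
#' @param seed Optional integer seed.
#' @return List with `recording` (contaminated copy) and `artifact_ids`
#'   (stimulus ids of contaminated events, possibly empty).
#' @export
inject_artifact_epochs <- function(recording, fraction, amplitude = 500,
                                   width_ms = 100, center_ms = 350,
                                   seed = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) return(with_seed(seed, inject_artifact_epochs(
    recording, fraction, amplitude, width_ms, center_ms, seed = NULL)))
  ev <- recording$events
  k <- round(fraction * nrow(ev))
  if (k == 0) return(list(recording = recording, artifact_ids = character(0)))
  pick <- sort(sample(nrow(ev), k))
  topo <- scalp_topography(recording$channels, c(0, 1.05), 0.45)
  recording$data <- add_component(recording$data, recording$rate,
                                  ev$onset_ms[pick], center_ms, width_ms,
                                  amplitude, topo)
  ids <- if ("stimulus_id" %in% names(ev)) ev$stimulus_id[pick] else pick
  list(recording = recording, artifact_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
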