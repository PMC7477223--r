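# Continuous recording + event log -> cleaned, decimated epoch set:
# zero-phase FIR band-pass, epoching with baseline correction, amplitude
# percentile (or absolute-threshold) artifact rejection, decimation.

# Linear convolution of each row of x (channels x samples) with taps b via
# the FFT, truncated to the full convolution length.
fft_convolve_rows <- function(x, b) {
  lx <- ncol(x); lb <- length(b)
  n <- stats::nextn(lx + lb - 1L, c(2, 3, 5))
  X <- stats::mvfft(rbind(t(x), matrix(0, n - lx, nrow(x))))
  B <- stats::fft(c(b, numeric(n - lb)))
  t(Re(stats::mvfft(X * B, inverse = TRUE))[seq_len(lx + lb - 1L), ,
                                            drop = FALSE]) / n
}

#' Design the band-pass FIR filter used for EEG cleaning
#'
#' Windowed-sinc (Hamming) linear-phase band-pass via [signal::fir1()]. The
#' number of taps is capped at `3 * rate + 1` (odd), which keeps the
#' transition at the 0.2 Hz low edge as sharp as a bounded-order FIR allows
#' while the 35 Hz high edge is comfortably sharp.
#'
#' @param rate Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (defaults 0.2 and 35 Hz).
#' @param taps Optional tap count override (forced odd).
#' @return Numeric vector of filter coefficients.
#' @export
design_bandpass <- function(rate, low_hz = 0.2, high_hz = 35, taps = NULL) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop("invalid band: need 0 < low < high < rate/2", call. = FALSE)
  if (is.null(taps)) taps <- 3L * as.integer(rate) + 1L
  if (taps %% 2L == 0L) taps <- taps + 1L
  b <- signal::fir1(taps - 1L, c(low_hz, high_hz) / (rate / 2), type = "pass")
  # a bounded-order window design cannot fully realise a 0.2 Hz edge; null
  # the DC gain exactly so constant offsets are always removed
  b - mean(b)
}

#' Band-pass filter a continuous recording
#'
#' Applies the linear-phase FIR band-pass to every channel with exact
#' group-delay compensation (the symmetric-filter delay of
#' `(taps - 1) / 2` samples is removed), giving zero phase distortion at
#' single-pass gain. Mid-band gain is within 10% of unity; DC and
#' frequencies well above the high cut are attenuated below 0.1.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz (defaults 0.2 and 35).
#' @param taps Optional tap-count override passed to [design_bandpass()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(recording, low_hz = 0.2, high_hz = 35,
                            taps = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  b <- design_bandpass(recording$rate, low_hz, high_hz, taps)
  delay <- (length(b) - 1L) / 2L
  n <- ncol(recording$data)
  y <- fft_convolve_rows(recording$data, b)
  out <- y[, delay + seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(recording$data)
  recording$data <- out
  recording$filter <- list(low_hz = low_hz, high_hz = high_hz,
                           taps = length(b), zero_phase = TRUE)
  recording
}

#' Cut a recording into baseline-corrected epochs
#'
#' Extracts, for every event, the half-open window
#' `[window_ms[1], window_ms[2])` relative to stimulus onset and subtracts
#' per channel the mean over the baseline interval. With the default
#' -200..900 ms window the epoch length is exactly `1.1 * rate` samples.
#'
#' @param recording An `eeg_recording` (normally already band-pass
#'   filtered).
#' @param events Event data frame; defaults to the recording's linked
#'   events.
#' @param window_ms Epoch window relative to onset, half-open (default
#'   `c(-200, 900)`).
#' @param baseline_ms Baseline interval, half-open (default `c(-200, 0)`).
#' @return An `epoch_set`: list with `data` (epochs x channels x samples
#'   array), `times` (ms relative to onset), `rate`, `channels`, the
#'   per-epoch `events` and a `retained` logical flag (all `TRUE`).
#' @export
epoch_recording <- function(recording, events = recording$events,
                            window_ms = c(-200, 900),
                            baseline_ms = c(-200, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- recording$rate
  step_ms <- 1000 / rate
  n_win <- round((window_ms[2] - window_ms[1]) / step_ms)
  times <- window_ms[1] + (seq_len(n_win) - 1) * step_ms
  onset_sample <- as.integer(round(events$onset_ms / 1000 * rate)) + 1L
  first <- onset_sample + as.integer(round(window_ms[1] / 1000 * rate))
  last <- first + n_win - 1L
  bad <- which(first < 1L | last > ncol(recording$data))
  if (length(bad))
    stop("epoch window outside recording for events: ",
         paste(utils::head(events$stimulus_id[bad], 10), collapse = ", "),
         call. = FALSE)
  nch <- nrow(recording$data)
  base_idx <- which(times >= baseline_ms[1] & times < baseline_ms[2])
  if (!length(base_idx)) stop("empty baseline interval", call. = FALSE)
  n_ev <- nrow(events)
  # channels x (samples-within-epoch fastest, then epochs), then reorder to
  # epochs x channels x samples
  idx <- as.vector(vapply(first, function(f) f + 0:(n_win - 1L),
                          integer(n_win)))
  data <- array(recording$data[, idx], dim = c(nch, n_win, n_ev))
  data <- aperm(data, c(3, 1, 2))
  base_mean <- rowMeans(data[, , base_idx, drop = FALSE], dims = 2)
  data <- data - array(base_mean, dim = dim(data))
  structure(list(data = data, times = times, rate = rate,
                 channels = recording$channels, events = events,
                 retained = rep(TRUE, nrow(events)),
                 window_ms = window_ms, baseline_ms = baseline_ms),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d retained) x %d ch x %d samples @ %g Hz, window [%g, %g) ms\n",
              dim(x$data)[1], sum(x$retained), dim(x$data)[2], dim(x$data)[3],
              x$rate, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Flag high-amplitude epochs as rejected
#'
#' Threshold-based artifact heuristic. In fraction mode (the default) the
#' `ceiling(fraction * n)` retained epochs with the largest absolute maximum
#' voltage (over all channels and samples) are rejected, emulating the
#' removal of approximately 11% of epochs per participant. In absolute mode
#' (`threshold` given) every epoch whose absolute maximum exceeds the
#' threshold is rejected. Ties on amplitude are broken by rejecting the
#' earlier-onset epoch first.
#'
#' @param epochs An `epoch_set`.
#' @param fraction Fraction of epochs to reject (default 0.11).
#' @param threshold Optional absolute voltage threshold in uV; when given,
#'   `fraction` is ignored.
#' @return The `epoch_set` with `retained` updated and the rejection rule
#'   recorded in `rejection`.
#' @export
reject_artifacts <- function(epochs, fraction = 0.11, threshold = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$data)[1]
  am <- matrix(abs(epochs$data), nrow = n_ep)
  absmax <- am[cbind(seq_len(n_ep), max.col(am, ties.method = "first"))]
  if (!is.null(threshold)) {
    drop_idx <- which(epochs$retained & absmax > threshold)
  } else {
    if (fraction < 0 || fraction >= 1)
      stop("`fraction` must lie in [0, 1)", call. = FALSE)
    cand <- which(epochs$retained)
    k <- ceiling(fraction * length(cand))
    ord <- cand[order(-absmax[cand], epochs$events$onset_ms[cand])]
    drop_idx <- ord[seq_len(k)]
  }
  epochs$retained[drop_idx] <- FALSE
  epochs$rejection <- list(fraction = if (is.null(threshold)) fraction else NA,
                           threshold = threshold %||% NA,
                           n_rejected = length(drop_idx))
  epochs
}

#' Decimate an epoch set
#'
#' Keeps every `factor`-th sample starting at the first, divides the
#' sampling rate accordingly and recomputes the time axis. The band-pass
#' high cut (35 Hz) already sits far below the post-decimation Nyquist
#' frequency, so no additional anti-alias filter is applied. Baseline
#' correction is re-applied on the decimated grid so retained epochs stay
#' exactly zero-mean over the baseline.
#'
#' @param epochs An `epoch_set`.
#' @param factor Positive integer decimation factor (default 4).
#' @return The decimated `epoch_set`.
#' @export
decimate_epochs <- function(epochs, factor = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(epochs)
  keep <- seq(1L, dim(epochs$data)[3], by = factor)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  epochs$rate <- epochs$rate / factor
  base_idx <- which(epochs$times >= epochs$baseline_ms[1] &
                      epochs$times < epochs$baseline_ms[2])
  if (length(base_idx)) {
    base_mean <- rowMeans(epochs$data[, , base_idx, drop = FALSE], dims = 2)
    epochs$data <- epochs$data - array(base_mean, dim = dim(epochs$data))
  }
  epochs
}

#' Run the fixed preprocessing pipeline
#'
#' Enforces the canonical stage order: band-pass filter, epoch + baseline
#' correction, amplitude-based rejection, decimation.
#'
#' @param recording An `eeg_recording`.
#' @param events Event data frame (defaults to the recording's).
#' @param low_hz,high_hz Band-pass edges (defaults 0.2 and 35 Hz).
#' @param window_ms,baseline_ms Epoch window and baseline (defaults
#'   `c(-200, 900)` and `c(-200, 0)` ms).
#' @param reject_fraction Rejection fraction (default 0.11); `NULL` skips
#'   rejection.
#' @param reject_threshold Optional absolute rejection threshold (uV).
#' @param decimation Decimation factor (default 4).
#' @param taps Optional FIR tap-count override.
#' @return The final `epoch_set`.
#' @export
preprocess <- function(recording, events = recording$events,
                       low_hz = 0.2, high_hz = 35,
                       window_ms = c(-200, 900), baseline_ms = c(-200, 0),
                       reject_fraction = 0.11, reject_threshold = NULL,
                       decimation = 4, taps = NULL) {
  rec <- bandpass_filter(recording, low_hz, high_hz, taps)
  ep <- epoch_recording(rec, events, window_ms, baseline_ms)
  if (!is.null(reject_threshold)) {
    ep <- reject_artifacts(ep, threshold = reject_threshold)
  } else if (!is.null(reject_fraction)) {
    ep <- reject_artifacts(ep, fraction = reject_fraction)
  }
  decimate_epochs(ep, decimation)
}

#' Keep only retained epochs
#'
#' @param epochs An `epoch_set`.
#' @return The `epoch_set` restricted to retained epochs.
#' @export
retained_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(epochs$retained)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$events <- epochs$events[keep, , drop = FALSE]
  rownames(epochs$events) <- NULL
  epochs$retained <- rep(TRUE, length(keep))
  epochs
}

#' Subset an epoch set by epoch index
#'
#' @param epochs An `epoch_set`.
#' @param idx Integer or logical index over epochs.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$events <- epochs$events[idx, , drop = FALSE]
  rownames(epochs$events) <- NULL
  epochs$retained <- epochs$retained[idx]
  epochs
}
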