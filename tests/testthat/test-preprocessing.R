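test_that("band-pass gains match the design targets", {
  rate <- 250
  n <- rate * 30
  t <- (seq_len(n) - 1) / rate
  mid <- (n / 3):(2 * n / 3)  # away from edge transients
  amp_after <- function(freq_hz, x = sin(2 * pi * freq_hz * t)) {
    rec <- make_recording(matrix(x, 1), rate = rate,
                          channels = "Pz")
    max(abs(bandpass_filter(rec)$data[1, mid]))
  }
  expect_equal(amp_after(10), 1, tolerance = 0.1)   # mid-band pass
  expect_lte(amp_after(50), 0.1)                    # above the high cut
  expect_lte(amp_after(0, x = rep(1, n)), 0.1)      # DC removed
  rec <- make_recording(matrix(rnorm(n), 1), rate = rate, channels = "Pz")
  expect_error(bandpass_filter(rec, low_hz = 40, high_hz = 30), "invalid band")
  expect_error(bandpass_filter(rec, high_hz = 200), "invalid band")
})

test_that("epoching yields exact window lengths and zero baselines", {
  # 1000 Hz: the -200..900 ms half-open window is exactly 1100 samples
  ev <- make_event_df(c("relevant", "irrelevant"), start_ms = 1000)
  rec <- make_recording(matrix(rnorm(2 * 4000), 2), rate = 1000,
                        channels = c("Pz", "Cz"), events = ev)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(2, 2, 1100))
  expect_equal(ep$times[1], -200)
  expect_equal(ep$times[1100], 899)
  base <- ep$times < 0
  for (i in 1:2) for (ch in 1:2)
    expect_lt(abs(mean(ep$data[i, ch, base])), 1e-9)

  # a constant channel epochs to exactly zero
  rec2 <- make_recording(matrix(5, 1, 4000), rate = 1000, channels = "Pz",
                         events = ev)
  expect_true(all(epoch_recording(rec2)$data == 0))

  # an event too close to the recording start fails, listing the id
  ev_bad <- make_event_df("relevant", start_ms = 0)
  rec3 <- make_recording(matrix(0, 1, 4000), rate = 1000, channels = "Pz",
                         events = ev_bad)
  expect_error(epoch_recording(rec3), "s000001")
})

test_that("rejection flags the highest-amplitude epochs deterministically", {
  set.seed(8)
  n_ep <- 100
  data <- array(rnorm(n_ep * 2 * 50), dim = c(n_ep, 2, 50))
  ep <- make_epoch_set(data, relevance = rep("relevant", n_ep))

  ep0 <- reject_artifacts(ep, fraction = 0)
  expect_true(all(ep0$retained))

  ep11 <- reject_artifacts(ep, fraction = 0.11)
  expect_equal(sum(!ep11$retained), 11)            # ceiling(0.11 * 100)

  # brute-force oracle: sort by absolute maximum, drop the top k
  absmax <- apply(abs(data), 1, max)
  oracle_drop <- order(-absmax)[1:11]
  expect_setequal(which(!ep11$retained), oracle_drop)

  # absolute-threshold mode
  thr <- sort(absmax, decreasing = TRUE)[6]
  ept <- reject_artifacts(ep, threshold = thr)
  expect_equal(which(!ept$retained), which(absmax > thr))
  expect_error(reject_artifacts(ep, fraction = 1), "fraction")
})

test_that("rejection recovers simulator ground-truth contamination", {
  # non-overlapping epochs keep the contamination ground truth exact
  ev <- make_event_df(rep(c("relevant", "irrelevant"), 25), period_ms = 1500)
  rec <- simulate_recording(ev, tiny_sim(), seed = 12)
  out <- inject_artifact_epochs(rec, 0.1, seed = 13)
  ep <- reject_artifacts(epoch_recording(bandpass_filter(out$recording)),
                         fraction = 0.1)
  rejected_ids <- ep$events$stimulus_id[!ep$retained]
  expect_true(all(out$artifact_ids %in% rejected_ids))
})

test_that("decimation subsamples, rescales the clock and preserves band content", {
  ev <- make_event_df(c("relevant", "irrelevant"), start_ms = 1000)
  rec <- make_recording(matrix(rnorm(4000), 1), rate = 1000, channels = "Pz",
                        events = ev)
  ep <- epoch_recording(rec)
  expect_identical(decimate_epochs(ep, 1), ep)

  ep4 <- decimate_epochs(ep, 4)
  expect_equal(dim(ep4$data)[3], 275)               # ceiling(1100 / 4)
  expect_equal(ep4$rate, 250)
  expect_equal(diff(ep4$times[1:2]), 4)
  base <- ep4$times >= -200 & ep4$times < 0
  expect_lt(max(abs(apply(ep4$data[, , base, drop = FALSE], c(1, 2), mean))),
            1e-6)

  # a 10 Hz sinusoid passes through decimation with < 1% amplitude change
  t <- (seq_len(4000) - 1) / 1000
  rec_s <- make_recording(matrix(sin(2 * pi * 10 * t), 1), rate = 1000,
                          channels = "Pz", events = ev)
  eps <- decimate_epochs(epoch_recording(rec_s), 4)
  expect_equal(max(abs(eps$data)), 1, tolerance = 0.01)
  expect_error(decimate_epochs(ep, 0), "positive integer")
})

test_that("the pipeline applies filter, epoch, reject, decimate in order", {
  ev <- make_event_df(rep(c("relevant", "irrelevant"), 20))
  rec <- simulate_recording(ev, tiny_sim(), seed = 21)
  ep <- preprocess(rec)
  expect_equal(ep$rate, 62.5)
  expect_equal(dim(ep$data)[3], 69)                 # ceiling(275 / 4)
  expect_equal(sum(!ep$retained), ceiling(0.11 * nrow(ev)))
  # manual staging reproduces the pipeline output exactly
  manual <- decimate_epochs(reject_artifacts(
    epoch_recording(bandpass_filter(rec)), 0.11), 4)
  expect_equal(ep$data, manual$data)
  expect_identical(ep$retained, manual$retained)
})
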