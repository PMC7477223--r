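# Brute-force AUC oracle: all pairs, ties count one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

test_that("AUC matches hand-computed and brute-force values", {
  expect_equal(auc(c(0.1, 0.4, 0.4, 0.8), c(0, 0, 1, 1)), 0.875)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  s <- c(0.2, 0.9, 0.3, 0.7, 0.7)
  y <- c(0, 1, 0, 1, 0)
  expect_equal(auc(s, y), 1 - auc(s, 1 - y))       # label-inversion symmetry
  expect_error(auc(s, rep(1, 5)), "both classes")

  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    expect_equal(auc(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("permutation p-values follow the count/k convention with floor 1/k", {
  # moderate separation: the trained classifier clearly beats every permuted
  # one without the test set being separable by a lucky sign alone
  set.seed(63)
  n <- 100
  y <- rep(0:1, n / 2)
  sig <- function(lab) cbind(1.5 * lab, 1.5 * lab, 0, 0, 0)
  x_strong <- matrix(rnorm(n * 5), n, 5) + sig(y)
  yt <- rep(0:1, 100)
  xt <- matrix(rnorm(200 * 5), 200, 5) + sig(yt)

  pr <- permutation_test(x_strong, y, xt, yt, k = 50, seed = 1)
  expect_gt(pr$observed, max(pr$permuted))
  expect_equal(pr$p_value, 1 / 50)                 # floor when none exceed
  expect_length(pr$permuted, 50)
  expect_gte(min(pr$p_value), 1 / 50)

  # an anti-predictive observed score sits below the whole null: p = 1
  fake_trainer <- function(x, y) structure(list(flip = TRUE), class = "flip")
  fake_scorer <- function(model, x) -x[, 1]
  pr2 <- permutation_test(x_strong, y, xt, yt, k = 20,
                          trainer = fake_trainer, scorer = fake_scorer,
                          seed = 2)
  expect_equal(pr2$p_value, 1)

  expect_error(permutation_test(x_strong, rep(1, n), xt, yt), "both classes")
})

test_that("difference waves are antisymmetric, linear, and recover the null", {
  set.seed(64)
  n_ep <- 60
  data <- array(rnorm(n_ep * 2 * 275), dim = c(n_ep, 2, 275))
  relevance <- rep(c("relevant", "irrelevant"), n_ep / 2)
  ep <- make_epoch_set(data, relevance = relevance,
                       channels = c("Pz", "Cz"))
  w <- grand_average_difference(ep, "Pz")
  swapped <- ep
  swapped$events$relevance <- ifelse(relevance == "relevant",
                                     "irrelevant", "relevant")
  w2 <- grand_average_difference(swapped, "Pz")
  expect_equal(w2$mean, -w$mean, tolerance = 1e-12)

  # linearity in the epoch data
  ep2 <- ep; ep2$data <- 2 * ep$data
  w3 <- grand_average_difference(ep2, "Pz")
  expect_equal(w3$mean, 2 * w$mean, tolerance = 1e-12)

  # pure-noise data: the peak is within sampling error of zero
  expect_lt(abs(w$peak_amplitude), 4 * w$peak_se)
  expect_true(w$peak_latency_ms >= 250 && w$peak_latency_ms <= 600)

  ep_one <- subset_epochs(ep, relevance == "relevant")
  expect_error(grand_average_difference(ep_one, "Pz"), "both relevance")
  expect_error(grand_average_difference(ep, "XX"), "unknown channel")

  path <- withr::local_tempfile(fileext = ".csv")
  write_difference_wave(w, path)
  back <- utils::read.csv(path)
  expect_equal(back$mean_uv, unname(w$mean), tolerance = 1e-9)
})

test_that("the study runner emits one row per participant-task and is reproducible", {
  cfg <- study_config(n_participants = 3, pairs = "young|old",
                      trials_per_block = 2, n_rel = 6, n_irr = 15,
                      n_latents = 80, m = 4,
                      sim = sim_config(n_channels = 4, rate = 250),
                      checkpoints = c(3, 6))
  s1 <- run_study(cfg, seed = 5)
  expect_equal(nrow(s1$report), 6)                  # 3 participants x 2 tasks
  expect_setequal(unique(s1$report$task), c("young", "old"))
  expect_true(all(c("auc", "sim_positive", "sim_random", "sim_negative")
                  %in% names(s1$report)))

  s2 <- run_study(cfg, seed = 5)
  expect_identical(s1$report, s2$report)            # bit-for-bit determinism
  expect_identical(s1$trajectories, s2$trajectories)

  s3 <- run_study(cfg, seed = 6)
  expect_false(identical(s1$report, s3$report))

  path <- withr::local_tempfile()
  write_study_report(s1, path)
  expect_true(file.exists(paste0(path, ".tsv")))
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 6)
})
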