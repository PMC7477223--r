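# Independent Ledoit-Wolf oracle: the published estimator computed with
# explicit per-sample loops (dimension-normalised Frobenius norms).
lw_oracle <- function(x) {
  n <- nrow(x); d <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- t(xc) %*% xc / n
  mu <- sum(diag(s)) / d
  norm2 <- function(a) sum(a * a) / d
  d2 <- norm2(s - mu * diag(d))
  b2bar <- 0
  for (k in seq_len(n)) b2bar <- b2bar + norm2(tcrossprod(xc[k, ]) - s)
  b2bar <- b2bar / n^2
  lambda <- if (d2 == 0) 0 else min(min(b2bar, d2) / d2, 1)
  list(sigma = (1 - lambda) * s + lambda * mu * diag(d), lambda = lambda)
}

test_that("window-mean features have the documented shape and ordering", {
  # constant epochs give constant features
  data <- array(3.5, dim = c(2, 4, 275))
  ep <- make_epoch_set(data)
  f <- extract_features(ep)
  expect_equal(dim(f), c(2, 4 * 7))
  expect_true(all(f == 3.5))
  # channel-major ordering: first 7 columns belong to the first channel
  expect_equal(colnames(f)[1:7], paste0(ep$channels[1], ".w", 1:7))

  # a temporal ramp averages to the window midpoints
  rate <- 250
  times <- -200 + (0:274) * 4
  ramp <- array(rep(times, each = 2 * 4), dim = c(2, 4, 275))
  epr <- make_epoch_set(ramp)
  fr <- extract_features(epr)
  width <- 750 / 7
  mids <- 50 + width * (seq_len(7) - 0.5)
  expect_lt(max(abs(fr[1, 1:7] - mids)), 4 / 2 + 1e-9)  # half a sample step

  expect_error(extract_features(ep, interval_ms = c(50, 2000)), "outside")
})

test_that("Ledoit-Wolf shrinkage matches the textbook-formula oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1); d <- sample(1:6, 1)
    x <- matrix(rnorm(n * d, sd = runif(1, 0.5, 3)), n, d)
    got <- ledoit_wolf(x)
    ref <- lw_oracle(x)
    expect_equal(got$sigma, ref$sigma, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$lambda, ref$lambda, tolerance = 1e-10)
    expect_gt(min(eigen(got$sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_true(got$lambda >= 0 && got$lambda <= 1)
  }

  # d = 1: any shrinkage leaves the scalar variance untouched
  x1 <- matrix(rnorm(20), 20, 1)
  got1 <- ledoit_wolf(x1)
  expect_equal(got1$sigma[1, 1], mean((x1 - mean(x1))^2), tolerance = 1e-12)

  # consistency: with n >> d the estimate approaches the sample covariance
  set.seed(32)
  xb <- matrix(rnorm(5000 * 3), ncol = 3) %*% matrix(c(2, 1, 0, 0, 1, 1, 0, 0, 3), 3)
  gotb <- ledoit_wolf(xb)
  sb <- crossprod(scale(xb, scale = FALSE)) / nrow(xb)
  expect_lt(gotb$lambda, 0.01)
  expect_lt(max(abs(gotb$sigma - sb)), 0.05)

  expect_error(ledoit_wolf(matrix(1, 1, 3)), "2 samples")
})

test_that("training separates separable classes and survives singularity", {
  set.seed(33)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2) + cbind(6 * y, 0)
  model <- train_relevance(x, y)
  xt <- matrix(rnorm(400), 200, 2) + cbind(6 * rep(0:1, each = 100), 0)
  expect_gte(auc(predict(model, xt)$score, rep(0:1, each = 100)), 0.99)

  # identical class distributions: held-out AUC indistinguishable from 0.5
  x0 <- matrix(rnorm(2000 * 2), ncol = 2)
  y0 <- rep(0:1, 1000)
  m0 <- train_relevance(x0[1:1000, ], y0[1:1000])
  expect_lt(abs(auc(predict(m0, x0[1001:2000, ])$score, y0[1001:2000]) - 0.5),
            0.05)

  # duplicated feature column: the empirical covariance is singular but
  # shrinkage keeps training well-defined
  xs <- cbind(x, x[, 1])
  ms <- train_relevance(xs, y)
  expect_true(ms$lambda > 0)
  expect_true(all(is.finite(ms$w)))

  expect_error(train_relevance(x, rep(1, n)), "both classes")
})

test_that("predictions gate on strict confidence and track the score order", {
  set.seed(34)
  y <- rep(0:1, each = 40)
  x <- matrix(rnorm(160), 80, 2) + cbind(2 * y, 0)
  model <- train_relevance(x, y)
  pred <- predict(model, x)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  expect_identical(pred$label, as.integer(pred$confidence > 0.7))
  expect_identical(order(pred$confidence), order(pred$score))  # monotone link

  # exactly-at-threshold is negative: a zero-score feature has confidence 0.5
  m2 <- model
  m2$threshold <- 0.5
  x_boundary <- matrix(-m2$b * m2$w / sum(m2$w^2), nrow = 1)
  p2 <- predict(m2, x_boundary)
  expect_equal(p2$confidence, 0.5)
  expect_identical(p2$label, 0L)

  expect_error(predict(model, matrix(0, 1, 5)), "dimension")
})

test_that("classical LDA direction is recovered at zero shrinkage", {
  skip_if_not_installed("MASS")
  set.seed(35)
  n <- 300
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3) %*% matrix(c(1, .3, 0, .3, 1, .2, 0, .2, 1), 3) +
    cbind(y, 2 * y, 0)
  ours <- train_relevance(x, y, lambda = 0)
  ref <- MASS::lda(x, grouping = y)
  ratio <- ours$w / drop(ref$scaling)
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)  # proportional
})

test_that("feature rescaling invariance holds at lambda 0 and breaks under shrinkage", {
  set.seed(36)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3) + cbind(y, 0, 0)
  xs <- x; xs[, 2] <- x[, 2] * 100

  s0 <- predict(train_relevance(x, y, lambda = 0), x)$score
  s0s <- predict(train_relevance(xs, y, lambda = 0), xs)$score
  expect_equal(s0, s0s, tolerance = 1e-6)

  s5 <- predict(train_relevance(x, y, lambda = 0.5), x)$score
  s5s <- predict(train_relevance(xs, y, lambda = 0.5), xs)$score
  expect_gt(max(abs(s5 - s5s)), 0.1)   # shrinkage is not scale-invariant
})

test_that("cross-task assembly excludes the reverse task and keeps source labels", {
  tasks <- default_tasks(8)
  rev <- reverse_pairs(tasks)
  set.seed(37)
  features_by_task <- lapply(stats::setNames(names(tasks), names(tasks)),
                             function(t) matrix(rnorm(20), 10, 2))
  labels_by_task <- lapply(features_by_task, function(f)
    rep(c(1L, 0L), 5))

  out <- assemble_training_set(features_by_task, labels_by_task, "blond", rev)
  expect_setequal(out$tasks_used,
                  c("male", "female", "young", "old", "smile", "no smile",
                    "blond"))
  expect_false("dark" %in% out$tasks_used)
  # 6 full tasks (10 epochs) + the target's train portion (8 of 10)
  expect_equal(length(out$y), 6 * 10 + 8)

  out2 <- assemble_training_set(features_by_task, labels_by_task, "smile", rev)
  expect_true("dark" %in% out2$tasks_used)
  expect_false("no smile" %in% out2$tasks_used)

  # pooled labels are the source tasks' own labels, in task order
  expect_equal(out$y[1:10], labels_by_task$male)

  out3 <- assemble_training_set(features_by_task, labels_by_task, "smile", rev,
                                include_target_train = FALSE)
  expect_false("smile" %in% out3$tasks_used)
})

test_that("models serialize to JSON and round-trip numerically", {
  set.seed(38)
  y <- rep(0:1, each = 20)
  x <- matrix(rnorm(80), 40, 2) + cbind(y, 0)
  colnames(x) <- c("Pz.w1", "Pz.w2")
  model <- train_relevance(x, y, tasks_used = c("young", "old"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$w, model$w, tolerance = 1e-12)
  expect_equal(back$sigma, model$sigma, tolerance = 1e-12)
  expect_equal(back$lambda, model$lambda, tolerance = 1e-15)
  expect_identical(back$tasks_used, model$tasks_used)
  xnew <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(back, xnew), predict(model, xnew), tolerance = 1e-12)
})
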