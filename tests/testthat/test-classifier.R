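# Log-mel features, the depthwise CNN, day flagging, and the
# recall-versus-SNR model.

test_that("featurize obeys its conventions", {
  fs <- 50000
  n <- round(0.25 * fs)
  # silence -> constant matrix at the log floor (zero once centred)
  f0 <- featurize(numeric(n), fs, center = FALSE)
  expect_equal(max(f0) - min(f0), 0)
  expect_equal(f0[1, 1], log10(stereopam:::default_feature_config(fs)$log_floor))
  expect_true(all(featurize(numeric(n), fs) == 0))
  # tone concentrates energy in the matching mel rows
  tone <- sin(2 * pi * 12500 * (0:(n - 1)) / fs)
  ft <- featurize(tone, fs, center = FALSE)
  hot <- which.max(rowMeans(ft))
  expect_gt(hot, 32)   # 12.5 kHz sits in the upper mel range at 50 kHz
  # amplitude x10 shifts raw features by a constant; centring removes it
  ft10 <- featurize(10 * tone, fs, center = FALSE)
  active <- rowMeans(ft) > -3
  shift <- (ft10 - ft)[active, ]
  expect_equal(stats::sd(shift), 0, tolerance = 1e-6)
  expect_equal(mean(shift), 2, tolerance = 1e-3)   # 20 dB = 2 decades
  # gain invariance of centred features (broadband clip, above the floor)
  set.seed(4)
  nz <- rnorm(n)
  expect_equal(featurize(10 * nz, fs), featurize(nz, fs),
               tolerance = 1e-6)
  expect_error(featurize(numeric(100), fs), "length")
})

test_that("the network matches the stated parameter budget", {
  par <- stereopam:::cnn_init()
  n <- stereopam:::cnn_n_params(par)
  expect_gte(n, 5000)
  expect_lte(n, 20000)   # within 2x of ~10k
})

test_that("training is deterministic and rejects single-class data", {
  tr <- make_training_clips(c(sperm = 15, cetacean = 5, noise = 15),
                            seed = 3)
  m1 <- train_classifier(tr$clips, tr$labels, 50000, seed = 5, epochs = 2)
  m2 <- train_classifier(tr$clips, tr$labels, 50000, seed = 5, epochs = 2)
  expect_identical(m1$par, m2$par)
  expect_error(train_classifier(tr$clips, rep("noise", length(tr$clips)),
                                50000),
               "both classes")
})

test_that("the trained model separates clicks from noise; shuffled labels do not", {
  m <- small_classifier()
  te <- make_training_clips(c(sperm = 40, cetacean = 10, noise = 40),
                            seed = 91)
  conf <- predict_classifier(m, te$clips)
  expect_gte(auc_score(conf, te$labels == "sperm"), 0.95)
  # label shuffling destroys the signal
  tr <- make_training_clips(c(sperm = 30, cetacean = 5, noise = 30),
                            seed = 17)
  set.seed(1)
  shuffled <- sample(tr$labels)
  ms <- train_classifier(tr$clips, shuffled, 50000, seed = 2, epochs = 6)
  auc_sh <- auc_score(predict_classifier(ms, te$clips),
                      te$labels == "sperm")
  expect_lt(abs(auc_sh - 0.5), 0.25)
})

test_that("classifier weights survive a JSON save/load round trip", {
  m <- small_classifier()
  f <- tempfile(fileext = ".json")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  te <- make_training_clips(c(sperm = 5, cetacean = 1, noise = 5),
                            seed = 55)
  expect_equal(predict_classifier(m2, te$clips),
               predict_classifier(m, te$clips), tolerance = 1e-6)
  unlink(f)
})

test_that("day flagging applies its strict thresholds", {
  mk <- function(day, conf, n) data.frame(day = day, confidence = rep(conf, n))
  tab <- rbind(mk("d1", 0.96, 41),   # flagged
               mk("d2", 0.96, 40),   # not: needs MORE than 40
               mk("d3", 0.94, 100))  # not: needs ABOVE 0.95
  expect_equal(flag_days(tab), "d1")
  expect_equal(flag_days(rbind(tab, mk("d4", 0.99, 50))), c("d1", "d4"))
})

test_that("recall curve has the right shape and the sigmoid fits it", {
  m <- small_classifier()
  set.seed(71)
  n_clip <- round(0.25 * FS)
  clicks <- lapply(1:30, function(i) {
    ck <- synth_click(click_model(ipi_ms = runif(1, 3, 7), n_pulses = 4), FS)
    x <- numeric(n_clip)
    at <- round(n_clip / 2)
    x[at:(at + length(ck) - 1)] <- ck
    x
  })
  noises <- lapply(1:10, function(i) synth_noise(2, 0.26, FS)[1:n_clip])
  cv <- recall_vs_snr(m, clicks, noises, FS,
                      snr_grid_db = seq(-15, 30, by = 5))
  # upper plateau near the clean-click recall, low end near noise FPR
  expect_gt(cv$recall[nrow(cv)], 0.8)
  fpr <- mean(predict_classifier(m, noises) > 0.5)
  expect_lte(cv$recall[1], max(fpr, 0.2))
  iso <- isotonic_recall(cv)
  expect_true(all(diff(iso$recall_iso) >= 0))
  fit <- fit_sigmoid(cv)
  expect_s3_class(fit, "recall_model")
  expect_false(attr(fit, "flat"))
})

test_that("sigmoid fitting recovers known parameters and is idempotent", {
  set.seed(6)
  x <- seq(-5, 15, by = 1)
  r <- pmin(pmax(0.9 / (1 + exp(-0.8 * (x - 5))) +
                   rnorm(length(x), 0, 0.01), 0), 1)
  m <- fit_sigmoid(data.frame(snr_db = x, recall = r))
  expect_equal(m$L, 0.9, tolerance = 0.1)
  expect_equal(m$x0, 5, tolerance = 0.5)
  expect_equal(m$k, 0.8, tolerance = 0.1)
  # refit on own predictions: identical parameters
  m2 <- fit_sigmoid(data.frame(snr_db = x,
                               recall = recall_probability(m, x)))
  expect_equal(m2$L, m$L, tolerance = 1e-6)
  expect_equal(m2$x0, m$x0, tolerance = 1e-6)
  expect_equal(m2$k, m$k, tolerance = 1e-6)
  # flat data: flagged, L at the level
  expect_warning(
    mf <- fit_sigmoid(data.frame(snr_db = x, recall = rep(1, length(x)))),
    "flat")
  expect_true(attr(mf, "flat"))
  expect_equal(mf$L, 1)
  expect_error(fit_sigmoid(data.frame(snr_db = 1:3, recall = c(0, 0.5, 1))),
               "at least 4")
})
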