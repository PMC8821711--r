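# Synthetic scene generator: click structure, arrival geometry, noise
# shaping, and full-scene rendering against its own stated conventions.

test_that("synth_click renders the multipulse structure", {
  fs <- 50000
  # 3 pulses at 5 ms: envelope peaks at 0, 5, 10 ms within 1 sample
  ck <- synth_click(click_model(n_pulses = 3, ipi_ms = 5,
                                pulse_decay_db = 0), fs)
  env <- abs(ck)
  pk <- sort(order(env, decreasing = TRUE)[1:400])
  # cluster the top samples into pulses and take each cluster's max
  cl <- cumsum(c(1, diff(pk) > 50))
  peaks <- vapply(split(pk, cl), function(ix) ix[which.max(env[ix])],
                  numeric(1))
  gaps_ms <- diff(sort(peaks)) / fs * 1000
  expect_length(gaps_ms, 2)
  expect_true(all(abs(gaps_ms - 5) <= 1000 / fs))
  expect_gte(length(ck) / fs * 1000, 15)
})

test_that("pulse decay of 6 dB halves successive pulse RMS within 5%", {
  fs <- 50000
  cm <- click_model(n_pulses = 3, ipi_ms = 5, pulse_decay_db = 6)
  ck <- synth_click(cm, fs)
  p0 <- which.max(abs(ck))
  w <- round(0.002 * fs)
  r <- vapply(0:2, function(k) {
    i <- p0 + round(k * 5e-3 * fs)
    stereopam:::rms(ck[(i - w / 2):(i + w / 2)])
  }, numeric(1))
  expect_equal(r[2] / r[1], 0.5, tolerance = 0.05)
  expect_equal(r[3] / r[2], 0.5, tolerance = 0.05)
})

test_that("single-pulse clicks have no secondary autocorrelation peak", {
  fs <- 50000
  ck <- synth_click(click_model(n_pulses = 1, ipi_ms = 5), fs)
  cand <- stereopam:::ipi_from_autocorr(ck, fs, c(2, 10))
  expect_lt(cand$prominence, 3)
})

test_that("aliasing click models are rejected", {
  expect_error(synth_click(click_model(center_freq_hz = 20000,
                                       bandwidth_hz = 12000), 50000),
               "aliases")
})

test_that("arrival geometry: broadside, endfire, and sign change", {
  geom <- array_geometry()
  mk <- function(x, y, d = 25) {
    whale_sim(data.frame(time_s = c(0, 10), x_km = c(x, x), y_km = c(y, y),
                         depth_m = c(d, d)), ici_s = 2,
              active_windows = list(c(0, 9)))
  }
  # broadside: perpendicular to the axis (bearing 230 -> broadside 140)
  b <- 140 * pi / 180
  arr <- simulate_arrivals(mk(5 * sin(b), 5 * cos(b)), geom)
  expect_true(all(abs(arr$tdoa_s) < 1e-6))
  # endfire: along the axis, far field -> |tdoa| -> spacing/c
  a <- 50 * pi / 180
  arr2 <- simulate_arrivals(mk(20 * sin(a), 20 * cos(a)), geom)
  expect_equal(abs(arr2$tdoa_s), rep(max_tdoa(geom), nrow(arr2)),
               tolerance = 1e-3)
  # crossing broadside: sign changes monotonically
  cross <- whale_sim(data.frame(time_s = c(0, 60),
                                x_km = 3 * c(sin(b - 0.5), sin(b + 0.5)),
                                y_km = 3 * c(cos(b - 0.5), cos(b + 0.5)),
                                depth_m = c(25, 25)),
                     ici_s = 2, active_windows = list(c(0, 60)))
  arr3 <- simulate_arrivals(cross, geom)
  expect_true(all(diff(sign(arr3$tdoa_s)) <= 0) ||
                all(diff(sign(arr3$tdoa_s)) >= 0))
  expect_gt(abs(arr3$tdoa_s[1] - arr3$tdoa_s[nrow(arr3)]), 0)
})

test_that("every truth TDoA is physically bounded", {
  geom <- array_geometry()
  set.seed(42)
  for (i in 1:20) {
    w <- whale_sim(data.frame(time_s = c(0, 10),
                              x_km = runif(2, -30, 30),
                              y_km = runif(2, -30, 30),
                              depth_m = runif(2, 0, 1600)),
                   ici_s = 1, active_windows = list(c(0, 9)))
    arr <- simulate_arrivals(w, geom)
    expect_true(all(abs(arr$tdoa_s) <= max_tdoa(geom) + 1e-12))
  }
})

test_that("synthetic noise matches the Wenz octave model within 1 dB", {
  fs <- 50000
  x <- synth_noise(3, 12, fs, seed = 21)
  lev <- octave_levels(x, fs)
  pred <- vapply(octave_centers(), function(ct) wenz_level(3, ct),
                 numeric(1))
  expect_true(all(abs(lev$spl_db - pred) <= 1))
})

test_that("higher sea state raises the low-frequency bands", {
  fs <- 50000
  l2 <- octave_spl(synth_noise(2, 8, fs, seed = 1), fs, 200)
  l5 <- octave_spl(synth_noise(5, 8, fs, seed = 1), fs, 200)
  expect_gt(l5, l2)
})

test_that("ferry boost is recovered from the rendered noise", {
  fs <- 50000
  win <- list(c(0, 5))
  x3 <- synth_noise(2, 10, fs, ferry_windows = win, ferry_boost_db = 3,
                    seed = 9)
  inb <- octave_spl(x3[1:(5 * fs)], fs, 800)
  outb <- octave_spl(x3[(5 * fs + 1):(10 * fs)], fs, 800)
  expect_equal(inb - outb, 3, tolerance = 0.5)
  x0 <- synth_noise(2, 10, fs, ferry_windows = win, ferry_boost_db = 0,
                    seed = 9)
  expect_lt(abs(octave_spl(x0[1:(5 * fs)], fs, 800) -
                  octave_spl(x0[(5 * fs + 1):(10 * fs)], fs, 800)), 0.5)
})

test_that("render_scene bookkeeping and received levels", {
  geom <- array_geometry()
  # empty scene: pure noise, zero truth rows
  sc0 <- render_scene(list(), geom, duration_s = 2, sea_state = 2, seed = 3)
  expect_equal(nrow(sc0$truth_clicks), 0)
  expect_equal(ncol(sc0$wave), 2)
  # one whale, clicking every second for 10 s
  tr <- data.frame(time_s = c(0, 11), x_km = c(2, 2), y_km = c(1, 1),
                   depth_m = c(300, 300))
  wh <- whale_sim(tr, ici_s = 1, active_windows = list(c(0.2, 9.3)))
  sc <- render_scene(list(wh), geom, duration_s = 11, sea_state = 2,
                     seed = 4)
  expect_equal(nrow(sc$truth_clicks), 10)
  expect_equal(nrow(sc$wave), 11 * geom$sample_rate_hz)
})

test_that("received click level follows SL - TL within 1 dB", {
  geom <- array_geometry()
  mk <- function(r_km) {
    whale_sim(data.frame(time_s = c(0, 6), x_km = c(0, 0),
                         y_km = c(r_km, r_km), depth_m = c(25, 25)),
              ici_s = 2, model = click_model(source_level_db = 190),
              active_windows = list(c(1, 1.5)))
  }
  # silence: sea state 0 still has noise, so measure click RMS windows
  # directly against the truth RL on a quiet bed
  rl_meas <- vapply(c(2, 4), function(r) {
    sc <- render_scene(list(mk(r)), geom, duration_s = 6, sea_state = 0,
                       seed = 8)
    i <- round(sc$truth_clicks$t_east_s[1] * sc$fs)
    w <- round(0.001 * sc$fs)
    yb <- bandpass(sc$wave[, 1], 6000, 15000, sc$fs)
    pk <- i + which.max(abs(yb[i:(i + 200)])) - 1
    stereopam:::db(stereopam:::rms(yb[(pk - w):(pk + w)]))
  }, numeric(1))
  tl_diff <- transmission_loss(4000, 1.43) - transmission_loss(2000, 1.43)
  expect_equal(rl_meas[1] - rl_meas[2], tl_diff, tolerance = 1)
  # absolute level: within 1 dB of SL - TL (bandpass keeps ~the full click band)
  expect_equal(rl_meas[1], 190 - transmission_loss(2000 * sqrt(1 + 0), 1.43),
               tolerance = 1.5)
})

test_that("scene writes WAV + truth and reads back", {
  geom <- array_geometry()
  wavf <- tempfile(fileext = ".wav")
  csvf <- tempfile(fileext = ".csv")
  jf <- tempfile(fileext = ".json")
  tr <- data.frame(time_s = c(0, 2), x_km = c(1, 1), y_km = c(1, 1),
                   depth_m = c(100, 100))
  wh <- whale_sim(tr, ici_s = 1, active_windows = list(c(0.5, 1.6)))
  sc <- render_scene(list(wh), geom, duration_s = 2, sea_state = 2,
                     seed = 5, out_wav = wavf, out_truth_csv = csvf,
                     out_json = jf)
  wv <- read_wav(wavf)
  expect_equal(nrow(wv$data), nrow(sc$wave))
  expect_equal(wv$fs, sc$fs)
  truth <- read.csv(csvf)
  expect_equal(nrow(truth), nrow(sc$truth_clicks))
  meta <- jsonlite::read_json(jf)
  expect_equal(meta$full_scale_db, 170)
  unlink(c(wavf, csvf, jf))
})
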