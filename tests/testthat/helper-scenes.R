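# Shared fixture builders. Everything is generated in code at test time;
# heavier objects are memoised for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

FS <- 50000

# stationary single-whale scene, ~2 km NE of the array, high SNR
single_whale_scene <- function() memo("single_scene", {
  tr <- data.frame(time_s = c(0, 12), x_km = c(1.2, 1.2),
                   y_km = c(1.0, 1.0), depth_m = c(300, 300))
  wh <- whale_sim(tr, ici_s = 1,
                  model = click_model(ipi_ms = 4.5, source_level_db = 200),
                  active_windows = list(c(0.5, 11.5)), id = "w1")
  render_scene(list(wh), array_geometry(), duration_s = 12, sea_state = 2,
               seed = 101)
})

# clicks embedded in noise clips at a controlled SNR (2 ms / 6-15 kHz)
clips_at_snr <- function(n, ipi_ms, snr_db, seed, fs = FS,
                         win_s = 0.04) {
  set.seed(seed)
  n_clip <- round(win_s * fs)
  cm <- click_model(ipi_ms = ipi_ms, n_pulses = 4)
  ck <- synth_click(cm, fs)
  lapply(seq_len(n), function(i) {
    nz <- synth_noise(2, win_s + 0.01, fs)[1:n_clip]
    x <- numeric(n_clip)
    at <- round(n_clip / 4)
    x[at:(at + length(ck) - 1)] <- ck
    yb <- bandpass(x, 6000, 15000, fs)
    pk <- which.max(abs(yb)); half <- round(0.001 * fs)
    c_spl <- stereopam:::db(stereopam:::rms(
      yb[max(1, pk - half):min(length(yb), pk + half)]))
    n_spl <- stereopam:::db(stereopam:::rms(bandpass(nz, 6000, 15000, fs)))
    nz + x * 10^((n_spl + snr_db - c_spl) / 20)
  })
}

# small trained classifier, reused across classifier tests
small_classifier <- function() memo("small_model", {
  tr <- make_training_clips(c(sperm = 120, cetacean = 30, noise = 120),
                            fs = FS, snr_db = 20, seed = 31)
  train_classifier(tr$clips, tr$labels, FS, seed = 7, epochs = 20)
})
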