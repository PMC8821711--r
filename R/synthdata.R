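# Synthetic stereo hydrophone scenes with known click structure, geometry
# and noise, so every downstream stage (detection, TDoA tracking, IPI, noise
# calibration, density) has a ground-truth oracle.

#' Multipulse click model
#'
#' Sperm whale clicks are multipulse transients: the initial pulse bounces
#' between two acoustic mirrors in the head (bent-horn anatomy), producing
#' decaying replicas P0, P1, P2 ... separated by the inter-pulse interval
#' (IPI). Each pulse here is a Gaussian-windowed tone burst.
#'
#' @param n_pulses number of pulses (>= 1).
#' @param ipi_ms inter-pulse interval, ms; must exceed `pulse_dur_ms`.
#' @param pulse_decay_db attenuation per successive pulse, dB (>= 0).
#' @param center_freq_hz pulse centre frequency (Hz).
#' @param bandwidth_hz pulse bandwidth (Hz); sets the Gaussian envelope.
#' @param pulse_dur_ms nominal pulse duration, ms.
#' @param source_level_db on-axis source level, dB re 1 uPa RMS at 1 m
#'   (2 ms window convention).
#' @return object of class `click_model`.
#' @export
click_model <- function(n_pulses = 3, ipi_ms = 5, pulse_decay_db = 6,
                        center_freq_hz = 12000, bandwidth_hz = 6000,
                        pulse_dur_ms = 1, source_level_db = 200) {
  stopifnot(n_pulses >= 1, ipi_ms > pulse_dur_ms, pulse_decay_db >= 0,
            center_freq_hz > 0, bandwidth_hz > 0, pulse_dur_ms > 0)
  structure(list(n_pulses = as.integer(n_pulses), ipi_ms = ipi_ms,
                 pulse_decay_db = pulse_decay_db,
                 center_freq_hz = center_freq_hz,
                 bandwidth_hz = bandwidth_hz, pulse_dur_ms = pulse_dur_ms,
                 source_level_db = source_level_db),
            class = "click_model")
}

#' Two-hydrophone array geometry
#'
#' @param spacing_m hydrophone separation (m).
#' @param depth_m array depth (m).
#' @param axis_bearing_deg compass bearing of the array axis (degrees);
#'   channel 1 ("east") sits at the reciprocal-bearing end.
#' @param sample_rate_hz recording sample rate (Hz).
#' @param sound_speed_ms sound speed (m/s).
#' @return object of class `array_geometry`.
#' @export
array_geometry <- function(spacing_m = 1.83, depth_m = 25,
                           axis_bearing_deg = 230, sample_rate_hz = 50000,
                           sound_speed_ms = 1500) {
  stopifnot(spacing_m > 0, sample_rate_hz > 0, sound_speed_ms > 0)
  structure(list(spacing_m = spacing_m, depth_m = depth_m,
                 axis_bearing_deg = axis_bearing_deg,
                 sample_rate_hz = sample_rate_hz,
                 sound_speed_ms = sound_speed_ms),
            class = "array_geometry")
}

#' Maximum physically possible |TDoA| for a geometry
#' @param geom an [array_geometry()].
#' @return seconds.
#' @export
max_tdoa <- function(geom) geom$spacing_m / geom$sound_speed_ms

# hydrophone horizontal positions (m, east/north), channel order (east, west)
hydrophone_positions <- function(geom) {
  b <- (geom$axis_bearing_deg + 180) %% 360   # reciprocal end = channel 1
  u <- c(sin(b * pi / 180), cos(b * pi / 180))
  list(east = u * geom$spacing_m / 2, west = -u * geom$spacing_m / 2)
}

#' Scripted whale for scene synthesis
#'
#' @param track data.frame with columns `time_s`, `x_km` (east), `y_km`
#'   (north), `depth_m`; positions are interpolated linearly between rows.
#' @param ici_s inter-click interval (s), > 0; foraging sperm whales click
#'   regularly at roughly 0.5-2 s.
#' @param model a [click_model()].
#' @param active_windows list of `c(start, end)` second pairs during which
#'   the whale clicks; default the full track span.
#' @param id whale identifier.
#' @return object of class `whale_sim`.
#' @export
whale_sim <- function(track, ici_s = 1, model = click_model(),
                      active_windows = NULL, id = "w1") {
  stopifnot(is.data.frame(track),
            all(c("time_s", "x_km", "y_km", "depth_m") %in% names(track)),
            all(track$depth_m >= 0), ici_s > 0)
  if (is.null(active_windows)) {
    active_windows <- list(range(track$time_s))
  }
  structure(list(track = track, ici_s = ici_s, model = model,
                 active_windows = active_windows, id = id),
            class = "whale_sim")
}

whale_position <- function(whale, t) {
  tr <- whale$track
  cbind(x_km = stats::approx(tr$time_s, tr$x_km, t, rule = 2)$y,
        y_km = stats::approx(tr$time_s, tr$y_km, t, rule = 2)$y,
        depth_m = stats::approx(tr$time_s, tr$depth_m, t, rule = 2)$y)
}

#' Synthesise one multipulse click waveform
#'
#' Renders `n_pulses` Gaussian tone bursts at lags `k * ipi_ms`, each
#' attenuated by `k * pulse_decay_db`. Peak amplitude of the main pulse is
#' 1; scale externally for received level.
#'
#' @param model a [click_model()].
#' @param fs sample rate (Hz); must satisfy
#'   `fs >= 2 * (center_freq + bandwidth/2)` (no aliasing).
#' @return numeric waveform of duration `>= n_pulses * ipi_ms`.
#' @export
synth_click <- function(model, fs) {
  top <- model$center_freq_hz + model$bandwidth_hz / 2
  if (fs < 2 * top) {
    stop("sample rate ", fs, " Hz aliases a click extending to ", top, " Hz")
  }
  dur_s <- (model$n_pulses * model$ipi_ms + 2 * model$pulse_dur_ms) / 1000
  n <- ceiling(dur_s * fs)
  t <- (0:(n - 1)) / fs
  # Gaussian envelope: sigma from bandwidth (gaussian FT duality)
  sigma <- 1 / (2 * pi * model$bandwidth_hz / (2 * sqrt(2 * log(2))))
  sigma <- max(sigma, model$pulse_dur_ms / 1000 / 6)
  x <- numeric(n)
  for (k in 0:(model$n_pulses - 1)) {
    t0 <- (model$pulse_dur_ms + k * model$ipi_ms) / 1000
    amp <- 10^(-k * model$pulse_decay_db / 20)
    x <- x + amp * exp(-(t - t0)^2 / (2 * sigma^2)) *
      cos(2 * pi * model$center_freq_hz * (t - t0))
  }
  x / max(abs(x))
}

#' True per-click arrivals for a whale and a geometry
#'
#' Straight-ray propagation: each click reaches each hydrophone after
#' `slant_range / c`, and the true TDoA is the arrival-time difference
#' (positive when the east channel leads). Received level is
#' `SL + G - TL(r)` with an isotropic source by default.
#'
#' @param whale a [whale_sim()].
#' @param geom an [array_geometry()].
#' @param alpha_db_per_km absorption used in the transmission loss.
#' @param beam_model beam model for the source directivity (see
#'   [beam_gain()]); default isotropic.
#' @return data.frame of truth rows: `whale_id`, `t_emit_s`, `t_east_s`,
#'   `t_west_s`, `tdoa_s`, `range_east_m`, `range_west_m`, `rl_east_db`,
#'   `rl_west_db`.
#' @export
simulate_arrivals <- function(whale, geom, alpha_db_per_km = 1.43,
                              beam_model = "isotropic") {
  hp <- hydrophone_positions(geom)
  emits <- unlist(lapply(whale$active_windows, function(w) {
    if (w[2] <= w[1]) return(numeric(0))
    seq(w[1], w[2], by = whale$ici_s)
  }))
  if (length(emits) == 0) {
    return(data.frame(whale_id = character(0), t_emit_s = numeric(0),
                      t_east_s = numeric(0), t_west_s = numeric(0),
                      tdoa_s = numeric(0), range_east_m = numeric(0),
                      range_west_m = numeric(0), rl_east_db = numeric(0),
                      rl_west_db = numeric(0)))
  }
  pos <- whale_position(whale, emits)
  dz <- pos[, "depth_m"] - geom$depth_m
  r_e <- sqrt((pos[, "x_km"] * 1000 - hp$east[1])^2 +
                (pos[, "y_km"] * 1000 - hp$east[2])^2 + dz^2)
  r_w <- sqrt((pos[, "x_km"] * 1000 - hp$west[1])^2 +
                (pos[, "y_km"] * 1000 - hp$west[2])^2 + dz^2)
  sl <- whale$model$source_level_db
  g <- beam_gain(0, beam_model)      # on-axis by default (isotropic: 0 dB)
  data.frame(whale_id = whale$id, t_emit_s = emits,
             t_east_s = emits + r_e / geom$sound_speed_ms,
             t_west_s = emits + r_w / geom$sound_speed_ms,
             tdoa_s = (r_w - r_e) / geom$sound_speed_ms,
             range_east_m = r_e, range_west_m = r_w,
             rl_east_db = sl + g - transmission_loss(pmax(r_e, 1),
                                                     alpha_db_per_km),
             rl_west_db = sl + g - transmission_loss(pmax(r_w, 1),
                                                     alpha_db_per_km))
}

#' Wenz-shaped ambient noise with optional ferry boosts
#'
#' Gaussian noise spectrally shaped to the Wenz-type model for the given
#' continuous sea state (units: linear uPa, so octave levels of the output
#' match [wenz_level()]). Inside each ferry window, all bands are raised
#' by `ferry_boost_db`.
#'
#' @param sea_state continuous sea state.
#' @param duration_s duration (s), > 0.
#' @param fs sample rate (Hz).
#' @param ferry_windows list of `c(start, end)` second pairs.
#' @param ferry_boost_db broadband boost inside ferry windows (dB).
#' @param shipping shipping activity for the Wenz model.
#' @param seed optional RNG seed.
#' @return numeric vector, pressure in uPa.
#' @export
synth_noise <- function(sea_state, duration_s, fs, ferry_windows = NULL,
                        ferry_boost_db = 0, shipping = 0.5, seed = NULL) {
  stopifnot(duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration_s * fs)
  w <- stats::rnorm(n)
  nf <- 2^ceiling(log2(n))
  wf <- stats::fft(c(w, numeric(nf - n)))
  f <- c(0:(nf / 2), -(nf / 2 - 1):-1) * fs / nf
  psd <- wenz_psd(pmax(abs(f), 1), sea_state, shipping)   # dB re 1 uPa^2/Hz
  h <- sqrt(10^(psd / 10) * fs / 2)   # white noise PSD (1-sided) is 2/fs
  x <- Re(stats::fft(wf * h, inverse = TRUE)) / nf
  x <- x[1:n]
  if (!is.null(ferry_windows) && ferry_boost_db != 0) {
    gain <- 10^(ferry_boost_db / 20)
    t <- (0:(n - 1)) / fs
    for (wnd in ferry_windows) {
      sel <- t >= wnd[1] & t < wnd[2]
      x[sel] <- x[sel] * gain
    }
  }
  x
}

#' Render a full stereo scene with ground truth
#'
#' Sums every whale's clicks into a Wenz-noise bed at the geometrically
#' correct per-channel arrival times and received levels
#' (`SL + G - TL`), and optionally writes a 2-channel PCM WAV plus truth
#' tables. Click amplitudes are scaled so the RMS over a 2 ms window on
#' the main pulse equals the received level.
#'
#' @param whales list of [whale_sim()] objects (may be empty).
#' @param geom an [array_geometry()].
#' @param duration_s scene duration (s).
#' @param sea_state continuous sea state of the noise bed.
#' @param ferry_windows,ferry_boost_db see [synth_noise()].
#' @param alpha_db_per_km absorption for the transmission loss.
#' @param full_scale_db WAV full-scale convention, dB re 1 uPa (samples
#'   are `pressure_uPa / 10^(full_scale_db/20)`).
#' @param seed RNG seed for the noise bed.
#' @param out_wav,out_truth_csv,out_json optional output paths (2-channel
#'   WAV; truth clicks CSV; JSON scene descriptor).
#' @param bits WAV bit depth (16 or 24).
#' @return object of class `stereo_scene`: `wave` (n x 2 matrix, uPa),
#'   `fs`, `geom`, `truth_clicks`, `truth_whales`, `full_scale_db`.
#' @export
render_scene <- function(whales, geom = array_geometry(), duration_s = 10,
                         sea_state = 2, ferry_windows = NULL,
                         ferry_boost_db = 0, alpha_db_per_km = 1.43,
                         full_scale_db = 170, seed = NULL,
                         out_wav = NULL, out_truth_csv = NULL,
                         out_json = NULL, bits = 16) {
  fs <- geom$sample_rate_hz
  n <- ceiling(duration_s * fs)
  if (!is.null(seed)) set.seed(seed)
  ch_e <- synth_noise(sea_state, duration_s, fs, ferry_windows,
                      ferry_boost_db, seed = NULL)
  ch_w <- synth_noise(sea_state, duration_s, fs, ferry_windows,
                      ferry_boost_db, seed = NULL)
  truth <- list(); whale_rows <- list()
  for (wh in whales) {
    arr <- simulate_arrivals(wh, geom, alpha_db_per_km)
    arr <- arr[arr$t_east_s < duration_s & arr$t_west_s < duration_s, ]
    wav <- synth_click(wh$model, fs)
    # scale so RMS in the 2 ms window on the main pulse is 1 (0 dB)
    peak_i <- which.max(abs(wav))
    halfw <- round(0.001 * fs)
    wnd <- max(1, peak_i - halfw):min(length(wav), peak_i + halfw)
    wav <- wav / rms(wav[wnd])
    lead <- peak_i - 1    # samples before main-pulse peak
    if (nrow(arr) > 0) {
      for (i in seq_len(nrow(arr))) {
        for (side in c("east", "west")) {
          t_arr <- if (side == "east") arr$t_east_s[i] else arr$t_west_s[i]
          rl <- if (side == "east") arr$rl_east_db[i] else arr$rl_west_db[i]
          i0 <- round(t_arr * fs) - lead
          idx <- i0:(i0 + length(wav) - 1)
          keep <- idx >= 1 & idx <= n
          if (!any(keep)) next
          amp <- 10^(rl / 20)
          if (side == "east") {
            ch_e[idx[keep]] <- ch_e[idx[keep]] + amp * wav[keep]
          } else {
            ch_w[idx[keep]] <- ch_w[idx[keep]] + amp * wav[keep]
          }
        }
      }
    }
    truth[[wh$id]] <- arr
    size <- select_size(wh$model$ipi_ms)
    whale_rows[[wh$id]] <- data.frame(
      whale_id = wh$id, true_ipi_ms = wh$model$ipi_ms,
      true_size_m = as.numeric(size),
      size_branch = attr(size, "branch"),
      source_level_db = wh$model$source_level_db,
      stringsAsFactors = FALSE)
  }
  truth_clicks <- if (length(truth)) do.call(rbind, truth) else
    simulate_arrivals(whale_sim(data.frame(time_s = 0, x_km = 1, y_km = 1,
                                           depth_m = 100),
                                active_windows = list(c(0, -1))), geom)
  rownames(truth_clicks) <- NULL
  truth_whales <- if (length(whale_rows)) do.call(rbind, whale_rows) else
    data.frame(whale_id = character(0), true_ipi_ms = numeric(0),
               true_size_m = numeric(0), size_branch = character(0),
               source_level_db = numeric(0))
  rownames(truth_whales) <- NULL
  scene <- structure(list(wave = cbind(east = ch_e, west = ch_w), fs = fs,
                          geom = geom, truth_clicks = truth_clicks,
                          truth_whales = truth_whales,
                          full_scale_db = full_scale_db,
                          sea_state = sea_state,
                          ferry_windows = ferry_windows,
                          ferry_boost_db = ferry_boost_db),
                     class = "stereo_scene")
  if (!is.null(out_wav)) {
    write_wav(scene$wave / 10^(full_scale_db / 20), fs, out_wav, bits = bits)
  }
  if (!is.null(out_truth_csv)) {
    utils::write.csv(truth_clicks, out_truth_csv, row.names = FALSE)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(list(
      fs = fs, duration_s = duration_s, full_scale_db = full_scale_db,
      sea_state = sea_state, ferry_boost_db = ferry_boost_db,
      geometry = unclass(geom),
      whales = truth_whales), out_json, auto_unbox = TRUE, digits = NA)
  }
  scene
}
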