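# High-recall click detection: zero-phase bandpass around the click band,
# Teager-Kaiser energy, smoothed envelope against an adaptive
# median + k*MAD threshold, refractory-period peak picking, and the
# 2 ms / 6-15 kHz SPL conventions used for SNR.

default_detect_config <- function() {
  list(low_hz = 10000, high_hz = 15000,      # "centred at 12.5 kHz"
       order = 4,
       threshold_k = 8,                      # median + k * MAD
       refractory_ms = 20,
       smooth_ms = 0.5,
       context_s = 2,                        # adaptive-threshold block
       snr_band = c(6000, 15000),
       click_window_ms = 2,
       noise_window_ms = 200,
       noise_gap_ms = 50)
}

#' Detect click-like transients in a (stereo) recording
#'
#' Per channel: bandpass (10-15 kHz, 4th order, zero phase), Teager-Kaiser
#' energy, short moving-average envelope, adaptive threshold
#' `median + k * MAD` computed over `context_s` blocks, and refractory
#' peak picking. Tuned for recall: the permissive default threshold also
#' fires on other impulses (boats, other odontocetes); precision is the
#' classifier's job.
#'
#' @param wave numeric vector (mono) or samples x channels matrix.
#' @param fs sample rate (Hz).
#' @param config list of detector parameters; see
#'   `stereopam:::default_detect_config()` for fields and defaults.
#' @return data.frame of detection events: `time_s`, `channel` (1-based),
#'   `tk_peak`, `click_spl_db`, `noise_spl_db`, `snr_db`, `edge` (TRUE
#'   when the noise window was truncated by the file edge).
#' @export
detect_clicks <- function(wave, fs, config = list()) {
  cfg <- utils::modifyList(default_detect_config(), config)
  if (is.vector(wave)) wave <- matrix(wave, ncol = 1)
  out <- list()
  for (ch in seq_len(ncol(wave))) {
    x <- wave[, ch]
    if (all(x == 0)) next
    y <- bandpass(x, cfg$low_hz, cfg$high_hz, fs, cfg$order)
    env <- moving_average(teager_kaiser(y), max(3, round(cfg$smooth_ms * fs / 1000)))
    thr <- block_threshold(env, fs, cfg$context_s, cfg$threshold_k)
    peaks <- pick_peaks(env, thr, round(cfg$refractory_ms * fs / 1000))
    if (length(peaks) == 0) next
    yb <- bandpass(x, cfg$snr_band[1], cfg$snr_band[2], fs, cfg$order)
    rows <- lapply(peaks, function(i) {
      m <- measure_click(yb, i, fs, cfg)
      data.frame(time_s = (i - 1) / fs, channel = ch, tk_peak = env[i],
                 click_spl_db = m$click_spl_db,
                 noise_spl_db = m$noise_spl_db, snr_db = m$snr_db,
                 edge = m$edge)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  if (length(out) == 0) {
    return(data.frame(time_s = numeric(0), channel = integer(0),
                      tk_peak = numeric(0), click_spl_db = numeric(0),
                      noise_spl_db = numeric(0), snr_db = numeric(0),
                      edge = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$time_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# blockwise adaptive threshold: median + k * MAD per context block
block_threshold <- function(env, fs, context_s, k) {
  n <- length(env)
  bs <- max(1, round(context_s * fs))
  starts <- seq(1, n, by = bs)
  thr <- numeric(n)
  for (s in starts) {
    e <- min(n, s + bs - 1)
    seg <- env[s:e]
    thr[s:e] <- stats::median(seg) + k * stats::mad(seg)
  }
  thr
}

# runs above threshold -> run maxima -> enforce refractory separation,
# keeping the larger peak of any conflicting pair
pick_peaks <- function(env, thr, refractory) {
  above <- which(env > thr)
  if (length(above) == 0) return(integer(0))
  run_id <- cumsum(c(1, diff(above) > 1))
  peaks <- vapply(split(above, run_id),
                  function(ix) ix[which.max(env[ix])], integer(1))
  peaks <- sort(peaks)
  kept <- integer(0)
  for (p in peaks) {
    if (length(kept) && p - kept[length(kept)] < refractory) {
      if (env[p] > env[kept[length(kept)]]) kept[length(kept)] <- p
    } else kept <- c(kept, p)
  }
  kept
}

# click SPL (2 ms window) and local noise SPL (200 ms ending 50 ms before)
# on an already 6-15 kHz filtered signal
measure_click <- function(yb, i, fs, cfg) {
  n <- length(yb)
  half <- round(cfg$click_window_ms / 2 * fs / 1000)
  cw <- max(1, i - half):min(n, i + half)
  gap <- round(cfg$noise_gap_ms * fs / 1000)
  nw_len <- round(cfg$noise_window_ms * fs / 1000)
  nw_end <- i - half - gap
  nw_start <- nw_end - nw_len + 1
  edge <- nw_start < 1 || (i - half) < 1 || (i + half) > n
  if (nw_end < 1) {   # fall back to a window after the click
    nw_start <- min(n, i + half + gap)
    nw_end <- min(n, nw_start + nw_len - 1)
  }
  nw <- max(1, nw_start):max(1, nw_end)
  click_spl <- db(rms(yb[cw]))
  noise_spl <- db(rms(yb[nw]))
  list(click_spl_db = click_spl, noise_spl_db = noise_spl,
       snr_db = click_spl - noise_spl, edge = edge)
}

#' SNR of a click at a known time
#'
#' Click level is the RMS over a 2 ms window (6-15 kHz band) centred on
#' the event; noise level is the RMS of a 200 ms window of the same band
#' ending 50 ms before the click.
#'
#' @param signal single-channel numeric vector (unfiltered).
#' @param time_s event time (s from file start).
#' @param fs sample rate (Hz).
#' @param config optional overrides of the detector conventions.
#' @return list `snr_db`, `click_spl_db`, `noise_spl_db`, `edge`.
#' @export
click_snr <- function(signal, time_s, fs, config = list()) {
  cfg <- utils::modifyList(default_detect_config(), config)
  i <- round(time_s * fs) + 1
  if (i < 1 || i > length(signal)) stop("event outside the file")
  yb <- bandpass(signal, cfg$snr_band[1], cfg$snr_band[2], fs, cfg$order)
  measure_click(yb, i, fs, cfg)
}

#' Match detections to truth click times
#'
#' Greedy one-to-one matching within a tolerance; used to score recall
#' against a synthetic scene's ground truth.
#'
#' @param detected_s detected event times (s).
#' @param truth_s true arrival times (s).
#' @param tol_s matching tolerance (s), default 2 ms.
#' @return list `recall`, `n_matched`, `matched` (logical per truth row).
#' @export
match_detections <- function(detected_s, truth_s, tol_s = 2e-3) {
  matched <- logical(length(truth_s))
  avail <- rep(TRUE, length(detected_s))
  for (i in seq_along(truth_s)) {
    d <- abs(detected_s - truth_s[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      matched[i] <- TRUE
      avail[j] <- FALSE
    }
  }
  list(recall = if (length(truth_s)) mean(matched) else NA_real_,
       n_matched = sum(matched), matched = matched)
}
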