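# ---- Butterworth bandpass design (second-order sections) --------------------
# No DSP package ships with the analysis environment, so the filter design is
# first-party: analog Butterworth prototype -> analog bandpass transform ->
# bilinear transform -> conjugate-paired biquads, each normalised to unit
# gain at the (warped) band centre.

#' Design a Butterworth bandpass filter as second-order sections
#'
#' @param order prototype order `n`; the bandpass filter has `2n` poles.
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sample rate in Hz.
#' @return matrix with one row per biquad: columns `b0 b1 b2 a0 a1 a2`
#'   (`a0 = 1`).
#' @export
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("invalid band: need 0 < low < high < fs/2")
  }
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  poles <- complex(0)
  for (p in p_proto) {
    t <- p * bw / 2
    s <- sqrt(t^2 - w0^2)
    poles <- c(poles, t + s, t - s)
  }
  zd <- (fs2 + poles) / (fs2 - poles)              # bilinear transform
  # pair each pole (Im >= 0) with its conjugate
  pos <- zd[Im(zd) > 1e-12]
  re <- sort(Re(zd[abs(Im(zd)) <= 1e-12]))
  sections <- list()
  for (p in pos) sections[[length(sections) + 1]] <- c(p, Conj(p))
  if (length(re) >= 2) {
    for (i in seq(1, length(re) - 1, by = 2)) {
      sections[[length(sections) + 1]] <- c(re[i], re[i + 1])
    }
  }
  # warped digital centre frequency for per-section gain normalisation
  wc <- 2 * atan(w0 / fs2)
  z0 <- exp(1i * wc)
  sos <- matrix(0, nrow = length(sections), ncol = 6)
  for (i in seq_along(sections)) {
    pp <- sections[[i]]
    a1 <- -Re(pp[1] + pp[2])
    a2 <- Re(pp[1] * pp[2])
    h <- (z0^2 - 1) / (z0^2 + a1 * z0 + a2)        # zeros at z = +1, -1
    g <- 1 / Mod(h)
    sos[i, ] <- c(g, 0, -g, 1, a1, a2)
  }
  sos
}

sos_filter_once <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    n <- length(x)
    ma <- b[1] * x
    if (n >= 2) ma[2:n] <- ma[2:n] + b[2] * x[1:(n - 1)]
    if (n >= 3) ma[3:n] <- ma[3:n] + b[3] * x[1:(n - 2)]
    x <- as.numeric(stats::filter(ma, -a[2:3], method = "recursive"))
  }
  x
}

#' Zero-phase filtering with a second-order-section filter
#'
#' Forward-backward application with odd-reflection edge padding, so the
#' output has no group delay (clicks stay where they are).
#'
#' @param sos matrix from [butter_bandpass_sos()].
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1, 9 * nrow(sos) + 3)
  if (pad > 0) {
    pre <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- sos_filter_once(sos, xe)
  y <- rev(sos_filter_once(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' @inheritParams butter_bandpass_sos
#' @param x signal vector.
#' @param order filter order (default 4, forward-backward doubles it).
#' @return filtered signal, same length.
#' @export
bandpass <- function(x, low_hz, high_hz, fs, order = 4) {
  if (all(x == 0)) return(x)
  sos <- butter_bandpass_sos(order, low_hz, high_hz, fs)
  sos_filtfilt(sos, x)
}

# ---- Teager-Kaiser ----------------------------------------------------------

#' Teager-Kaiser energy operator
#'
#' `psi[n] = x[n]^2 - x[n-1] * x[n+1]`, endpoints padded by repetition.
#' Emphasises impulsive energy; exactly zero on constant inputs.
#'
#' @param x numeric vector, length >= 3.
#' @return energy sequence, same length as `x`.
#' @export
teager_kaiser <- function(x) {
  n <- length(x)
  if (n < 3) stop("teager_kaiser needs length >= 3")
  xm <- c(x[1], x[1:(n - 1)])
  xp <- c(x[2:n], x[n])
  x^2 - xm * xp
}

# ---- spectra ----------------------------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Short-time power spectrum
#'
#' Hann-windowed frames, magnitude-squared one-sided FFT.
#'
#' @param x signal vector.
#' @param fs sample rate (Hz).
#' @param n_fft FFT size (frame length).
#' @param hop hop size in samples.
#' @return list with `power` ((n_fft/2+1) x frames), `freq_hz`, `time_s`.
#' @export
stft_power <- function(x, fs, n_fft = 1024, hop = n_fft %/% 2) {
  n <- length(x)
  if (n < n_fft) x <- c(x, numeric(n_fft - n))
  n <- length(x)
  n_frames <- 1 + (n - n_fft) %/% hop
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1) * hop, "+")
  frames <- matrix(x[idx], nrow = n_fft) * hann_window(n_fft)
  spec <- stats::mvfft(frames)
  half <- n_fft %/% 2 + 1
  p <- Mod(spec[1:half, , drop = FALSE])^2
  list(power = p,
       freq_hz = (0:(half - 1)) * fs / n_fft,
       time_s = ((seq_len(n_frames) - 1) * hop + n_fft / 2) / fs)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters on the mel scale, spanning `f_lo`..`f_hi`.
#'
#' @param n_mels number of mel bands.
#' @param n_fft FFT size the filterbank applies to.
#' @param fs sample rate.
#' @param f_lo,f_hi frequency span in Hz.
#' @return `n_mels` x `(n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, fs, f_lo = 0, f_hi = fs / 2) {
  half <- n_fft %/% 2 + 1
  freqs <- (0:(half - 1)) * fs / n_fft
  mels <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_mels + 2)
  edges <- mel_to_hz(mels)
  fb <- matrix(0, n_mels, half)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Real cepstrum
#'
#' Inverse FFT of the log magnitude spectrum. The quefrency (in seconds) of
#' a cepstral peak locates a periodicity in the spectrum, e.g. the
#' inter-pulse interval of a multipulse click.
#'
#' @param x signal vector.
#' @param fs sample rate.
#' @return list with `cep` (real cepstrum, same length) and `quefrency_s`.
#' @export
real_cepstrum <- function(x, fs) {
  n <- length(x)
  spec <- stats::fft(x)
  logmag <- log(pmax(Mod(spec), 1e-12))
  cep <- Re(stats::fft(logmag, inverse = TRUE)) / n
  list(cep = cep, quefrency_s = (0:(n - 1)) / fs)
}

#' Cross-correlation lag between two signals
#'
#' FFT cross-correlation restricted to `|lag| <= max_lag` samples; returns
#' the lag of the maximum and the normalised peak value. Positive lag means
#' `y` is delayed relative to `x`.
#'
#' @param x,y equal-length numeric vectors.
#' @param max_lag maximum |lag| in samples.
#' @return list `lag` (samples, signed), `peak` (normalised correlation).
#' @export
xcorr_peak <- function(x, y, max_lag) {
  n <- length(x)
  stopifnot(length(y) == n)
  nf <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nf - n)))
  Y <- stats::fft(c(y, numeric(nf - n)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / nf
  # cc[1] is lag 0; cc[k+1] lag k (y delayed by -k?); build symmetric lag axis
  lags <- c(0:(nf / 2 - 1), -(nf / 2):-1)
  keep <- abs(lags) <= max_lag
  cc_k <- cc[keep]; lag_k <- lags[keep]
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(list(lag = 0L, peak = 0))
  i <- which.max(cc_k)
  # positive correlation at lag L means y[t] ~ x[t - L] => y delayed by L
  list(lag = -lag_k[i], peak = cc_k[i] / denom)
}

rms <- function(x) sqrt(mean(x^2))

db <- function(x) 20 * log10(pmax(x, 1e-300))

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2)) -> y
  y[is.na(y)] <- x[is.na(y)]
  y
}
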