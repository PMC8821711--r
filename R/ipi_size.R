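# Inter-pulse interval estimation and body size conversion. The IPI of a
# sperm whale click (delay between successive intra-click pulses) scales
# with the length of the spermaceti organ and hence the animal: two
# published photogrammetric regressions convert IPI (ms) to animal size (m),
# one calibrated on juveniles (used below 4 ms) and one on large adults
# (used at and above 4 ms).

#' Real cepstrum of a click window
#'
#' Thin wrapper of [real_cepstrum()] returning the quefrency axis in ms;
#' the dominant cepstral peak inside the IPI search band is the per-click
#' IPI candidate.
#'
#' @param click numeric waveform of one click (window should cover at
#'   least twice the maximum IPI searched).
#' @param fs sample rate (Hz).
#' @return data.frame `quefrency_ms`, `cep`.
#' @export
cepstrum <- function(click, fs) {
  cp <- real_cepstrum(click, fs)
  half <- seq_len(floor(length(click) / 2))
  data.frame(quefrency_ms = cp$quefrency_s[half] * 1000, cep = cp$cep[half])
}

# peak of a curve restricted to a quefrency/lag band, with a prominence
# score relative to the in-band median absolute level. Maxima hugging the
# band edge are rejected: a smoothly decaying curve (single-pulse click,
# lag-zero noise lobe) has its in-band maximum at the edge, not a peak.
band_peak <- function(value, axis_ms, band_ms, edge_guard_ms = 0.3) {
  sel <- axis_ms >= band_ms[1] & axis_ms <= band_ms[2]
  if (!any(sel)) return(list(ms = NA_real_, prominence = 0))
  v <- value[sel]; a <- axis_ms[sel]
  i <- which.max(v)
  if (a[i] < band_ms[1] + edge_guard_ms || a[i] > band_ms[2] - edge_guard_ms) {
    return(list(ms = a[i], prominence = 0))
  }
  base <- stats::median(abs(v))
  spread <- stats::mad(v)
  prom <- if (spread > 0) (v[i] - base) / spread else 0
  list(ms = a[i], prominence = prom)
}

# per-click IPI candidate from the cepstrum
ipi_from_cepstrum <- function(click, fs, band_ms = c(2, 10)) {
  cp <- cepstrum(click, fs)
  band_peak(cp$cep, cp$quefrency_ms, band_ms)
}

# per-click IPI candidate from the autocorrelation view: bandpassed signal
# windowed around the main pulse, envelope of its autocorrelation. Pulse
# replicas are coherent copies, so the ACF envelope peaks at the IPI lag
# while noise only contributes near lag zero.
ipi_from_autocorr <- function(click, fs, band_ms = c(2, 10)) {
  y <- bandpass(click, 5000, 18000, fs)
  pk <- which.max(abs(y))
  lo <- max(1, pk - round(0.003 * fs))
  hi <- min(length(y), pk + round(1.5 * band_ms[2] * fs / 1000))
  y <- y[lo:hi]
  n <- length(y)
  nf <- 2^ceiling(log2(2 * n))
  sp <- stats::fft(c(y, numeric(nf - n)))
  ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:n] / nf
  env <- moving_average(abs(ac), max(3, round(0.2e-3 * fs)))
  lags_ms <- (0:(n - 1)) / fs * 1000
  band_peak(env, lags_ms, band_ms)
}

#' Estimate the inter-pulse interval from a set of clicks
#'
#' Each click yields two candidates (cepstrum and envelope
#' autocorrelation); a click is kept when the two agree within
#' `agree_tol_ms`. The track-level consensus is a 20%-trimmed mean over
#' the kept per-click values. Estimation is refused for passages with
#' more than 2 simultaneous individuals, where click trains interleave and
#' per-animal IPIs cannot be attributed.
#'
#' @param clicks list of click waveforms (numeric vectors).
#' @param fs sample rate (Hz).
#' @param method `"consensus"` (default), `"cepstrum"`, or
#'   `"autocorrelation"`.
#' @param search_band_ms IPI search band, ms (default 2-10, spanning the
#'   observable 7-15.5 m size range through both regressions).
#' @param n_individuals number of simultaneous animals on the track(s)
#'   the clicks come from; > 2 is refused.
#' @param agree_tol_ms cepstrum/autocorrelation agreement tolerance.
#' @param min_prominence peak prominence (MAD units) below which a
#'   candidate is ignored.
#' @return object of class `ipi_estimate`: `ipi_ms`, `method`, `size_m`,
#'   `size_branch`, `size_class`, `n_clicks`, `n_used`, `reliable`,
#'   `disagreement_ms`.
#' @export
estimate_ipi <- function(clicks, fs, method = c("consensus", "cepstrum",
                                                "autocorrelation"),
                         search_band_ms = c(2, 10), n_individuals = 1,
                         agree_tol_ms = 0.5, min_prominence = 3) {
  method <- match.arg(method)
  if (n_individuals > 2) {
    stop("IPI estimation is refused for passages with more than 2 ",
         "individuals (interleaved click trains)")
  }
  if (length(clicks) < 1) stop("need at least one click")
  cand <- t(vapply(clicks, function(ck) {
    ce <- ipi_from_cepstrum(ck, fs, search_band_ms)
    ac <- ipi_from_autocorr(ck, fs, search_band_ms)
    c(ce$ms, ce$prominence, ac$ms, ac$prominence)
  }, numeric(4)))
  colnames(cand) <- c("cep_ms", "cep_prom", "acf_ms", "acf_prom")
  per_click <- switch(method,
    cepstrum = ifelse(cand[, "cep_prom"] >= min_prominence,
                      cand[, "cep_ms"], NA_real_),
    autocorrelation = ifelse(cand[, "acf_prom"] >= min_prominence,
                             cand[, "acf_ms"], NA_real_),
    consensus = {
      ok <- cand[, "cep_prom"] >= min_prominence &
        cand[, "acf_prom"] >= min_prominence &
        abs(cand[, "cep_ms"] - cand[, "acf_ms"]) <= agree_tol_ms
      ifelse(ok, (cand[, "cep_ms"] + cand[, "acf_ms"]) / 2, NA_real_)
    })
  used <- per_click[!is.na(per_click)]
  disagreement <- stats::median(abs(cand[, "cep_ms"] - cand[, "acf_ms"]),
                                na.rm = TRUE)
  reliable <- length(used) >= max(1, length(clicks) * 0.25) &&
    (method != "consensus" || disagreement <= agree_tol_ms)
  ipi <- if (length(used)) mean(used, trim = 0.2) else NA_real_
  size <- if (is.na(ipi)) NA_real_ else select_size(ipi)
  structure(list(ipi_ms = ipi, method = method,
                 size_m = as.numeric(size),
                 size_branch = if (is.na(ipi)) NA_character_ else
                   attr(size, "branch"),
                 size_class = if (is.na(ipi)) NA_character_ else
                   size_class(as.numeric(size)),
                 n_clicks = length(clicks), n_used = length(used),
                 reliable = reliable, disagreement_ms = disagreement),
            class = "ipi_estimate")
}

#' Juvenile-calibrated IPI-to-size regression
#'
#' `AS = 4.833 + 1.453 * IPI - 0.001 * IPI^2` (size in m, IPI in ms);
#' calibrated on animals under ~11 m.
#'
#' @param ipi_ms inter-pulse interval, ms (> 0 for physical use; the
#'   function evaluates the polynomial for any `ipi_ms >= 0`).
#' @return animal size in metres.
#' @export
gordon_size <- function(ipi_ms) {
  4.833 + 1.453 * ipi_ms - 0.001 * ipi_ms^2
}

#' Adult-calibrated IPI-to-size regression
#'
#' `AS = 1.258 * IPI + 5.736` (size in m, IPI in ms); calibrated on
#' animals over ~11 m.
#'
#' @inheritParams gordon_size
#' @return animal size in metres.
#' @export
growcott_size <- function(ipi_ms) {
  1.258 * ipi_ms + 5.736
}

#' Branch-selected IPI-to-size conversion
#'
#' Uses the juvenile regression ([gordon_size()]) for IPI below 4 ms and
#' the adult regression ([growcott_size()]) at and above 4 ms (the
#' boundary value is assigned to the adult branch; the published strict
#' inequalities leave exactly 4 ms undefined).
#'
#' @inheritParams gordon_size
#' @return size in metres, with attribute `branch` = `"gordon"` or
#'   `"growcott"`.
#' @export
select_size <- function(ipi_ms) {
  stopifnot(length(ipi_ms) == 1, ipi_ms > 0)
  if (ipi_ms < 4) {
    structure(gordon_size(ipi_ms), branch = "gordon")
  } else {
    structure(growcott_size(ipi_ms), branch = "growcott")
  }
}

#' Demographic size class from body length
#'
#' `< 9` m: immature male or female; `9-12` m: adult female or juvenile
#' male; `>= 12` m: adult male. Boundary values are assigned upward.
#'
#' @param size_m body length (m), > 0.
#' @return one of `"immature"`, `"adult_female_or_juvenile_male"`,
#'   `"adult_male"`.
#' @export
size_class <- function(size_m) {
  stopifnot(all(size_m > 0))
  ifelse(size_m < 9, "immature",
         ifelse(size_m < 12, "adult_female_or_juvenile_male", "adult_male"))
}

#' Invert the branch-selected size rule
#'
#' Finds the IPI whose branch-selected size equals `size_m`; used to
#' script synthetic whales of known size.
#'
#' @param size_m target body length (m).
#' @return IPI in ms.
#' @export
ipi_for_size <- function(size_m) {
  g4 <- gordon_size(4)      # 10.629 m: top of the juvenile branch
  gr4 <- growcott_size(4)   # 10.768 m: bottom of the adult branch
  if (size_m <= gordon_size(0)) stop("size below the model's range")
  if (size_m < g4) {
    stats::uniroot(function(i) gordon_size(i) - size_m, c(1e-9, 4),
                   tol = 1e-12)$root
  } else if (size_m >= gr4) {
    (size_m - 5.736) / 1.258
  } else {
    4  # sizes inside the branch discontinuity map to the boundary
  }
}
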