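# From per-click inter-channel delays to tracks, passages, and counts of
# simultaneous individuals - the stereo contribution of the pipeline. A
# moving whale traces a smooth TDoA-versus-time curve; clustering those
# curves separates individuals, and >= 1 h of silence separates passages.

#' TDoA of one detected click
#'
#' Lag of the cross-correlation maximum between the two channels over a
#' short window around the event, restricted to the physically possible
#' `|lag| <= max_lag`. Positive TDoA means the east channel (column 1)
#' leads.
#'
#' @param wave samples x 2 matrix (east, west).
#' @param time_s event time (s).
#' @param fs sample rate (Hz).
#' @param max_lag_s lag bound in seconds (default `spacing / c` at the
#'   default geometry, 1.83/1500).
#' @param window_ms correlation window length (ms).
#' @param min_peak normalised correlation floor below which the point is
#'   flagged low-confidence.
#' @return list `time_s`, `tdoa_s`, `correlation_peak`, `low_confidence`.
#' @export
tdoa_of_click <- function(wave, time_s, fs, max_lag_s = 1.83 / 1500,
                          window_ms = 20, min_peak = 0.1) {
  stopifnot(ncol(wave) == 2)
  max_lag <- ceiling(max_lag_s * fs)
  half <- round(window_ms / 2 * fs / 1000)
  i <- round(time_s * fs) + 1
  lo <- max(1, i - half)
  hi <- min(nrow(wave), i + half)
  x <- wave[lo:hi, 1]
  y <- wave[lo:hi, 2]
  r <- xcorr_peak(x, y, max_lag)
  list(time_s = time_s, tdoa_s = r$lag / fs, correlation_peak = r$peak,
       low_confidence = r$peak < min_peak)
}

#' TDoAs for a table of detection events
#'
#' @param wave samples x 2 matrix.
#' @param events data.frame with a `time_s` column (one row per click;
#'   events from both channels may be passed, duplicates within
#'   `max_lag_s` are collapsed to one TDoA point).
#' @inheritParams tdoa_of_click
#' @return data.frame `time_s`, `tdoa_s`, `correlation_peak`,
#'   `low_confidence`.
#' @export
tdoa_of_events <- function(wave, events, fs, max_lag_s = 1.83 / 1500,
                           window_ms = 20, min_peak = 0.1) {
  t <- sort(unique(events$time_s))
  if (length(t) > 1) {     # collapse cross-channel duplicates of one click
    keep <- c(TRUE, diff(t) > max_lag_s)
    t <- t[keep]
  }
  rows <- lapply(t, function(ti)
    as.data.frame(tdoa_of_click(wave, ti, fs, max_lag_s, window_ms,
                                min_peak)))
  if (!length(rows)) {
    return(data.frame(time_s = numeric(0), tdoa_s = numeric(0),
                      correlation_peak = numeric(0),
                      low_confidence = logical(0)))
  }
  do.call(rbind, rows)
}

default_track_config <- function() {
  list(max_gap_s = 120,          # max silence inside one track
       max_rate_s_per_s = 1e-4,  # max TDoA drift, 0.1 ms per second
       base_jitter_s = 1e-4,     # measurement jitter allowance
       min_points = 20,
       min_duration_s = 300,
       min_rate_hz = 0.2)        # min click density (foraging ICI ~0.5-2 s)
}

#' Cluster TDoA points into per-individual tracks
#'
#' Greedy nearest-neighbour chaining in (time, TDoA): a point joins the
#' open track whose last point is within `max_gap_s` and whose TDoA is
#' within `base_jitter_s + max_rate_s_per_s * dt`; otherwise it opens a
#' new track. Short or sparse chains (below `min_points` points,
#' `min_duration_s` duration, or `min_rate_hz` click density - regular
#' foraging click trains run at roughly 0.5-2 clicks/s) are discarded as
#' false-alarm scatter.
#'
#' @param points data.frame `time_s`, `tdoa_s` (time-ordered; a
#'   `low_confidence` column, if present, is dropped first).
#' @param config list of clustering parameters, see
#'   `stereopam:::default_track_config()`.
#' @return list with `points` (input rows plus `track_id`, 0 = unassigned
#'   or discarded) and `tracks` (data.frame `track_id`, `start_s`,
#'   `end_s`, `n_points`, `duration_s`, `mean_tdoa_s`).
#' @export
build_tracks <- function(points, config = list()) {
  cfg <- utils::modifyList(default_track_config(), config)
  if ("low_confidence" %in% names(points)) {
    points <- points[!points$low_confidence, , drop = FALSE]
  }
  points <- points[order(points$time_s), , drop = FALSE]
  n <- nrow(points)
  id <- integer(n)
  last_t <- numeric(0); last_d <- numeric(0)  # open-track state
  for (i in seq_len(n)) {
    t <- points$time_s[i]; d <- points$tdoa_s[i]
    best <- 0L; best_dev <- Inf
    for (k in seq_along(last_t)) {
      dt <- t - last_t[k]
      if (dt > cfg$max_gap_s) next
      tol <- cfg$base_jitter_s + cfg$max_rate_s_per_s * max(dt, 0)
      dev <- abs(d - last_d[k])
      if (dev <= tol && dev < best_dev) { best <- k; best_dev <- dev }
    }
    if (best == 0L) {
      last_t <- c(last_t, t); last_d <- c(last_d, d)
      id[i] <- length(last_t)
    } else {
      last_t[best] <- t; last_d[best] <- d
      id[i] <- best
    }
  }
  points$track_id <- id
  keep <- integer(0)
  tracks <- list()
  for (k in sort(unique(id))) {
    sel <- id == k
    dur <- diff(range(points$time_s[sel]))
    rate <- if (dur > 0) sum(sel) / dur else Inf
    if (sum(sel) >= cfg$min_points && dur >= cfg$min_duration_s &&
        rate >= cfg$min_rate_hz) {
      keep <- c(keep, k)
      tracks[[length(tracks) + 1]] <- data.frame(
        track_id = length(tracks) + 1L,
        start_s = min(points$time_s[sel]),
        end_s = max(points$time_s[sel]),
        n_points = sum(sel), duration_s = dur,
        mean_tdoa_s = mean(points$tdoa_s[sel]))
    }
  }
  relabel <- stats::setNames(rep(0L, max(id, 1)), seq_len(max(id, 1)))
  relabel[as.character(keep)] <- seq_along(keep)
  points$track_id <- ifelse(id == 0, 0L, relabel[as.character(id)])
  list(points = points,
       tracks = if (length(tracks)) do.call(rbind, tracks) else
         data.frame(track_id = integer(0), start_s = numeric(0),
                    end_s = numeric(0), n_points = integer(0),
                    duration_s = numeric(0), mean_tdoa_s = numeric(0)))
}

#' Group tracks into passages
#'
#' Tracks separated by less than `gap_s` of silence belong to one
#' passage; a gap of `gap_s` or more (strictly "at least 1 h" at the
#' default) starts a new one.
#'
#' @param tracks data.frame with `start_s`, `end_s` (one row per track).
#' @param gap_s silence threshold (s), default 3600.
#' @return data.frame `passage_id`, `start_s`, `end_s`, `duration_s`,
#'   `n_tracks`, `n_individuals` (max simultaneous tracks).
#' @export
segment_passages <- function(tracks, gap_s = 3600) {
  if (nrow(tracks) == 0) {
    return(data.frame(passage_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_tracks = integer(0), n_individuals = integer(0)))
  }
  tracks <- tracks[order(tracks$start_s), , drop = FALSE]
  pid <- integer(nrow(tracks))
  pid[1] <- 1L
  cur_end <- tracks$end_s[1]
  for (i in seq_len(nrow(tracks))[-1]) {
    if (tracks$start_s[i] - cur_end < gap_s) {
      pid[i] <- pid[i - 1]
    } else {
      pid[i] <- pid[i - 1] + 1L
    }
    cur_end <- max(cur_end, tracks$end_s[i])
  }
  out <- lapply(split(tracks, pid), function(d) {
    data.frame(start_s = min(d$start_s), end_s = max(d$end_s),
               duration_s = max(d$end_s) - min(d$start_s),
               n_tracks = nrow(d),
               n_individuals = count_individuals(d))
  })
  res <- do.call(rbind, out)
  res <- cbind(passage_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Maximum number of simultaneous tracks in a passage
#'
#' Sweep-line maximum overlap of the track time intervals: the number of
#' individuals credited to the passage.
#'
#' @param tracks data.frame with `start_s`, `end_s` (non-empty).
#' @return integer count, >= 1.
#' @export
count_individuals <- function(tracks) {
  if (nrow(tracks) == 0) stop("passage has no tracks")
  ev <- rbind(data.frame(t = tracks$start_s, d = 1),
              data.frame(t = tracks$end_s, d = -1))
  ev <- ev[order(ev$t, -ev$d), ]   # starts before ends at ties (closed intervals)
  max(cumsum(ev$d))
}
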