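# Orchestration: clip factories for classifier training, bundled scene
# fixtures, the end-to-end pipeline runner with a manifest, and YAML
# configuration.

#' Generate labelled training clips
#'
#' Synthetic clips for classifier training/evaluation: sperm whale
#' multipulse clicks in Wenz noise (label `"sperm"`), generic transient
#' distractors - single narrowband bursts, e.g. other odontocetes or
#' echosounders (label `"cetacean"`) - and plain noise (label
#' `"noise"`).
#'
#' @param n_per_class named integer vector, clips per class.
#' @param fs sample rate (Hz).
#' @param snr_db click SNR (2 ms / 6-15 kHz convention), recycled.
#' @param sea_state noise bed sea state.
#' @param seed RNG seed.
#' @param ipi_range_ms range of true IPIs sampled for click clips.
#' @return list with `clips` (list of waveforms), `labels`, `ipi_ms`
#'   (true IPI per clip, NA for non-click classes).
#' @export
make_training_clips <- function(n_per_class = c(sperm = 100, cetacean = 30,
                                                noise = 100),
                                fs = 50000, snr_db = 20, sea_state = 2,
                                seed = 1, ipi_range_ms = c(3, 8)) {
  set.seed(seed)
  cfg <- default_feature_config(fs)
  n_clip <- round(cfg$clip_ms * fs / 1000)
  clips <- list(); labels <- character(0); ipis <- numeric(0)
  noise_clip <- function() {
    synth_noise(sea_state, cfg$clip_ms / 1000 + 0.01, fs)[1:n_clip]
  }
  scale_to_snr <- function(burst, nz, snr) {
    yb <- bandpass(burst, 6000, 15000, fs)
    i <- which.max(abs(yb)); half <- round(0.001 * fs)
    c_spl <- db(rms(yb[max(1, i - half):min(length(yb), i + half)]))
    n_spl <- db(rms(bandpass(nz, 6000, 15000, fs)))
    burst * 10^((n_spl + snr - c_spl) / 20)
  }
  snrs <- rep(snr_db, length.out = sum(n_per_class))
  k <- 0
  for (i in seq_len(n_per_class["sperm"])) {
    k <- k + 1
    ipi <- stats::runif(1, ipi_range_ms[1], ipi_range_ms[2])
    cm <- click_model(n_pulses = sample(3:5, 1), ipi_ms = ipi,
                      pulse_decay_db = stats::runif(1, 4, 8))
    ck <- synth_click(cm, fs)
    nz <- noise_clip()
    x <- numeric(n_clip)
    at <- round(n_clip / 2 - length(ck) / 2) + sample(-200:200, 1)
    x[at:(at + length(ck) - 1)] <- ck
    clips[[k]] <- nz + scale_to_snr(x, nz, snrs[k])
    labels <- c(labels, "sperm"); ipis <- c(ipis, ipi)
  }
  for (i in seq_len(n_per_class["cetacean"])) {
    k <- k + 1
    nz <- noise_clip()
    f0 <- stats::runif(1, 2000, 20000)
    dur <- stats::runif(1, 0.3, 3) / 1000
    tt <- (0:(round(6 * dur * fs))) / fs
    burst <- exp(-(tt - 3 * dur)^2 / (2 * dur^2)) * sin(2 * pi * f0 * tt)
    x <- numeric(n_clip)
    at <- round(n_clip / 2) + sample(-200:200, 1)
    x[at:(at + length(burst) - 1)] <- burst
    clips[[k]] <- nz + scale_to_snr(x, nz, snrs[k])
    labels <- c(labels, "cetacean"); ipis <- c(ipis, NA_real_)
  }
  for (i in seq_len(n_per_class["noise"])) {
    k <- k + 1
    clips[[k]] <- noise_clip()
    labels <- c(labels, "noise"); ipis <- c(ipis, NA_real_)
  }
  list(clips = clips, labels = labels, ipi_ms = ipis)
}

#' Bundled scene fixtures
#'
#' Small deterministic scenes exercising every stage: a single whale, two
#' whales at separated TDoAs, a nine-whale stress case, pure noise, and a
#' ferry-boost scene. All are generated programmatically (no audio is
#' shipped).
#'
#' @param seed RNG seed.
#' @param duration_s scene length (s); fixtures keep this short.
#' @return named list of `stereo_scene` objects.
#' @export
make_fixtures <- function(seed = 1, duration_s = 12) {
  geom <- array_geometry()
  line_track <- function(x, y, d) data.frame(time_s = c(0, duration_s),
                                             x_km = c(x, x), y_km = c(y, y),
                                             depth_m = c(d, d))
  w1 <- whale_sim(line_track(1.2, 1.0, 300), ici_s = 1,
                  model = click_model(ipi_ms = 4.5),
                  active_windows = list(c(0.5, duration_s - 0.5)), id = "w1")
  w2 <- whale_sim(line_track(-1.5, 0.8, 400), ici_s = 0.9,
                  model = click_model(ipi_ms = 3.2),
                  active_windows = list(c(0.5, duration_s - 0.5)), id = "w2")
  nine <- lapply(seq_len(9), function(i) {
    ang <- (i - 1) / 9 * 2 * pi
    whale_sim(line_track(2 * cos(ang), 2 * sin(ang), 200 + 50 * i),
              ici_s = 0.8 + 0.05 * i,
              model = click_model(ipi_ms = 3 + 0.5 * i),
              active_windows = list(c(0.5, duration_s - 0.5)),
              id = paste0("w", i))
  })
  list(
    single = render_scene(list(w1), geom, duration_s, sea_state = 2,
                          seed = seed),
    two = render_scene(list(w1, w2), geom, duration_s, sea_state = 2,
                       seed = seed + 1),
    nine = render_scene(nine, geom, duration_s, sea_state = 2,
                        seed = seed + 2),
    noise_only = render_scene(list(), geom, duration_s, sea_state = 2,
                              seed = seed + 3),
    ferry = render_scene(list(), geom, duration_s, sea_state = 2,
                         ferry_windows = list(c(0, duration_s / 2)),
                         ferry_boost_db = 3, seed = seed + 4))
}

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @return nested list of all stage parameters.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(seed = seed,
       scene = list(duration_s = 12, sea_state = 2, ferry_boost_db = 0,
                    n_whales = 2),
       detect = default_detect_config(),
       track = utils::modifyList(default_track_config(),
                                 list(min_points = 5, min_duration_s = 5)),
       ipi = list(search_band_ms = c(2, 10)),
       noise = list(cal_db = 0),
       range = list(n_emissions = 1e5, disc_radius_km = 400,
                    max_depth_m = 1600, depth_model = "uniform",
                    sl_db = 200, nl_db = 44, alpha_db_per_km = 1.43,
                    recall = list(L = 0.95, x0 = 5, k = 0.8)),
       density = list(habitat_fraction = 0.5, n_days = NA))
}

validate_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  extra <- setdiff(names(config), names(base))
  if (length(extra)) stop("unknown config sections: ",
                          paste(extra, collapse = ", "))
  utils::modifyList(base, config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline on a synthetic scene
#'
#' synthesize -> detect -> TDoA -> tracks -> passages -> IPI/size ->
#' octave noise -> Monte-Carlo effective area -> density, writing each
#' stage's outputs and a manifest into `out_dir`. Stages with existing
#' outputs are resumed (skipped) unless `overwrite`.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir run directory (created).
#' @param overwrite recompute stages whose outputs exist.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("stereopam_run_"),
                         overwrite = FALSE) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("stereopam")),
                   seed = config$seed, stages = list(),
                   config_hash = config_hash(config))
  stage_path <- function(stage, file) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    file.path(d, file)
  }
  timing <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, elapsed_s = proc.time()[["elapsed"]] - t0)
  }

  # --- scene ---
  wav_path <- stage_path("scene", "scene.wav")
  truth_path <- stage_path("scene", "truth_clicks.csv")
  fs <- array_geometry()$sample_rate_hz
  if (overwrite || !file.exists(wav_path)) {
    tm <- timing({
      fx <- make_fixtures(config$seed, config$scene$duration_s)
      scene <- if (config$scene$n_whales >= 2) fx$two else fx$single
      write_wav(scene$wave / 10^(scene$full_scale_db / 20), scene$fs,
                wav_path)
      utils::write.csv(scene$truth_clicks, truth_path, row.names = FALSE)
      utils::write.csv(scene$truth_whales,
                       stage_path("scene", "truth_whales.csv"),
                       row.names = FALSE)
      scene
    })
    scene <- tm$value
    manifest$stages$scene <- list(elapsed_s = tm$elapsed_s,
                                  resumed = FALSE)
  } else {
    wv <- read_wav(wav_path)
    scene <- structure(list(wave = wv$data * 10^(170 / 20), fs = wv$fs,
                            truth_clicks = utils::read.csv(truth_path),
                            full_scale_db = 170),
                       class = "stereo_scene")
    manifest$stages$scene <- list(resumed = TRUE)
  }

  # --- detection ---
  det_path <- stage_path("detect", "detections.csv")
  if (overwrite || !file.exists(det_path)) {
    tm <- timing({
      det <- detect_clicks(scene$wave, scene$fs, config$detect)
      utils::write.csv(det, det_path, row.names = FALSE)
      det
    })
    det <- tm$value
    manifest$stages$detect <- list(elapsed_s = tm$elapsed_s,
                                   n_events = nrow(det), resumed = FALSE)
  } else {
    det <- utils::read.csv(det_path)
    manifest$stages$detect <- list(resumed = TRUE, n_events = nrow(det))
  }
  if (nrow(det) == 0) {
    manifest$stages$track <- list(skipped = "no detections from stage 'detect'")
    tracks <- data.frame(); passages <- data.frame()
  }

  # --- tdoa + tracks + passages ---
  if (nrow(det) > 0) {
    tm <- timing({
      pts <- tdoa_of_events(scene$wave, det, scene$fs)
      tr <- build_tracks(pts, config$track)
      psg <- segment_passages(tr$tracks)
      utils::write.csv(pts, stage_path("track", "tdoa_points.csv"),
                       row.names = FALSE)
      utils::write.csv(tr$tracks, stage_path("track", "tracks.csv"),
                       row.names = FALSE)
      utils::write.csv(psg, stage_path("track", "passages.csv"),
                       row.names = FALSE)
      list(points = pts, tracks = tr$tracks, passages = psg)
    })
    tracks <- tm$value$tracks; passages <- tm$value$passages
    manifest$stages$track <- list(elapsed_s = tm$elapsed_s,
                                  n_tracks = nrow(tracks),
                                  n_passages = nrow(passages))
  }

  # --- IPI / size ---
  n_ind <- if (nrow(passages)) max(passages$n_individuals) else 0
  if (nrow(det) > 0 && n_ind >= 1 && n_ind <= 2) {
    tm <- timing({
      win <- round(0.03 * scene$fs)
      clicks <- lapply(det$time_s[det$channel == 1], function(t) {
        i <- round(t * scene$fs)
        scene$wave[max(1, i - win %/% 3):min(nrow(scene$wave), i + win), 1]
      })
      est <- estimate_ipi(clicks, scene$fs,
                          search_band_ms = config$ipi$search_band_ms,
                          n_individuals = n_ind)
      utils::write.csv(data.frame(ipi_ms = est$ipi_ms, size_m = est$size_m,
                                  size_class = est$size_class,
                                  branch = est$size_branch,
                                  n_clicks = est$n_clicks,
                                  reliable = est$reliable),
                       stage_path("ipi", "ipi.csv"), row.names = FALSE)
      est
    })
    manifest$stages$ipi <- list(elapsed_s = tm$elapsed_s,
                                ipi_ms = tm$value$ipi_ms)
  } else {
    manifest$stages$ipi <- list(
      skipped = if (nrow(det) == 0) "no detections from stage 'detect'"
      else ">2 simultaneous individuals")
  }

  # --- octave noise (east channel only) ---
  tm <- timing({
    lv <- octave_levels(scene$wave[, 1], scene$fs,
                        cal_db = config$noise$cal_db)
    utils::write.csv(lv, stage_path("noise", "octave_levels.csv"),
                     row.names = FALSE)
    lv
  })
  nl_12800 <- tm$value$spl_db[tm$value$center_hz == 12800]
  manifest$stages$noise <- list(elapsed_s = tm$elapsed_s,
                                nl_12800_db = nl_12800)

  # --- effective area + density ---
  tm <- timing({
    rc <- config$range$recall
    ea <- mc_effective_area(
      mc_config(config$range$n_emissions, config$range$disc_radius_km,
                config$range$max_depth_m, config$range$depth_model,
                seed = config$seed),
      sl_db = config$range$sl_db, nl_db = config$range$nl_db,
      recall = recall_model(rc$L, rc$x0, rc$k),
      alpha_db_per_km = config$range$alpha_db_per_km)
    n_days <- config$density$n_days
    if (is.na(n_days)) n_days <- config$scene$duration_s / 86400
    n_animals <- if (nrow(passages)) sum(passages$n_individuals) else 0
    dens <- whale_density(n_animals, max(n_days, 1e-9),
                          habitat_area(ea$re_km,
                                       config$density$habitat_fraction))
    jsonlite::write_json(list(effective_area = unclass(ea),
                              density = unclass(dens)),
                         stage_path("range", "range_density.json"),
                         auto_unbox = TRUE, digits = NA)
    list(ea = ea, dens = dens)
  })
  manifest$stages$range <- list(elapsed_s = tm$elapsed_s,
                                re_km = tm$value$ea$re_km,
                                density = tm$value$dens$density_per_1000km2)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
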