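# The sonar-equation chain for cue-density estimation: seawater absorption,
# transmission loss, beam directivity, SNR budget, Monte-Carlo effective
# detection area/radius, and density per 1000 km^2.

#' Francois-Garrison seawater absorption coefficient
#'
#' Boric acid + magnesium sulphate + pure-water viscosity contributions.
#' At 12.5 kHz, 11 degrees C, 38.5 ppt, 500 m, pH 8 (Mediterranean
#' conditions at sperm whale click frequencies) the model gives
#' ~1.4 dB/km.
#'
#' @param f_khz frequency in kHz (> 0).
#' @param temp_c temperature, degrees C (-6 to 35).
#' @param salinity_ppt salinity, ppt (5 to 50).
#' @param depth_m depth, m (0 to 7000).
#' @param ph pH (6 to 9).
#' @return absorption in dB/km.
#' @export
absorption <- function(f_khz, temp_c = 11, salinity_ppt = 38.5,
                       depth_m = 500, ph = 8) {
  if (any(f_khz < 0)) stop("frequency must be >= 0")
  if (temp_c < -6 || temp_c > 35) stop("temperature outside model range")
  if (salinity_ppt < 5 || salinity_ppt > 50) stop("salinity outside model range")
  if (depth_m < 0 || depth_m > 7000) stop("depth outside model range")
  if (ph < 6 || ph > 9) stop("pH outside model range")
  f <- f_khz; T <- temp_c; S <- salinity_ppt; D <- depth_m
  c_ms <- 1412 + 3.21 * T + 1.19 * S + 0.0167 * D
  # boric acid
  A1 <- 8.86 / c_ms * 10^(0.78 * ph - 5)
  P1 <- 1
  f1 <- 2.8 * sqrt(S / 35) * 10^(4 - 1245 / (T + 273))
  # magnesium sulphate
  A2 <- 21.44 * S / c_ms * (1 + 0.025 * T)
  P2 <- 1 - 1.37e-4 * D + 6.2e-9 * D^2
  f2 <- 8.17 * 10^(8 - 1990 / (T + 273)) / (1 + 0.0018 * (S - 35))
  # pure water viscosity
  P3 <- 1 - 3.83e-5 * D + 4.9e-10 * D^2
  A3 <- if (T <= 20) {
    4.937e-4 - 2.59e-5 * T + 9.11e-7 * T^2 - 1.50e-8 * T^3
  } else {
    3.964e-4 - 1.146e-5 * T + 1.45e-7 * T^2 - 6.5e-10 * T^3
  }
  A1 * P1 * f1 * f^2 / (f1^2 + f^2) +
    A2 * P2 * f2 * f^2 / (f2^2 + f^2) +
    A3 * P3 * f^2
}

#' Transmission loss: spherical spreading plus absorption
#'
#' `TL = 20 log10(r) + alpha * r`, with `r` in metres for the spreading
#' term and kilometres for the absorption term.
#'
#' @param r_m range in metres (>= 1).
#' @param alpha_db_per_km absorption coefficient, dB/km.
#' @return transmission loss in dB (vectorised over `r_m`).
#' @export
transmission_loss <- function(r_m, alpha_db_per_km = 1.43) {
  if (any(r_m < 1)) stop("range must be >= 1 m")
  20 * log10(r_m) + alpha_db_per_km * r_m / 1000
}

#' Source directivity gain
#'
#' Gain relative to the on-axis direction (0 dB on axis by convention;
#' the source level carries the absolute scale). Models:
#' * `"isotropic"` - 0 dB at every angle;
#' * `list(type = "piston", ka = ...)` - circular-piston directivity
#'   `20 log10 |2 J1(ka sin t) / (ka sin t)|`, floored at `floor_db`;
#' * `list(type = "table", angle_rad = ..., gain_db = ...,
#'   offset_db = 0)` - interpolated user table (e.g. a published beam
#'   pattern given in relative amplitude, with a constant offset to place
#'   it on an absolute scale).
#'
#' @param off_axis_angle_rad angle from the acoustic axis, radians in
#'   `[0, pi]` (vectorised).
#' @param model `"isotropic"`, `"piston"`, or a list as above.
#' @param floor_db lower clamp for the parametric pattern (dB).
#' @return gain in dB (<= 0 for the parametric models).
#' @export
beam_gain <- function(off_axis_angle_rad, model = "isotropic",
                      floor_db = -40) {
  th <- off_axis_angle_rad
  if (any(th < 0 | th > pi)) stop("off-axis angle must be in [0, pi]")
  if (is.character(model)) model <- list(type = model)
  if (is.null(model$type)) stop("beam model needs a 'type'")
  switch(model$type,
    isotropic = rep(0, length(th)),
    piston = {
      ka <- if (is.null(model$ka)) 28.8 else model$ka  # ~0.55 m at 12.5 kHz
      x <- ka * sin(th)
      g <- ifelse(x < 1e-9, 1, 2 * besselJ(x, 1) / x)
      pmax(20 * log10(pmax(abs(g), 1e-12)), floor_db)
    },
    table = {
      if (is.null(model$angle_rad) || is.null(model$gain_db)) {
        stop("table beam model needs angle_rad and gain_db")
      }
      off <- if (is.null(model$offset_db)) 0 else model$offset_db
      stats::approx(model$angle_rad, model$gain_db, th, rule = 2)$y + off
    },
    stop("unknown beam model: ", model$type))
}

#' Sonar-equation SNR at the antenna
#'
#' `SNR = SL + G - TL - NL`, all in dB.
#'
#' @param sl_db source level (dB re 1 uPa @ 1 m).
#' @param beam_gain_db directivity gain (dB).
#' @param tl_db transmission loss (dB).
#' @param nl_db noise level (dB re 1 uPa).
#' @return SNR in dB.
#' @export
snr_at_antenna <- function(sl_db, beam_gain_db, tl_db, nl_db) {
  sl_db + beam_gain_db - tl_db - nl_db
}

#' Sigmoid recall model
#'
#' `recall(snr) = L / (1 + exp(-k (snr - x0)))`: the continuous model of
#' detector recall versus SNR used inside the Monte-Carlo detection
#' simulation. `recall(x0) = L/2` exactly.
#'
#' @param L upper plateau in `(0, 1]`.
#' @param x0 SNR midpoint (dB).
#' @param k slope (per dB, > 0).
#' @return object of class `recall_model`.
#' @export
recall_model <- function(L, x0, k) {
  stopifnot(L > 0, L <= 1, k > 0)
  structure(list(L = L, x0 = x0, k = k, type = "sigmoid"),
            class = "recall_model")
}

#' Evaluate a recall model
#'
#' @param model a [recall_model()] or any function `snr -> [0, 1]`.
#' @param snr_db SNR values (dB).
#' @return detection probabilities.
#' @export
recall_probability <- function(model, snr_db) {
  p <- if (is.function(model)) {
    model(snr_db)
  } else if (inherits(model, "recall_model")) {
    model$L / (1 + exp(-model$k * (snr_db - model$x0)))
  } else stop("not a recall model")
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    stop("recall model returned probabilities outside [0, 1]")
  }
  pmin(pmax(p, 0), 1)
}

#' Monte-Carlo configuration for the effective-area simulation
#'
#' @param n_emissions number of simulated click emissions (>= 1e4 for
#'   reported results; the survey-scale value is `pi/4 * 2^30`, the desk
#'   default 1e6).
#' @param disc_radius_km radius of the simulated disc (km).
#' @param max_depth_m maximum whale depth (m).
#' @param depth_model `"uniform"` over `[0, max_depth_m]`, or
#'   `"lognormal"` (log10 mean 2.55 ~ 354 m, log10 sd 0.3, resampled
#'   above `max_depth_m`).
#' @param seed RNG seed.
#' @return object of class `mc_config`.
#' @export
mc_config <- function(n_emissions = 1e6, disc_radius_km = 400,
                      max_depth_m = 1600,
                      depth_model = c("uniform", "lognormal"),
                      seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_emissions >= 1, disc_radius_km > 0, max_depth_m > 0)
  structure(list(n_emissions = as.integer(n_emissions),
                 disc_radius_km = disc_radius_km,
                 max_depth_m = max_depth_m, depth_model = depth_model,
                 seed = as.integer(seed)),
            class = "mc_config")
}

mc_draws <- function(mc) {
  n <- mc$n_emissions
  set.seed(mc$seed)
  r_km <- mc$disc_radius_km * sqrt(stats::runif(n))   # area-uniform
  depth <- if (mc$depth_model == "uniform") {
    stats::runif(n, 0, mc$max_depth_m)
  } else {
    d <- 10^stats::rnorm(n, 2.55, 0.3)
    bad <- which(d > mc$max_depth_m)
    while (length(bad)) {
      d[bad] <- 10^stats::rnorm(length(bad), 2.55, 0.3)
      bad <- bad[d[bad] > mc$max_depth_m]
    }
    d
  }
  cos_th <- stats::runif(n, -1, 1)   # uniform orientation on the sphere
  list(r_km = r_km, depth_m = depth, off_axis_rad = acos(cos_th))
}

#' Monte-Carlo effective detection area
#'
#' Emissions are spread area-uniformly over a disc of radius
#' `disc_radius_km`, with depths from the configured depth model and
#' orientations uniform on the sphere. For each emission the
#' sonar-equation SNR at the antenna is computed
#' (`SNR = SL + G - TL - NL`, `TL = 20 log10 r + alpha r`), converted to
#' a detection probability by the recall model, and averaged:
#' `p = mean`, `a_e = pi R^2 p`, `r_e = sqrt(a_e / pi)`.
#'
#' @param mc an [mc_config()].
#' @param sl_db source level (dB re 1 uPa @ 1 m).
#' @param nl_db noise level at the antenna (dB re 1 uPa), conventionally
#'   the 12,800 Hz octave level.
#' @param recall a [recall_model()] or function `snr -> [0, 1]`.
#' @param beam_model see [beam_gain()].
#' @param alpha_db_per_km absorption (dB/km).
#' @param antenna_depth_m receiver depth (m).
#' @param draws optional precomputed draws (for common random numbers
#'   across a noise sweep); overrides `mc$seed`.
#' @return object of class `effective_area_result`: `p`, `a_km2`,
#'   `ae_km2`, `re_km`, `mc_se` (standard error of `p`), `n`.
#' @export
mc_effective_area <- function(mc, sl_db = 200, nl_db = 44,
                              recall = recall_model(0.95, 5, 0.8),
                              beam_model = "isotropic",
                              alpha_db_per_km = 1.43,
                              antenna_depth_m = 25, draws = NULL) {
  if (is.null(draws)) draws <- mc_draws(mc)
  slant_m <- sqrt((draws$r_km * 1000)^2 +
                    (draws$depth_m - antenna_depth_m)^2)
  tl <- transmission_loss(pmax(slant_m, 1), alpha_db_per_km)
  g <- beam_gain(draws$off_axis_rad, beam_model)
  snr <- snr_at_antenna(sl_db, g, tl, nl_db)
  p_i <- recall_probability(recall, snr)
  p <- mean(p_i)
  a <- pi * mc$disc_radius_km^2
  structure(list(p = p, a_km2 = a, ae_km2 = a * p,
                 re_km = sqrt(a * p / pi),
                 mc_se = stats::sd(p_i) / sqrt(length(p_i)),
                 n = length(p_i)),
            class = "effective_area_result")
}

#' Effective radius as a function of background noise level
#'
#' Runs [mc_effective_area()] over a grid of noise levels with common
#' random numbers, so the resulting curve is smooth in NL.
#'
#' @param nl_grid_db sorted noise levels (dB re 1 uPa).
#' @param mc an [mc_config()].
#' @param ... further arguments to [mc_effective_area()].
#' @return data.frame `nl_db`, `p`, `ae_km2`, `re_km`, `mc_se`.
#' @export
radius_vs_noise <- function(nl_grid_db, mc, ...) {
  if (length(nl_grid_db) == 0) {
    return(data.frame(nl_db = numeric(0), p = numeric(0),
                      ae_km2 = numeric(0), re_km = numeric(0),
                      mc_se = numeric(0)))
  }
  draws <- mc_draws(mc)
  rows <- lapply(nl_grid_db, function(nl) {
    r <- mc_effective_area(mc, nl_db = nl, draws = draws, ...)
    data.frame(nl_db = nl, p = r$p, ae_km2 = r$ae_km2, re_km = r$re_km,
               mc_se = r$mc_se)
  })
  do.call(rbind, rows)
}

#' Habitable area within the effective radius
#'
#' `fraction * pi * re^2`: the part of the effective-detection disc that
#' is plausible habitat (e.g. 0.5 when half the disc is shallow shelf).
#'
#' @param re_km effective radius (km), > 0.
#' @param habitat_fraction fraction in `(0, 1]`.
#' @return area in km^2.
#' @export
habitat_area <- function(re_km, habitat_fraction = 0.5) {
  stopifnot(re_km >= 0, habitat_fraction > 0, habitat_fraction <= 1)
  habitat_fraction * pi * re_km^2
}

#' Average cue density per 1000 km^2
#'
#' `D = (n_animals / n_days) / habitat_area * 1000`: the mean number of
#' animals simultaneously present per 1000 km^2, from the total count of
#' detected animals over the survey, the survey duration, and the
#' monitored habitat area.
#'
#' @param n_animals total animals detected over the survey (>= 0).
#' @param n_days survey duration in days (> 0).
#' @param habitat_area_km2 monitored habitat area (km^2, > 0).
#' @return object of class `density_result`: `n_animals`, `n_days`,
#'   `habitat_area_km2`, `density_per_1000km2`.
#' @export
whale_density <- function(n_animals, n_days, habitat_area_km2) {
  if (n_days <= 0 || habitat_area_km2 <= 0) {
    stop("survey days and habitat area must be positive")
  }
  if (n_animals < 0) stop("animal count must be >= 0")
  structure(list(n_animals = n_animals, n_days = n_days,
                 habitat_area_km2 = habitat_area_km2,
                 density_per_1000km2 =
                   n_animals / n_days / habitat_area_km2 * 1000),
            class = "density_result")
}

#' @export
print.effective_area_result <- function(x, ...) {
  cat(sprintf(
    "Effective detection area: p = %.4g (SE %.2g), a_e = %.4g km^2, r_e = %.3g km (n = %d)\n",
    x$p, x$mc_se, x$ae_km2, x$re_km, x$n))
  invisible(x)
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Density: %.2f animals / 1000 km^2 (%g animals, %g days, %g km^2)\n",
              x$density_per_1000km2, x$n_animals, x$n_days,
              x$habitat_area_km2))
  invisible(x)
}
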