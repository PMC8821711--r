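# Sonar-equation chain and the Monte-Carlo effective-area model.

test_that("Francois-Garrison reproduces the survey absorption value", {
  a <- absorption(12.5, temp_c = 11, salinity_ppt = 38.5, depth_m = 500,
                  ph = 8)
  expect_equal(a, 1.43, tolerance = 0.1 / 1.43)
  expect_equal(absorption(0), 0)
  # monotone in frequency over 1-50 kHz
  f <- seq(1, 50, by = 1)
  expect_true(all(diff(absorption(f)) > 0))
  expect_error(absorption(12.5, temp_c = 60), "temperature")
  expect_error(absorption(12.5, ph = 3), "pH")
})

test_that("transmission loss: spherical spreading plus absorption", {
  expect_equal(transmission_loss(1, 1.43), 0, tolerance = 0.01)
  expect_equal(transmission_loss(1000, 1.43), 61.43)
  expect_equal(transmission_loss(10000, 1.43), 94.3)
  expect_error(transmission_loss(0.5), ">= 1")
})

test_that("beam models behave as documented", {
  expect_equal(beam_gain(0, "piston"), 0)
  expect_equal(beam_gain(seq(0, pi, length.out = 10), "isotropic"),
               rep(0, 10))
  # piston: non-increasing out to the first null (ka sin th = 3.83)
  ka <- 28.8
  th <- seq(0, asin(3.83 / ka), length.out = 50)
  g <- beam_gain(th, list(type = "piston", ka = ka))
  expect_true(all(diff(g) <= 1e-9))
  # table model with constant offset (relative pattern -> absolute)
  tab <- list(type = "table", angle_rad = c(0, pi / 2, pi),
              gain_db = c(-161, -181, -201), offset_db = 161)
  expect_equal(beam_gain(0, tab), 0)
  expect_equal(beam_gain(pi, tab), -40)
  expect_error(beam_gain(0, list(type = "nosuch")), "unknown beam model")
  expect_error(beam_gain(4, "isotropic"), "angle")
})

test_that("the SNR budget is exact arithmetic", {
  expect_equal(snr_at_antenna(200, 0, 94.3, 44), 61.7)
  expect_equal(snr_at_antenna(200, 0, 94.3, 54),
               snr_at_antenna(200, 0, 94.3, 44) - 10)
  expect_equal(snr_at_antenna(150, 0, 150 - 44, 44), 0)
})

test_that("recall model: recall(x0) = L/2 and bounds are enforced", {
  m <- recall_model(0.9, 5, 0.8)
  expect_equal(recall_probability(m, 5), 0.45)
  expect_true(all(recall_probability(m, seq(-50, 50)) >= 0 &
                    recall_probability(m, seq(-50, 50)) <= 0.9))
  expect_error(
    mc_effective_area(mc_config(1000, seed = 1),
                      recall = function(s) rep(2, length(s))),
    "outside")
})

test_that("everything detected: p = 1 and r_e equals the disc radius", {
  ea <- mc_effective_area(mc_config(10000, seed = 2),
                          recall = function(s) rep(1, length(s)))
  expect_equal(ea$p, 1)
  expect_equal(ea$re_km, 400)
  expect_equal(ea$ae_km2, pi * 400^2)
})

test_that("step recall matches the geometric closed form within 3 SE", {
  R0 <- 50; SL <- 200; NL <- 44; alpha <- 1.43
  snr0 <- SL - transmission_loss(R0 * 1000, alpha) - NL
  step <- function(snr) as.numeric(snr >= snr0)
  # depths far smaller than the ranges involved -> slant ~ horizontal
  ea <- mc_effective_area(mc_config(1e5, 400, max_depth_m = 50, seed = 11),
                          sl_db = SL, nl_db = NL, recall = step,
                          alpha_db_per_km = alpha)
  p_true <- R0^2 / 400^2
  expect_lt(abs(ea$p - p_true), 3 * ea$mc_se)
  expect_equal(ea$re_km, R0, tolerance = 0.05)
})

test_that("result identities and seed reproducibility hold exactly", {
  mc <- mc_config(20000, seed = 5)
  a <- mc_effective_area(mc)
  b <- mc_effective_area(mc)
  expect_identical(a, b)
  expect_equal(a$ae_km2, a$a_km2 * a$p)
  expect_equal(a$re_km, sqrt(a$ae_km2 / pi))
  c2 <- mc_effective_area(mc_config(20000, seed = 6))
  expect_false(identical(a$p, c2$p))
})

test_that("lognormal depth model stays within bounds and runs", {
  ea <- mc_effective_area(mc_config(20000, depth_model = "lognormal",
                                    seed = 4))
  expect_true(ea$p > 0 && ea$p < 1)
  d <- stereopam:::mc_draws(mc_config(5000, depth_model = "lognormal",
                                      seed = 9))
  expect_true(all(d$depth_m <= 1600))
  expect_equal(stats::median(log10(d$depth_m)), 2.55, tolerance = 0.05)
})

test_that("effective radius shrinks with background noise", {
  cv <- radius_vs_noise(seq(30, 70, by = 5), mc_config(2e4, seed = 3))
  expect_true(all(diff(cv$re_km) <= 0))
  # +6 dB source level offsets the curve by +6 dB in NL (budget symmetry)
  cv_hi <- radius_vs_noise(seq(36, 76, by = 5), mc_config(2e4, seed = 3),
                           sl_db = 206)
  expect_equal(cv_hi$re_km, cv$re_km, tolerance = 1e-10)
  expect_equal(nrow(radius_vs_noise(numeric(0), mc_config(1000))), 0)
})

test_that("habitat area and density reproduce the worked survey numbers", {
  expect_equal(round(habitat_area(32.9, 0.5), -2), 1700)
  expect_equal(habitat_area(10, 1), pi * 100)
  expect_equal(habitat_area(0, 0.5), 0)
  d <- whale_density(422, 147, 1700)
  expect_equal(round(d$density_per_1000km2, 2), 1.69)
  expect_equal(whale_density(0, 147, 1700)$density_per_1000km2, 0)
  expect_equal(whale_density(844, 147, 1700)$density_per_1000km2,
               2 * d$density_per_1000km2)
  expect_error(whale_density(422, 0, 1700), "positive")
})
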