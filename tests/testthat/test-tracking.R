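# TDoA measurement, track clustering, passage segmentation and counts.

test_that("tdoa_of_click recovers constructed delays", {
  fs <- 50000
  set.seed(21)
  x <- rnorm(fs)   # broadband noise "click" context
  wave <- cbind(x, x)
  r0 <- tdoa_of_click(wave, 0.5, fs)
  expect_equal(r0$tdoa_s, 0)
  d <- 30
  wave2 <- cbind(x, c(numeric(d), x[1:(fs - d)]))
  r <- tdoa_of_click(wave2, 0.5, fs)
  expect_equal(r$tdoa_s, d / fs, tolerance = 1 / fs)
  expect_false(r$low_confidence)
})

test_that("scene TDoAs match truth within one sample", {
  sc <- single_whale_scene()
  det <- detect_clicks(sc$wave, sc$fs)
  ev <- det[det$channel == 1, ]
  pts <- tdoa_of_events(sc$wave, ev, sc$fs)
  # score only points that correspond to a true click
  errs <- vapply(seq_len(nrow(pts)), function(i) {
    j <- which.min(abs(sc$truth_clicks$t_east_s - pts$time_s[i]))
    if (abs(sc$truth_clicks$t_east_s[j] - pts$time_s[i]) > 2e-3) NA_real_
    else pts$tdoa_s[i] - sc$truth_clicks$tdoa_s[j]
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gte(length(errs), nrow(sc$truth_clicks) * 0.9)
  expect_true(all(abs(errs) <= 1 / sc$fs + 1e-12))
  expect_true(all(abs(pts$tdoa_s) <= max_tdoa(sc$geom) + 1 / sc$fs))
})

test_that("one continuously clicking whale yields one track", {
  sc <- single_whale_scene()
  det <- detect_clicks(sc$wave, sc$fs)
  pts <- tdoa_of_events(sc$wave, det, sc$fs)
  tr <- build_tracks(pts, list(min_points = 5, min_duration_s = 5))
  expect_equal(nrow(tr$tracks), 1)
  in_track <- tr$points$track_id == 1
  truth_n <- nrow(sc$truth_clicks)
  expect_gte(sum(in_track), 0.9 * truth_n)
})

test_that("two separated whales yield two tracks without identity swaps", {
  set.seed(9)
  t1 <- seq(0, 300, by = 1)
  p1 <- data.frame(time_s = t1, tdoa_s = 8e-4 + rnorm(length(t1), 0, 1e-5))
  p2 <- data.frame(time_s = t1 + 0.4,
                   tdoa_s = -6e-4 + rnorm(length(t1), 0, 1e-5))
  pts <- rbind(p1, p2)
  tr <- build_tracks(pts[order(pts$time_s), ], list(min_points = 20,
                                                    min_duration_s = 60))
  expect_equal(nrow(tr$tracks), 2)
  lab <- tr$points$track_id[order(tr$points$tdoa_s)]
  expect_equal(length(unique(lab[1:length(t1)])), 1)   # no swaps
})

test_that("uniform random false alarms produce no tracks", {
  set.seed(12)
  pts <- data.frame(time_s = sort(runif(100, 0, 600)),
                    tdoa_s = runif(100, -1.2e-3, 1.2e-3))
  tr <- build_tracks(pts)   # default minima: >= 20 points, >= 5 min
  expect_equal(nrow(tr$tracks), 0)
})

test_that("passages split on the one-hour rule", {
  mk <- function(s, e) data.frame(start_s = s, end_s = e)
  # 30 min gap -> one passage
  p1 <- segment_passages(rbind(mk(0, 600), mk(600 + 1800, 600 + 1800 + 600)))
  expect_equal(nrow(p1), 1)
  # 61 min gap -> two passages
  p2 <- segment_passages(rbind(mk(0, 600), mk(600 + 3660, 600 + 3660 + 600)))
  expect_equal(nrow(p2), 2)
  # exactly 1 h -> split (strict "at least 1 h")
  p3 <- segment_passages(rbind(mk(0, 600), mk(600 + 3600, 600 + 3600 + 600)))
  expect_equal(nrow(p3), 2)
  # single 10-min track: one passage of 10 min
  p4 <- segment_passages(mk(0, 600))
  expect_equal(nrow(p4), 1)
  expect_equal(p4$duration_s, 600)
  expect_equal(p4$n_individuals, 1)
})

test_that("count_individuals equals the brute-force maximum overlap", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    s <- runif(n, 0, 100)
    e <- s + runif(n, 5, 60)
    tracks <- data.frame(start_s = s, end_s = e)
    grid <- seq(0, 170, by = 0.05)
    brute <- max(vapply(grid, function(g)
      sum(s <= g & g <= e), numeric(1)))
    expect_equal(count_individuals(tracks), brute)
  }
  # nine fully overlapping tracks -> 9
  nine <- data.frame(start_s = rep(0, 9), end_s = rep(100, 9))
  expect_equal(count_individuals(nine), 9)
  # pairwise overlaps without a triple
  tri <- data.frame(start_s = c(0, 8, 16), end_s = c(10, 18, 26))
  expect_equal(count_individuals(tri), 2)
})

test_that("track assignment is invariant to global time shifts", {
  set.seed(44)
  t1 <- seq(0, 200, by = 2)
  pts <- data.frame(time_s = t1, tdoa_s = 5e-4 + 1e-7 * t1)
  cfg <- list(min_points = 10, min_duration_s = 30)
  a <- build_tracks(pts, cfg)
  pts2 <- pts; pts2$time_s <- pts2$time_s + 12345
  b <- build_tracks(pts2, cfg)
  expect_equal(a$points$track_id, b$points$track_id)
  expect_equal(b$tracks$start_s - a$tracks$start_s, 12345)
})
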