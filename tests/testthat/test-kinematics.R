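# speed, angles, bends, bouts, stimulus and response summaries

test_that("speed follows the displacement arithmetic with a zero first frame", {
  n <- 50
  kp <- array(0, c(n, 1, 2))
  kp[, 1, 1] <- (seq_len(n) - 1) * 0.2 # 0.2 px/frame
  tr <- trajectory_series(kp, framerate = 100, mm_per_px = 0.1)
  sp <- compute_speed(tr)
  expect_equal(sp[1], 0)
  expect_equal(sp[-1], rep(2.0, n - 1)) # 0.2 px * 0.1 mm/px * 100 Hz
  # stationary fish
  tr0 <- trajectory_series(array(5, c(10, 1, 2)), 100, 0.1)
  expect_equal(compute_speed(tr0), rep(0, 10))
})

test_that("the mean filter has the stated impulse response and preserves constants", {
  x <- rep(3.7, 500)
  expect_equal(smooth_series(x, 1, 100), x)
  imp <- rep(0, 500); imp[250] <- 1
  sm <- smooth_series(imp, 1, 100) # 1 s at 100 Hz -> 101-frame window
  expect_equal(sm[250], 1 / 101)
  expect_equal(sm[250 - 50], 1 / 101)
  expect_equal(sm[250 + 50], 1 / 101)
  expect_equal(sm[250 + 51], 0)
  # interior-dominated series keep their mean
  expect_lt(abs(mean(sm) - mean(imp)), 1e-9)
})

test_that("a 7-point semicircle reads 150 degrees and invariances hold", {
  th <- seq(0, pi, length.out = 7)
  semi <- cbind(cos(th), sin(th)) * 20
  expect_equal(rostral_caudal_angle(semi), 150, tolerance = 1e-9)
  expect_equal(rostral_caudal_angle(cbind(1:7, 2 * (1:7))), 0, tolerance = 1e-9)
  set.seed(31)
  for (rep in 1:25) {
    kp <- cbind(cumsum(runif(6, 0.5, 2)), cumsum(rnorm(6, 0, 0.7)))
    kp <- rbind(c(0, 0), kp)
    a <- rostral_caudal_angle(kp)
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    moved <- sweep(kp %*% t(R), 2, runif(2, -50, 50), `+`)
    expect_equal(rostral_caudal_angle(moved), a, tolerance = 1e-9)
    expect_equal(rostral_caudal_angle(cbind(kp[, 1], -kp[, 2])), -a,
                 tolerance = 1e-9)
  }
  expect_error(rostral_caudal_angle(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident")
  expect_error(rostral_caudal_angle(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("bend detection classifies peaks against the 110-degree threshold", {
  fr <- 1000
  tri <- function(peak, center, half, n) {
    i <- seq_len(n) - 1
    peak * pmax(0, 1 - abs(i - center) / half)
  }
  # |peaks| = {120, 95, 115} with alternating sign -> 2 high-amplitude bends
  ang <- tri(120, 15, 10, 100) - tri(95, 45, 10, 100) + tri(115, 75, 10, 100)
  det <- detect_bends(ang, fr, kinematic_config())
  expect_equal(nrow(det$events), 3L)
  expect_equal(det$summary$n_high_amplitude, 2L)
  expect_equal(det$events$peak_angle, c(120, -95, 115))
  # single triangular pulse peaking 130 deg at t = 0.015 s
  one <- tri(130, 15, 8, 60)
  d1 <- detect_bends(one, fr, kinematic_config())
  expect_equal(d1$summary$first_peak_angle, 130)
  expect_equal(d1$summary$first_peak_time, 0.015)
  expect_equal(d1$summary$max_angle, 130)
  # all sub-threshold: no high-amplitude bends
  d2 <- detect_bends(tri(80, 30, 10, 60), fr, kinematic_config())
  expect_equal(d2$summary$n_high_amplitude, 0L)
  expect_false(d2$summary$any_high_amplitude)
})

test_that("bout segmentation matches the worked example and edge cases", {
  sp <- c(0, 0, 5, 6, 5, 0, 0, 3, 0)
  b <- detect_bouts(sp, 100, kinematic_config())
  expect_equal(nrow(b), 2L)
  expect_equal(b$duration, c(0.03, 0.01))
  expect_equal(b$peak_speed, c(6, 3))
  expect_equal(b$start_time, c(0.02, 0.07))
  expect_equal(nrow(detect_bouts(rep(1.5, 20), 100, kinematic_config())), 0L)
  all_above <- detect_bouts(rep(4, 20), 100, kinematic_config())
  expect_equal(nrow(all_above), 1L)
  expect_equal(all_above$duration, 0.2)
})

test_that("bout and bend detectors equal brute-force oracles on random series", {
  set.seed(77)
  cfg <- kinematic_config()
  for (rep in 1:300) {
    n <- sample(5:60, 1)
    sp <- pmax(0, rnorm(n, 1.5, 2))
    expect_equal(detect_bouts(sp, 100, cfg),
                 oracle_bouts(sp, 100, cfg$bout_threshold))
    ang <- rnorm(n, 0, 80) * rbinom(n, 1, 0.9) # zeros act as boundaries
    if (n >= 3) {
      det <- detect_bends(ang, 100, cfg)$events
      expect_equal(det, oracle_bends(ang, 100, cfg$bend_threshold))
    }
  }
})

test_that("bout count is monotone non-increasing in the threshold for unimodal bouts", {
  # per-bout unimodal speed profiles (the biological case): raising the
  # threshold can only drop whole bouts, never split one
  tri <- function(center, half, peak, n) {
    i <- seq_len(n) - 1
    peak * pmax(0, 1 - abs(i - center) / half)
  }
  sp <- tri(20, 8, 3, 200) + tri(60, 10, 6, 200) + tri(120, 6, 9, 200) +
    tri(170, 9, 1.5, 200)
  counts <- vapply(c(0.5, 1, 2, 4, 8), function(th) {
    nrow(detect_bouts(sp, 100, kinematic_config(bout_threshold = th)))
  }, numeric(1))
  expect_equal(counts, c(4, 4, 3, 2, 1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stimulus windows cover 5 s, use raw speed, and truncate with a warning", {
  script <- trajectory_script(
    framerate = 100, duration = 8, mm_per_px = 0.1,
    bout_schedule = data.frame(start = c(1.0, 3.5), duration = c(0.3, 0.4),
                               peak_speed = c(4, 6)),
    body_length = 30)
  mv <- generate_trajectory_movie(script, scene_spec(frame_size = 512),
                                  render = FALSE)
  s <- stimulus_summary(mv$truth, mark = 3.0, cfg = kinematic_config())
  expect_equal(diff(unname(s$window)) * 100, 500) # 5 s at 100 Hz
  expect_equal(s$n_bouts, 1L)
  expect_equal(s$max_speed, max(mv$truth_table$speed_mm_s[301:800]))
  nb <- round(0.4 * 100)
  expect_gte(s$max_speed, 6 * sin(pi * (nb / 2 - 0.5) / nb) - 1e-9)
  expect_lte(s$max_speed, 6)
  # a window with no bouts reports zero and missing means
  q <- stimulus_summary(mv$truth, mark = 0, cfg = kinematic_config(stim_window = 0.5))
  expect_equal(q$n_bouts, 0L)
  expect_true(is.na(q$mean_bout_duration))
  expect_warning(stimulus_summary(mv$truth, mark = 7.5), "truncated")
  expect_error(stimulus_summary(mv$truth, mark = 99), "outside")
})

test_that("response summaries report duration, path length and progress", {
  n <- 250
  kp <- array(0, c(n, 1, 2))
  kp[, 1, 1] <- seq(0, 40, length.out = n)
  tr <- trajectory_series(kp, framerate = 1000, mm_per_px = 0.05)
  rs <- response_summary(tr)
  expect_equal(rs$duration, 0.25)
  expect_equal(rs$distance, 2.0)
  expect_equal(rs$progress[n], 1.0)
  expect_equal(rs$progress[1], 1 / n)
})

test_that("the end-to-end synthetic pipeline recovers the script exactly", {
  script <- trajectory_script(
    framerate = 100, duration = 4, mm_per_px = 0.1,
    bout_schedule = data.frame(start = c(0.5, 2.0, 3.0),
                               duration = c(0.3, 0.4, 0.2),
                               peak_speed = c(6, 3.5, 8)),
    bend_schedule = data.frame(peak_time = c(1.2, 1.5, 2.6),
                               peak_angle = c(130, -95, 121)),
    body_length = 40)
  mv <- generate_trajectory_movie(script, scene_spec(frame_size = 512),
                                  render = FALSE)
  cfg <- kinematic_config()
  sp <- compute_speed(mv$truth, cfg)
  bouts <- detect_bouts(sp, 100, cfg)
  expect_equal(nrow(bouts), 3L) # scripted bout count, exactly
  for (b in 1:3) { # peak speeds within one-frame discretization of the pulse
    nb <- round(script$bout_schedule$duration[b] * 100)
    pk <- script$bout_schedule$peak_speed[b]
    expect_lte(bouts$peak_speed[b], pk)
    expect_gte(bouts$peak_speed[b], pk * sin(pi * (nb / 2 - 0.5) / nb) - 1e-9)
  }
  ang <- vapply(seq_len(dim(mv$truth$keypoints)[1]),
                function(t) rostral_caudal_angle(mv$truth$keypoints[t, , ]),
                numeric(1))
  bends <- detect_bends(ang, 100, cfg)
  expect_equal(bends$summary$n_high_amplitude, 2L) # 130 and 121, not -95
  peaks <- bends$events$peak_angle[bends$events$is_high_amplitude]
  expect_equal(peaks, c(130, 121), tolerance = 1e-8)
})
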