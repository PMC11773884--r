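# frame IO, ROI grids, tracking plumbing, export

test_that("frame sequences load with scaling, RGB conversion and error reporting", {
  dir <- withr::local_tempdir()
  m1 <- matrix(seq(0, 1, length.out = 64), 8, 8)
  tiff::writeTIFF(m1, file.path(dir, "000000.tiff"), bits.per.sample = 16L)
  png::writePNG(m1, file.path(dir, "000001.png"))
  fr <- load_frames(dir)
  expect_equal(length(fr), 2L)
  expect_lt(max(abs(fr[[1]] - m1)), 1 / 65535 + 1e-9)
  expect_equal(max(fr[[1]]), 1.0) # full-range 16-bit maps to 1
  # RGB converts by luminance average with a warning
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  png::writePNG(rgb, file.path(dir, "000002.png"))
  expect_warning(fr2 <- load_frames(dir), "luminance")
  expect_equal(fr2[[3]], apply(rgb, c(1, 2), mean), tolerance = 1 / 255)
  # mixed sizes are reported by name
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "000003.png"))
  expect_error(suppressWarnings(load_frames(dir)), "000003")
  expect_error(load_frames(file.path(dir, "missing")), "no such directory")
  expect_error(load_frames(file.path(dir, "000001.png")), "video")
})

test_that("ROI grids tile the bounds without overlap and map coordinates back", {
  grid <- make_roi_grid(4, 6, c(10, 20, 120, 80))
  expect_equal(grid$n, 24L)
  expect_equal(grid$roi_w, 20L)
  expect_equal(grid$roi_h, 20L)
  # offsets are distinct and inside bounds
  expect_equal(nrow(unique(grid$offsets)), 24L)
  frame <- matrix(runif(200 * 200), 200, 200)
  cr <- crop_roi(frame, grid, 1)
  expect_equal(dim(cr$image), c(20L, 20L))
  # keypoint at ROI-local (10, 10) with offset (100, 100) -> plate (110, 110)
  grid2 <- make_roi_grid(1, 1, c(100, 100, 50, 50))
  cr2 <- crop_roi(frame, grid2, 1)
  expect_equal(cr2$offset + c(10, 10), c(110, 110))
  expect_equal(cr2$image, frame[101:150, 101:150])
  expect_error(crop_roi(matrix(0, 30, 30), grid2, 1), "exceeds")
})

test_that("plate -> ROI -> network -> heatmap -> plate round trip is within 0.5 px", {
  # plate with a 2x2 ROI grid; a scripted keypoint per frame and ROI;
  # the oracle predictor replays encoded heatmaps, bypassing any network
  set.seed(123)
  H <- 32L
  grid <- make_roi_grid(2, 2, c(0, 0, 96, 96))
  frames <- replicate(5, matrix(runif(96 * 96, 0.6, 0.9), 96, 96),
                      simplify = FALSE)
  plate_kp <- list()
  net_kp <- list()
  lb <- finpose:::letterbox(matrix(0, 48, 48), H, H)
  for (roi in 1:4) for (f in 1:5) {
    off <- grid$offsets[roi, ]
    # target heatmap-pixel centers so the codec leg of the trip is exact and
    # only the coordinate mapping is under test
    net_xy <- 2 * sample(4:11, 2, replace = TRUE) + 0.5
    local <- (net_xy - (lb$scale - 1) / 2 - lb$pad) / lb$scale
    plate_kp[[length(plate_kp) + 1L]] <- local + off
    net_kp[[length(net_kp) + 1L]] <- matrix(net_xy, 1)
  }
  oracle <- oracle_predictor(net_kp, H, H)
  trajs <- track_movie(frames, oracle, grid, framerate = 100, mm_per_px = 0.1)
  expect_equal(length(trajs), 4L)
  i <- 0
  for (roi in 1:4) for (f in 1:5) {
    i <- i + 1
    got <- trajs[[roi]]$keypoints[f, 1, ]
    expect_lt(max(abs(got - plate_kp[[i]])), 0.5)
    expect_gt(trajs[[roi]]$confidence[f, 1], 0.9)
  }
})

test_that("a 24-ROI movie yields 24 trajectories of full length", {
  kp <- replicate(24 * 3, matrix(c(8.5, 8.5), 1), simplify = FALSE)
  oracle <- oracle_predictor(kp, 16L, 16L)
  grid <- make_roi_grid(4, 6, c(0, 0, 48, 32))
  frames <- replicate(3, matrix(0.5, 32, 48), simplify = FALSE)
  trajs <- track_movie(frames, oracle, grid, framerate = 100, mm_per_px = 0.1)
  expect_equal(length(trajs), 24L)
  expect_true(all(vapply(trajs, function(t) dim(t$keypoints)[1], numeric(1)) == 3))
})

test_that("a briefly trained network is more confident on fish than on background", {
  ds <- tiny_dataset(32, seed = 14)
  sp <- split_dataset(ds, 0.75, seed = 1)
  res <- train(build_network(tiny_net_cfg()), sp$train, sp$val,
               tiny_train_cfg(n_updates = 100L),
               ccfg = codec_config(correctness_radius = 2))
  conf_on <- function(img) {
    y <- predict_heatmaps(res$net, standardize(img, res$stats))
    max(y)
  }
  fish <- mean(vapply(sp$val$frames[1:4], conf_on, numeric(1)))
  blank <- conf_on(matrix(0.85, 64, 64)) # empty well, background only
  expect_gt(fish, blank)
})

test_that("exports round-trip CSVs and stamp the run summary", {
  script <- trajectory_script(
    framerate = 100, duration = 2, mm_per_px = 0.1,
    bout_schedule = data.frame(start = 0.5, duration = 0.3, peak_speed = 6),
    bend_schedule = data.frame(peak_time = 1.2, peak_angle = 120),
    body_length = 40)
  mv <- generate_trajectory_movie(script, scene_spec(frame_size = 256),
                                  render = FALSE)
  run <- analysis_run(list(mv$truth, mv$truth), seed = 7,
                      config = list(note = "synthetic"))
  dir <- withr::local_tempdir()
  files <- export_outputs(run, dir)
  csvs <- list.files(dir, pattern = "_trajectory\\.csv$")
  expect_equal(length(csvs), 2L) # one per ROI
  tab <- utils::read.csv(file.path(dir, "roi_01_trajectory.csv"))
  orig <- kinematics_table(mv$truth)
  expect_lt(max(abs(tab$x_0 - orig$x_0)), 1e-6)
  expect_lt(max(abs(tab$speed_mm_s - orig$speed_mm_s)), 1e-6)
  expect_true("rostral_caudal_angle_deg" %in% names(tab))
  expect_true(any(grepl("segment_angle_0_deg", names(tab))))
  bouts <- utils::read.csv(file.path(dir, "roi_01_bouts.csv"))
  expect_equal(nrow(bouts), 1L)
  summ <- jsonlite::fromJSON(file.path(dir, "run_summary.json"))
  expect_equal(summ$seed, 7)
  expect_true(nchar(summ$config_hash) == 8)
  expect_true(file.exists(file.path(dir, "roi_02_trajectory.png")))
})
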