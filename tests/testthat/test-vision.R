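test_that("a static scene becomes all-background after burn-in", {
  set.seed(1)
  frame <- matrix(150, 24, 24)
  model <- mog_init(frame, mog_params())
  mask <- NULL
  for (t in 1:60) {
    out <- segment_foreground(frame + round(rnorm(24 * 24, 0, 2)), model)
    model <- out$model
    mask <- out$mask
  }
  expect_false(any(mask))
})

test_that("a persistently jumping disk stays foreground", {
  frame0 <- matrix(150, 30, 30)
  model <- mog_init(frame0, mog_params())
  ok <- TRUE
  for (t in 1:45) {
    fr <- frame0
    # never revisits a position, so the mover is never absorbed
    r <- 3 + 3 * ((t - 1) %% 9)
    cc <- 3 + 3 * ((t - 1) %/% 9)
    fr[r:(r + 2), cc:(cc + 2)] <- 40
    out <- segment_foreground(fr, model)
    model <- out$model
    if (t > 10 && !all(out$mask[r:(r + 2), cc:(cc + 2)])) ok <- FALSE
  }
  expect_true(ok)
})

test_that("compiled MOG updates bit-match the straight-line R oracle", {
  p <- mog_params()
  frames <- oracle_fixture_frames()
  oracle <- mog_oracle_run(frames, p)
  model <- mog_init(frames[, , 1], p)
  for (t in seq_len(dim(frames)[3])) {
    out <- segment_foreground(frames[, , t], model)
    model <- out$model
    expect_identical(unname(out$mask == TRUE), unname(oracle$masks[, , t]))
  }
  expect_identical(as.numeric(model$w), as.numeric(oracle$w))
  expect_identical(as.numeric(model$mu), as.numeric(oracle$mu))
  expect_identical(as.numeric(model$v), as.numeric(oracle$v))
})

test_that("full-recording analysis agrees with oracle masks plus labelling", {
  p <- mog_params()
  frames <- oracle_fixture_frames(Tn = 30, seed = 9)
  oracle <- mog_oracle_run(frames, p)
  series <- analyze_recording(frames, fps = 10, duration = 3, burnin = 0,
                              params = p, min_area = 4, max_area = 100)
  for (t in seq_len(30)) {
    ref <- detect_blobs(oracle$masks[, , t], min_area = 4, max_area = 100)
    expect_equal(series$frames$count[t], nrow(ref))
  }
})

test_that("blob extraction follows the closed-form examples", {
  empty <- matrix(FALSE, 30, 30)
  expect_equal(nrow(detect_blobs(empty, min_area = 4)), 0)

  m <- matrix(FALSE, 40, 40)
  m[20:24, 10:14] <- TRUE
  b <- detect_blobs(m, min_area = 4)
  expect_equal(b$x, 12)
  expect_equal(b$y, 22)
  expect_equal(b$area, 25)

  # isolated pixels vanish under the area filter
  set.seed(2)
  sprinkle <- matrix(FALSE, 50, 50)
  sprinkle[cbind(seq(2, 48, by = 4), seq(2, 48, by = 4))] <- TRUE
  expect_equal(nrow(detect_blobs(sprinkle, min_area = 4)), 0)

  # diagonal-only contact is one 8-connected component
  diagm <- matrix(FALSE, 10, 10)
  diagm[cbind(3:6, 3:6)] <- TRUE
  expect_equal(nrow(detect_blobs(diagm, min_area = 2)), 1)
})

test_that("a 180-s recording at 0.1-s intervals yields 1800 analyzed frames", {
  frames <- array(120, c(12, 12, 1801))
  series <- analyze_recording(frames, fps = 10)
  expect_equal(nrow(series$frames), 1800)
  expect_equal(sum(series$frames$burnin), 10)
  # static scene: zero counts after burn-in
  expect_equal(sum(series$frames$count), 0)
})

test_that("frame-rate metadata is required and stride must be integer", {
  frames <- array(120, c(8, 8, 30))
  expect_error(analyze_recording(frames, duration = 1), "frame rate")
  expect_error(analyze_recording(frames, fps = 7, duration = 1), "stride")
  expect_error(analyze_recording(frames, fps = 10, duration = 180),
               "too short")
})

test_that("detection is deterministic and bounded on a noise-free fixture", {
  g <- test_geometry()
  p <- behavior_params(rate_C_to_F = 0, rate_F_to_C = 0, rate_F_to_N = 0,
                       rate_N_to_F = 0, rng_seed = 21)  # always flying
  truth <- simulate_cohort(p, g, duration = 20)
  frames <- render_video(truth, g, noise_sd = 0)
  s1 <- analyze_recording(frames, fps = 10, duration = 20)
  s2 <- analyze_recording(frames, fps = 10, duration = 20)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$blobs, s2$blobs)
  expect_true(all(s1$frames$count <= 5))
})

test_that("detection recovers the simulated cohort on the default fixture", {
  g <- cone_geometry()
  p <- net_presets("irritant", rng_seed = 31)
  truth <- simulate_cohort(p, g, duration = 60)
  frames <- render_video(truth, g, blob_radius = 3, noise_sd = 4, seed = 32)
  series <- analyze_recording(frames, fps = 10, duration = 60)
  sc <- score_detections(series, truth, radius = 3)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$frame_agreement, 0.9)
})

test_that("detection CSV round trip is lossless", {
  frames <- oracle_fixture_frames(Tn = 20, seed = 13)
  series <- analyze_recording(frames, fps = 10, duration = 2, burnin = 0.5,
                              min_area = 4, max_area = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(series, path)
  back <- read_detections_csv(path)
  expect_equal(back$frames$count, series$frames$count)
  expect_equal(back$blobs$x, series$blobs$x, tolerance = 1e-12)
  expect_equal(back$blobs$area, series$blobs$area)
})
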