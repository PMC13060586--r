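test_that("region assignment follows the declared midline convention", {
  g <- test_geometry()
  expect_equal(assign_region(g$center_x, g$apex_y, g), "top")
  expect_equal(unname(assign_region(g$center_x, g$net_edge["y"], g)),
               "bottom")
  # exactly on the midline -> bottom (net-proximal tie-break)
  expect_equal(assign_region(g$center_x, g$midline_y, g), "bottom")
  expect_equal(assign_region(g$center_x, g$midline_y - 1e-9, g), "top")
})

test_that("constant one-detection-per-frame series fills bins exactly", {
  g <- test_geometry()
  n <- 1800
  series <- manual_series(rep(1L, n), blob_x = rep(g$center_x, n),
                          blob_y = rep(g$base_y - 1, n))
  prof <- aggregate_bins(series, g)
  expect_equal(nrow(prof$bins), 36)
  expect_equal(prof$bins$bin_start_s, seq(0, 175, by = 5))
  expect_true(all(prof$bins$count_bottom == 50))
  expect_true(all(prof$bins$count_top == 0))
  expect_equal(prof$total_activity, 1800)
})

test_that("empty series aggregates to an all-zero profile", {
  g <- test_geometry()
  series <- manual_series(rep(0L, 1800), numeric(0), numeric(0))
  prof <- aggregate_bins(series, g)
  expect_equal(prof$total_activity, 0)
  expect_true(all(prof$bins$count_top == 0 & prof$bins$count_bottom == 0))
})

test_that("totals equal an independent sum over the exported CSV", {
  g <- test_geometry()
  truth <- simulate_cohort(net_presets("irritant", rng_seed = 41), g,
                           duration = 30)
  frames <- render_video(truth, g, noise_sd = 4, seed = 42)
  series <- analyze_recording(frames, fps = 10, duration = 30)
  prof <- aggregate_bins(series, g, bin_width = 5)
  # independent arithmetic: sum the count column of the CSV by hand
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(series, path)
  tab <- read.csv(path)
  expect_equal(prof$total_activity, sum(tab$count[!tab$burnin]))
  # region partition: every detection in exactly one region
  expect_equal(sum(prof$bins$count_top) + sum(prof$bins$count_bottom),
               prof$total_activity)
})

test_that("incomplete or mismatched series are rejected", {
  g <- test_geometry()
  short <- manual_series(rep(1L, 100), rep(30, 100), rep(20, 100))
  short$duration <- 180
  expect_error(aggregate_bins(short, g), "incomplete")
})

test_that("mean profile reproduces the closed-form two-replicate CI", {
  g <- test_geometry()
  mk <- function(k) {
    series <- manual_series(rep(k, 360), rep(g$center_x, 360 * k),
                            rep(g$base_y - 1, 360 * k), interval = 0.5)
    aggregate_bins(series, g, bin_width = 5)
  }
  p40 <- mk(4L)   # 40 per 5-s bin at 0.5-s interval
  p60 <- mk(6L)   # 60 per bin
  mp <- mean_profile(list(p40, p60))
  bot <- mp[mp$region == "bottom", ]
  expect_true(all(abs(bot$mean - 50) < 1e-12))
  half <- qt(0.975, 1) * sd(c(40, 60)) / sqrt(2)
  expect_equal(bot$ci_hi - bot$mean, rep(half, nrow(bot)), tolerance = 1e-9)
  # identical replicates collapse the band
  mp0 <- mean_profile(list(p40, p40))
  expect_true(all(abs(mp0$ci_hi - mp0$ci_lo) < 1e-9))
})

test_that("heterogeneous binning is rejected", {
  g <- test_geometry()
  a <- aggregate_bins(manual_series(rep(1L, 1800), rep(30, 1800),
                                    rep(40, 1800)), g)
  b <- aggregate_bins(manual_series(rep(1L, 360), rep(30, 360),
                                    rep(40, 360), interval = 0.5), g,
                      bin_width = 10)
  expect_error(mean_profile(list(a, b)), "binning")
})

test_that("profile CSV round trip preserves totals and bins", {
  g <- test_geometry()
  prof <- aggregate_bins(manual_series(rep(2L, 1800), rep(30, 3600),
                                       rep(10, 3600)), g,
                         assay_id = "a1", strain = "KS", net = "ctrl")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$total_activity, prof$total_activity)
  expect_equal(back$bins$count_top, prof$bins$count_top)
  expect_equal(back$assay_id, "a1")
})
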