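test_that("the content equation evaluates as printed", {
  expect_equal(content_per_round(x = 0, a = 100, m = 0.15), 0)
  # unit-factor identity: C = f = 1, x = a, m = 0.001 g -> 1 g/kg
  expect_equal(content_per_round(x = 120, a = 120, m = 0.001), 1)
  # arithmetic oracle: independent one-line re-evaluation
  set.seed(4)
  for (i in 1:20) {
    x <- runif(1, 0, 5000); a <- runif(1, 10, 500)
    m <- runif(1, 0.05, 0.3); C <- runif(1, 0.8, 1.2); f <- runif(1, 1, 10)
    expect_equal(content_per_round(x, a, m, C, f),
                 (x / a) * (0.001 / m) * C * f, tolerance = 1e-12)
  }
  expect_error(content_per_round(1, a = 0, m = 0.1), "slope")
  expect_error(content_per_round(1, a = 10, m = 0), "mass")
})

test_that("content is linear in x and f, inverse-linear in a and m", {
  base <- content_per_round(100, 50, 0.15, C = 1.1, f = 2)
  expect_equal(content_per_round(200, 50, 0.15, C = 1.1, f = 2), 2 * base)
  expect_equal(content_per_round(100, 50, 0.15, C = 1.1, f = 4), 2 * base)
  expect_equal(content_per_round(100, 100, 0.15, C = 1.1, f = 2), base / 2)
  expect_equal(content_per_round(100, 50, 0.30, C = 1.1, f = 2), base / 2)
})

test_that("multi-round totals track first-round extraction efficiency", {
  res <- total_content(c(97, 2, 1, 0))
  expect_equal(res$total, 100)
  expect_equal(res$first_round_fraction, 0.97)
  expect_false(res$qc_flag)
  expect_equal(total_content(42)$first_round_fraction, 1)
  expect_true(total_content(c(90, 5, 3, 2))$qc_flag)
})

test_that("areal conversion is dimensionally correct", {
  expect_equal(convert_to_areal(1.53, 0.1500, 50), 45.9)
  expect_equal(convert_to_areal(0, 0.15, 50), 0)
  expect_equal(convert_to_areal(2, 0.15, 100),
               convert_to_areal(2, 0.15, 50) / 2)
  expect_error(convert_to_areal(1, 0.15, 0), "area")
})

test_that("relative SD matches hand arithmetic", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(8, 10, 12)), 20)
  expect_error(rsd(c(-8, -10, -12)), "positive mean")
})

test_that("first-order Savitzky-Golay preserves linear signal exactly", {
  wn <- seq(400, 1600, by = 2)
  lin <- spectrum_trace(wn, 3 + 0.01 * wn)
  sm <- signal::sgolayfilt(lin$intensity, p = 1, n = 5)
  expect_equal(sm, lin$intensity, tolerance = 1e-8)
})

test_that("preprocessing yields a unit-norm spectrum, idempotently", {
  set.seed(6)
  syn <- make_synthetic_spectrum(noise_sd = 1)
  out <- preprocess_spectrum(syn$spectrum)
  expect_equal(sqrt(sum(out$intensity^2)), 1, tolerance = 1e-9)
  expect_true(all(out$flags))
  # re-normalising a normalised spectrum changes nothing
  y <- out$intensity
  expect_equal(y / sqrt(sum(y^2)), y, tolerance = 1e-12)
  expect_error(preprocess_spectrum(syn$spectrum, sg_window = 4), "odd")
  expect_error(preprocess_spectrum(syn$spectrum, sg_window = 5,
                                   sg_order = 5), "below")
})

test_that("ALS baseline recovers a known slow baseline away from peaks", {
  syn <- make_synthetic_spectrum(
    peaks = data.frame(center = c(800, 1200), height = c(60, 40),
                       width = c(6, 8)),
    baseline_coef = c(30, 15, -10), noise_sd = 0.5, seed = 7)
  est <- als_baseline(syn$spectrum$intensity)
  wn <- syn$spectrum$wavenumber
  away <- abs(wn - 800) > 40 & abs(wn - 1200) > 40 &
    wn > min(wn) + 30 & wn < max(wn) - 30
  rms <- sqrt(mean((est[away] - syn$baseline[away])^2))
  expect_lt(rms / sqrt(mean(syn$baseline[away]^2)), 0.05)
  # baseline never exceeds the signal maximum on nonnegative input
  expect_lte(max(est), max(syn$spectrum$intensity) + 1e-8)
})

test_that("the crystalline marker call responds to the 1000 1/cm band", {
  base <- list(center = c(942, 479), height = c(8, 8), width = c(4, 4))
  # flat noise spectrum -> amorphous-like, near-zero score
  flat <- make_synthetic_spectrum(peaks = data.frame(center = numeric(),
                                                     height = numeric(),
                                                     width = numeric()),
                                  baseline_coef = c(5, 2), noise_sd = 0.8,
                                  seed = 8)
  call_flat <- crystalline_marker(preprocess_spectrum(flat$spectrum))
  expect_equal(call_flat$call, "amorphous-like")
  expect_lt(call_flat$score, 5)

  # strong injected marker peak (10x noise) -> crystalline-like
  cryst <- make_synthetic_spectrum(
    peaks = data.frame(center = c(1000, base$center),
                       height = c(40, base$height),
                       width = c(4, base$width)),
    baseline_coef = c(5, 2), noise_sd = 0.8, seed = 9)
  call_c <- crystalline_marker(preprocess_spectrum(cryst$spectrum))
  expect_equal(call_c$call, "crystalline-like")
  expect_gte(call_c$score, 5)

  # same secondary bands without the marker -> amorphous-like
  amorph <- make_synthetic_spectrum(
    peaks = data.frame(center = base$center, height = base$height,
                       width = base$width),
    baseline_coef = c(5, 2), noise_sd = 0.8, seed = 10)
  call_a <- crystalline_marker(preprocess_spectrum(amorph$spectrum))
  expect_equal(call_a$call, "amorphous-like")
  expect_true(all(call_a$secondary_scores > call_a$score))

  expect_error(crystalline_marker(preprocess_spectrum(
    make_synthetic_spectrum(wavenumber = seq(600, 1800, 2))$spectrum)),
    "cover")
})

test_that("two-column spectrum files round-trip", {
  syn <- make_synthetic_spectrum(noise_sd = 0.3, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(syn$spectrum, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumber, syn$spectrum$wavenumber)
  expect_equal(back$intensity, syn$spectrum$intensity, tolerance = 1e-6)
  # descending axes are normalised to ascending
  rev_spec <- spectrum_trace(rev(syn$spectrum$wavenumber),
                             rev(syn$spectrum$intensity))
  expect_equal(rev_spec$wavenumber, syn$spectrum$wavenumber)
})
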