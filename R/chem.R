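#' Insecticide content from one HPLC extraction round
#'
#' Evaluates the content equation
#' `I = (x / a) * (0.001 / m) * C * f`
#' where `x` is the sample peak area, `a` the calibration-curve slope,
#' `m` the net sample mass in grams, `C` the internal-standard correction
#' factor and `f` the dilution factor.  Unit convention: `x / a` is the
#' concentration (ug/ml) of the 1-ml acetonitrile resuspension, and the
#' `0.001` factor converts ug to mg against the mass in grams, so `I` is
#' in g/kg.  `C` is accepted as an input; its derivation from internal
#' standard peak areas is instrument-specific.
#'
#' @param x Sample peak area (detector units, >= 0).
#' @param a Calibration slope (area per concentration unit, > 0).
#' @param m Net sample mass in grams (> 0).
#' @param C Internal-standard correction factor (default 1).
#' @param f Dilution factor (>= 1, default 1).
#' @return Insecticide content in g/kg.
#' @examples
#' content_per_round(x = 1500, a = 120, m = 0.15)
#' @export
content_per_round <- function(x, a, m, C = 1, f = 1) {
  stopifnot(x >= 0, f >= 1, C > 0)
  if (!all(a > 0)) stop("calibration slope `a` must be positive")
  if (!all(m > 0)) stop("sample mass `m` must be positive")
  (x / a) * (0.001 / m) * C * f
}

#' Total content over sequential extraction rounds
#'
#' Sums per-round contents (up to the 4 sequential extractions of the
#' standard protocol) and reports the first-round fraction.  A QC flag is
#' raised when less than 97% of the insecticide came out in the first
#' round, the efficiency expected of a working extraction.
#'
#' @param contents Numeric vector of per-round contents (round order),
#'   length 1-4.
#' @param qc_fraction First-round fraction below which the flag is raised.
#' @return A list with `total`, `fractions`, `first_round_fraction`,
#'   `qc_flag`.
#' @export
total_content <- function(contents, qc_fraction = 0.97) {
  stopifnot(length(contents) >= 1, length(contents) <= 4,
            all(contents >= 0))
  total <- sum(contents)
  fractions <- if (total > 0) contents / total else rep(NA_real_,
                                                        length(contents))
  first <- if (total > 0) fractions[1] else NA_real_
  list(total = total, fractions = fractions, first_round_fraction = first,
       qc_flag = isTRUE(first < qc_fraction))
}

#' Convert content in g/kg to areal density in mg/m2
#'
#' `I` g/kg equals mg/g, so areal density is
#' `I * mass_g / (area_cm2 * 1e-4)` mg/m2.  A typical net swatch is about
#' 50 cm2 and 0.15 g, so 1.53 g/kg corresponds to 45.9 mg/m2.
#'
#' @param content_g_kg Content in g/kg.
#' @param mass_g Sample mass in grams.
#' @param area_cm2 Sample area in cm2 (> 0).
#' @return Areal density in mg/m2.
#' @export
convert_to_areal <- function(content_g_kg, mass_g, area_cm2) {
  stopifnot(mass_g > 0)
  if (!all(area_cm2 > 0)) stop("sample area must be positive")
  content_g_kg * mass_g / area_cm2 * 1e4
}

#' Percent relative standard deviation
#'
#' `100 * sd / mean` with the sample SD; requires a positive mean.
#'
#' @param values Numeric vector, length >= 2.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m <= 0) stop("RSD requires a positive mean")
  100 * sd(values) / m
}

#' Construct a Raman spectrum trace
#'
#' @param wavenumber Strictly monotone axis in 1/cm.
#' @param intensity Intensities, same length.
#' @return A `spectrum_trace` with processing-state flags (`smoothed`,
#'   `baseline_corrected`, `normalized`), all `FALSE` initially.
#' @export
spectrum_trace <- function(wavenumber, intensity) {
  stopifnot(length(wavenumber) == length(intensity),
            length(wavenumber) >= 3)
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone")
  if (all(d < 0)) {
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 flags = c(smoothed = FALSE, baseline_corrected = FALSE,
                           normalized = FALSE)),
            class = "spectrum_trace")
}

#' Read / write two-column spectra
#'
#' Whitespace- or comma-separated text with wavenumber in the first column
#' and intensity in the second; comment lines starting with `#` are
#' skipped.
#'
#' @param path File path.
#' @return `read_spectrum()` returns a [spectrum_trace()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  parts <- strsplit(trimws(raw), "[,[:space:]]+")
  m <- do.call(rbind, lapply(parts, function(p) {
    p <- p[nzchar(p)]
    as.numeric(p[1:2])
  }))
  if (anyNA(m)) stop("could not parse two numeric columns from ", path)
  spectrum_trace(m[, 1], m[, 2])
}

#' @param s A `spectrum_trace`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum_trace"))
  writeLines(paste(format(s$wavenumber, trim = TRUE),
                   format(s$intensity, trim = TRUE)), path)
  invisible(path)
}

#' Asymmetric least squares baseline estimate
#'
#' Eilers-style penalised least squares: minimises
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, 2))^2)` with asymmetry
#' weights `p` for points above the running baseline and `1 - p` below,
#' iterated a fixed number of times.  Solved with sparse banded matrices.
#'
#' @param y Numeric signal.
#' @param lambda Smoothness penalty (default 1e5).
#' @param p Asymmetry weight in (0, 1) (default 0.01).
#' @param iters Number of reweighting iterations.
#' @return The baseline estimate, same length as `y`.
#' @export
als_baseline <- function(y, lambda = 1e5, p = 0.01, iters = 10) {
  n <- length(y)
  stopifnot(n >= 4, lambda > 0, p > 0, p < 1, iters >= 1)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + P, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Standard Raman preprocessing chain
#'
#' Savitzky-Golay smoothing (window 5, polynomial order 1 by default; a
#' first-order filter reproduces linear signal exactly), asymmetric least
#' squares baseline subtraction, then L2 (vector) normalisation.  Flags
#' are set in that order; normalisation is idempotent.
#'
#' @param s A [spectrum_trace()].
#' @param sg_window Odd SG window length (>= 3).
#' @param sg_order SG polynomial order (< `sg_window`).
#' @param als_lambda,als_p,als_iters Baseline parameters, see
#'   [als_baseline()].
#' @return The processed `spectrum_trace` (unit L2 norm).
#' @export
preprocess_spectrum <- function(s, sg_window = 5, sg_order = 1,
                                als_lambda = 1e5, als_p = 0.01,
                                als_iters = 10) {
  stopifnot(inherits(s, "spectrum_trace"))
  if (sg_window %% 2 == 0) stop("SG window must be odd")
  if (sg_order >= sg_window) stop("SG order must be below the window size")
  if (length(s$intensity) < sg_window)
    stop("spectrum shorter than the SG window")
  y <- signal::sgolayfilt(s$intensity, p = sg_order, n = sg_window)
  y <- y - als_baseline(y, lambda = als_lambda, p = als_p,
                        iters = als_iters)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("zero spectrum cannot be normalised")
  s$intensity <- y / nrm
  s$flags[] <- TRUE
  s
}

#' Crystallinity marker call from a preprocessed spectrum
#'
#' QC heuristic flagging spectra whose strongest crystalline-deltamethrin
#' marker band (1000 1/cm by default) stands out of the local noise.
#' Within `marker +/- window` the peak prominence is the maximum intensity
#' minus the median of the flanking regions (one to three windows away on
#' each side); local noise is the median absolute successive difference of
#' the flanks scaled to an SD.  The call is `"crystalline-like"` iff the
#' marker signal-to-noise score reaches `snr_threshold`; secondary bands
#' are scored the same way and reported but do not drive the call (a
#' spectrum with only the secondary particulate bands stays
#' `"amorphous-like"`).  This is a surface-QC heuristic, not a claim about
#' deltamethrin polymorph physics.
#'
#' @param s A preprocessed [spectrum_trace()].
#' @param marker Marker band position (1/cm).
#' @param secondary Secondary band positions (1/cm).
#' @param window Half-window in 1/cm.
#' @param snr_threshold Score at or above which the call is
#'   crystalline-like.
#' @return A list with `call`, `score`, `prominence`, `noise` and
#'   `secondary_scores`.
#' @export
crystalline_marker <- function(s, marker = 1000, secondary = c(942, 479),
                               window = 5, snr_threshold = 5) {
  stopifnot(inherits(s, "spectrum_trace"))
  wn <- s$wavenumber
  rng <- range(wn)
  for (m in c(marker, secondary)) {
    if (m - 3 * window < rng[1] || m + 3 * window > rng[2])
      stop("spectrum axis does not cover the ", m, " 1/cm marker window")
  }
  score_at <- function(m) {
    inw <- wn >= m - window & wn <= m + window
    flank <- (wn >= m - 3 * window & wn < m - window) |
      (wn > m + window & wn <= m + 3 * window)
    prom <- max(s$intensity[inw]) - median(s$intensity[flank])
    noise <- median(abs(diff(s$intensity[flank]))) / 0.954
    if (noise <= .Machine$double.eps) noise <- .Machine$double.eps
    c(prominence = prom, noise = noise,
      score = max(prom, 0) / noise)
  }
  mk <- score_at(marker)
  sec <- vapply(secondary, function(m) score_at(m)["score"], numeric(1))
  names(sec) <- paste0(secondary, "cm-1")
  list(call = if (mk["score"] >= snr_threshold) "crystalline-like"
       else "amorphous-like",
       score = unname(mk["score"]), prominence = unname(mk["prominence"]),
       noise = unname(mk["noise"]), secondary_scores = sec)
}

#' Generate a synthetic Raman spectrum with known structure
#'
#' Gaussian peaks on a polynomial baseline with white noise -- the fixture
#' generator used to validate the preprocessing chain against a known
#' baseline and the marker call against injected peaks.
#'
#' @param wavenumber Axis (default 300-1800 1/cm at 2 1/cm).
#' @param peaks Data frame with columns `center`, `height`, `width` (SD in
#'   1/cm); may have 0 rows.
#' @param baseline_coef Polynomial baseline coefficients (intercept
#'   first), evaluated on a 0-1 rescaled axis.
#' @param noise_sd White-noise SD.
#' @param seed Optional seed.
#' @return A list with `spectrum` (a [spectrum_trace()]) and the true
#'   `baseline` vector.
#' @export
make_synthetic_spectrum <- function(wavenumber = seq(300, 1800, by = 2),
                                    peaks = data.frame(center = 1200,
                                                       height = 50,
                                                       width = 8),
                                    baseline_coef = c(20, 10, -6),
                                    noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  baseline <- rowSums(vapply(seq_along(baseline_coef), function(k)
    baseline_coef[k] * u^(k - 1), numeric(length(u))))
  y <- baseline
  if (nrow(peaks)) {
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$height[i] *
        exp(-(wavenumber - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  list(spectrum = spectrum_trace(wavenumber, y), baseline = baseline)
}
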