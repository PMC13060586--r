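#' Parameters of the mixture-of-Gaussians background model
#'
#' Per-pixel adaptive background subtraction in the Stauffer-Grimson
#' style: each pixel carries `n_components` Gaussian components with
#' weight, mean and variance.  A pixel is foreground iff no component of
#' the top-weighted set covering cumulative weight `background_threshold`
#' matches it within `match_sd` standard deviations.  The matched
#' component is updated with `learning_rate`; unmatched pixels replace the
#' weakest component.
#'
#' Defaults (`K = 3`, `match_sd = 2.5`, `T = 0.9`, `alpha = 0.02`,
#' variance floor 4) are standard for this family of models.  Note the
#' semantics this implies: a mosquito resting motionless is absorbed into
#' the background within a few frames and stops being counted, so
#' "activity" means movement events, not presence.
#'
#' @param n_components Number of mixture components per pixel.
#' @param learning_rate Adaptation rate `alpha` in (0, 1).
#' @param background_threshold Cumulative weight `T` in (0, 1) defining the
#'   background component set.
#' @param match_sd Match threshold `lambda` in standard deviations.
#' @param var_floor Lower bound on component variance (gray levels squared).
#' @param init_var Variance given to newly created components.
#' @param new_weight Weight given to a replacement component before
#'   renormalisation.
#' @return An object of class `mog_params`.
#' @export
mog_params <- function(n_components = 3, learning_rate = 0.02,
                       background_threshold = 0.9, match_sd = 2.5,
                       var_floor = 4, init_var = 100, new_weight = 0.05) {
  stopifnot(n_components >= 1, n_components <= 16,
            learning_rate > 0, learning_rate < 1,
            background_threshold > 0, background_threshold < 1,
            match_sd > 0, var_floor > 0, init_var >= var_floor,
            new_weight > 0, new_weight < 1)
  structure(list(n_components = as.integer(n_components),
                 learning_rate = learning_rate,
                 background_threshold = background_threshold,
                 match_sd = match_sd, var_floor = var_floor,
                 init_var = init_var, new_weight = new_weight),
            class = "mog_params")
}

#' Initialise a background model from a first frame
#'
#' Component 1 of every pixel is seeded with the pixel's value at full
#' weight; the remaining components start empty (weight 0).
#'
#' @param frame A numeric matrix of gray levels.
#' @param params A [mog_params()].
#' @return A `mog_model`: arrays `w`, `mu`, `v` of dimension
#'   H x W x K plus the parameters.
#' @export
mog_init <- function(frame, params = mog_params()) {
  stopifnot(is.matrix(frame), inherits(params, "mog_params"))
  H <- nrow(frame); W <- ncol(frame); K <- params$n_components
  w <- array(0, c(H, W, K))
  mu <- array(0, c(H, W, K))
  v <- array(params$init_var, c(H, W, K))
  w[, , 1] <- 1
  mu[, , 1] <- frame
  structure(list(w = w, mu = mu, v = v, params = params,
                 dim = c(H, W)), class = "mog_model")
}

#' Segment the moving foreground of one frame
#'
#' Classifies each pixel against the current background model and updates
#' the model in the same pass.  The caller receives the post-update model;
#' the foreground decision itself is made against the pre-update state.
#'
#' @param frame A numeric matrix matching the model dimensions.
#' @param model A `mog_model` from [mog_init()].
#' @return A list with `mask` (logical matrix, `TRUE` = foreground) and
#'   `model` (the updated `mog_model`).
#' @export
segment_foreground <- function(frame, model) {
  stopifnot(inherits(model, "mog_model"), is.matrix(frame))
  if (!all(dim(frame) == model$dim))
    stop("frame dimensions do not match the background model")
  p <- model$params
  out <- mog_segment_cpp(frame, as.numeric(model$w), as.numeric(model$mu),
                         as.numeric(model$v), p$n_components,
                         p$learning_rate, p$background_threshold,
                         p$match_sd, p$var_floor, p$init_var, p$new_weight)
  K <- p$n_components
  dm <- c(model$dim, K)
  model$w <- array(out$w, dm)
  model$mu <- array(out$mu, dm)
  model$v <- array(out$v, dm)
  list(mask = out$mask, model = model)
}

#' Extract blobs from a binary foreground mask
#'
#' 8-connected components with pixel area in `[min_area, max_area]`.
#' Centroids are unweighted pixel-coordinate means, 1-based, with
#' `x` = column and `y` = row.
#'
#' @param mask A logical matrix.
#' @param min_area,max_area Area bounds in pixels squared
#'   (`0 < min_area < max_area`).
#' @return A data frame with columns `x`, `y`, `area` (possibly 0 rows).
#' @examples
#' m <- matrix(FALSE, 40, 40)
#' m[20:24, 10:14] <- TRUE
#' detect_blobs(m, min_area = 4)   # centroid (12, 22), area 25
#' @export
detect_blobs <- function(mask, min_area = 6, max_area = 400) {
  stopifnot(is.logical(mask), is.matrix(mask),
            min_area > 0, max_area > min_area)
  label_blobs_cpp(mask, min_area, max_area)
}

#' Analyze a cone-test recording into a detection series
#'
#' The automated movement-detection stage: frames are subsampled to one
#' per `interval` seconds (subsampling precedes segmentation, so the model
#' only ever sees analyzed frames), segmented against the adaptive
#' background model, and reduced to per-frame moving-blob counts and
#' centroids.  A standard 180-s assay at 0.1-s intervals yields exactly
#' 1800 analyzed frames.  The first `burnin` seconds are processed for
#' model adaptation but reported with count 0 and flagged, since the model
#' needs initialisation.
#'
#' @param frames An H x W x T array of gray levels, or a directory written
#'   by [write_frames_png()].
#' @param fps Source frame rate; defaults to the `fps` attribute of
#'   `frames`.  `fps * interval` must be a whole-number stride.
#' @param interval Analysis interval in seconds.
#' @param duration Assay duration in seconds; the recording must cover it.
#'   Defaults to 180.
#' @param burnin Burn-in period in seconds (default 1).
#' @param params A [mog_params()].
#' @param min_area,max_area Blob area filter, as in [detect_blobs()].
#' @return A `detection_series`: list with `frames` (data frame
#'   `frame_index` (0-based), `time_s`, `count`, `burnin`) and `blobs`
#'   (data frame `frame_index`, `x`, `y`, `area`), plus `interval` and
#'   `duration`.
#' @export
analyze_recording <- function(frames, fps = NULL, interval = 0.1,
                              duration = 180, burnin = 1,
                              params = mog_params(), min_area = 6,
                              max_area = 400) {
  if (is.character(frames)) frames <- read_frames_png(frames)
  stopifnot(length(dim(frames)) == 3)
  if (is.null(fps)) fps <- attr(frames, "fps")
  if (is.null(fps))
    stop("frame rate unknown: supply `fps` (no metadata found)")
  stride <- fps * interval
  if (abs(stride - round(stride)) > 1e-8)
    stop("`fps * interval` must be a whole-number frame stride")
  stride <- as.integer(round(stride))
  n_analyzed <- duration / interval
  if (abs(n_analyzed - round(n_analyzed)) > 1e-8)
    stop("`interval` must divide `duration`")
  n_analyzed <- as.integer(round(n_analyzed))
  idx <- 1L + (0:(n_analyzed - 1L)) * stride
  if (max(idx) > dim(frames)[3])
    stop(sprintf("recording too short: need %d frames at stride %d, have %d",
                 max(idx), stride, dim(frames)[3]))
  sub <- frames[, , idx, drop = FALSE]
  burnin_frames <- as.integer(round(burnin / interval))
  det <- mog_detect_cpp(as.numeric(sub), dim(sub)[1], dim(sub)[2],
                        n_analyzed, params$n_components,
                        params$learning_rate, params$background_threshold,
                        params$match_sd, params$var_floor, params$init_var,
                        params$new_weight, min_area, max_area,
                        burnin_frames)
  frames_df <- data.frame(
    frame_index = 0:(n_analyzed - 1L),
    time_s = round((0:(n_analyzed - 1L)) * interval, 6),
    count = as.integer(det$counts),
    burnin = seq_len(n_analyzed) <= burnin_frames)
  blobs_df <- data.frame(frame_index = det$blob_frame, x = det$blob_x,
                         y = det$blob_y, area = det$blob_area)
  structure(list(frames = frames_df, blobs = blobs_df,
                 interval = interval, duration = duration,
                 burnin = burnin), class = "detection_series")
}

#' Write / read a detection series as CSV
#'
#' One row per analyzed frame: `frame_index, time_s, count, burnin,
#' centroids`, where `centroids` is a JSON-encoded list of
#' `[x, y, area]` triples, so the round trip is lossless.
#'
#' @param series A `detection_series` from [analyze_recording()].
#' @param path File path.
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns a `detection_series`.
#' @export
write_detections_csv <- function(series, path) {
  stopifnot(inherits(series, "detection_series"))
  fr <- series$frames
  cents <- vapply(fr$frame_index, function(i) {
    b <- series$blobs[series$blobs$frame_index == i, , drop = FALSE]
    as.character(jsonlite::toJSON(unname(as.matrix(b[, c("x", "y", "area")])),
                                  digits = NA))
  }, character(1))
  out <- cbind(fr, centroids = cents)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "time_s", "count", "burnin", "centroids")
  if (!all(need %in% names(tab)))
    stop("not a detection series CSV")
  blobs <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    m <- jsonlite::fromJSON(tab$centroids[i])
    if (!length(m)) return(NULL)
    m <- matrix(m, ncol = 3)
    data.frame(frame_index = tab$frame_index[i], x = m[, 1], y = m[, 2],
               area = m[, 3])
  }))
  if (is.null(blobs))
    blobs <- data.frame(frame_index = integer(), x = numeric(),
                        y = numeric(), area = numeric())
  interval <- if (nrow(tab) > 1) tab$time_s[2] - tab$time_s[1] else NA_real_
  structure(list(frames = tab[, c("frame_index", "time_s", "count",
                                  "burnin")],
                 blobs = blobs, interval = interval,
                 duration = nrow(tab) * interval,
                 burnin = sum(tab$burnin) * interval),
            class = "detection_series")
}
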