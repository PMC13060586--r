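#' Static background image for a cone recording
#'
#' A light scene with the cone silhouette shaded slightly darker and the
#' net edge drawn as a dark line, standing in for the static part of a
#' smartphone recording.
#'
#' @param geometry A [cone_geometry()].
#' @param outside_gray,cone_gray,net_gray Gray levels (0-255).
#' @return A `frame_height` x `frame_width` numeric matrix.
#' @export
cone_background <- function(geometry, outside_gray = 180, cone_gray = 150,
                            net_gray = 120) {
  H <- geometry$frame_height
  W <- geometry$frame_width
  bg <- matrix(outside_gray, H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  bg[in_cone(geometry, xs, ys)] <- cone_gray
  yr <- round(geometry$base_y)
  if (yr >= 1 && yr <= H) {
    cols <- seq(ceiling(geometry$net_edge["x0"]),
                floor(geometry$net_edge["x1"]))
    bg[yr, cols] <- net_gray
  }
  bg
}

#' Render a truth log as a grayscale frame stack
#'
#' One frame per truth time point: the static background plus one filled
#' disk per agent at its truth position plus i.i.d. Gaussian pixel noise,
#' rounded and clipped to 0-255 (so PNG export is lossless).  Agents closer
#' than about one blob radius merge into a single blob -- the realistic
#' occlusion failure mode for the detector, which is documented rather than
#' avoided.
#'
#' @param truth A `truth_log` from [simulate_cohort()].
#' @param geometry A [cone_geometry()]; defaults to the geometry attached to
#'   `truth`.
#' @param blob_radius Disk radius in pixels (>= 1).
#' @param agent_intensity Disk gray level; keep
#'   `|agent_intensity - cone_gray| > 3 * noise_sd` for detectable agents.
#' @param noise_sd Gaussian pixel noise SD in gray levels.
#' @param seed Optional seed for the noise stream.
#' @return A `frame_height` x `frame_width` x `n_frames` numeric array of
#'   integer-valued gray levels with attributes `fps` and `blob_radius`.
#' @export
render_video <- function(truth, geometry = attr(truth, "geometry"),
                         blob_radius = 3, agent_intensity = 40,
                         noise_sd = 4, seed = NULL) {
  stopifnot(inherits(truth, "truth_log"), blob_radius >= 1)
  if (is.null(geometry))
    stop("no geometry attached to `truth`; pass `geometry` explicitly")
  if (geometry$frame_width < 2 * geometry$base_halfwidth)
    stop("geometry is larger than the frame")
  n_agents <- length(unique(truth$agent_id))
  nt <- nrow(truth) / n_agents
  xs <- matrix(truth$x, nrow = nt, ncol = n_agents, byrow = TRUE)
  ys <- matrix(truth$y, nrow = nt, ncol = n_agents, byrow = TRUE)
  bg <- cone_background(geometry)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  frames <- render_frames_cpp(bg, xs, ys, blob_radius, agent_intensity,
                              noise_sd)
  dt <- attr(truth, "dt")
  attr(frames, "fps") <- if (!is.null(dt) && is.finite(dt)) 1 / dt else NULL
  attr(frames, "blob_radius") <- blob_radius
  frames
}

#' Write / read a frame stack as a numbered PNG image sequence
#'
#' Frames are written as 8-bit grayscale `frame_000001.png`,
#' `frame_000002.png`, ... in `dir`.  Because rendered frames hold integer
#' gray levels, the round trip is lossless.
#'
#' @param frames An H x W x T array with values in 0-255.
#' @param dir Directory (created if needed).
#' @param fps Frames per second stored alongside the images (in `fps.txt`)
#'   so the analysis stage can recover timing; defaults to the `fps`
#'   attribute of `frames`.
#' @return `write_frames_png()` returns `dir` invisibly;
#'   `read_frames_png()` returns the H x W x T array with an `fps`
#'   attribute when available.
#' @export
write_frames_png <- function(frames, dir, fps = attr(frames, "fps")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(frames)[3]
  for (t in seq_len(nt)) {
    png::writePNG(frames[, , t] / 255,
                  file.path(dir, sprintf("frame_%06d.png", t)))
  }
  if (!is.null(fps))
    writeLines(format(fps), file.path(dir, "fps.txt"))
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files found in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- first[, , 1]
  frames <- array(0, c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- round(first * 255)
  for (t in seq_along(files)[-1]) {
    img <- png::readPNG(files[t])
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[, , t] <- round(img * 255)
  }
  fps_file <- file.path(dir, "fps.txt")
  if (file.exists(fps_file))
    attr(frames, "fps") <- as.numeric(readLines(fps_file)[1])
  frames
}
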