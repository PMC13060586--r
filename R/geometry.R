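#' Cone geometry for a video cone test
#'
#' Describes the projected silhouette of the WHO plastic cone as seen by the
#' camera: an isosceles trapezoid with the apex up and the net edge along the
#' base.  Image coordinates are used throughout the package: `x` is the
#' column, `y` the row, and `y` increases downward, so the "top" of the cone
#' (the apex) has the *smaller* `y`.  `midline_y` splits the cone region of
#' interest into upper and lower halves.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param apex_y,base_y Rows of the cone apex and base (net edge);
#'   `apex_y < base_y`.
#' @param apex_halfwidth,base_halfwidth Half-widths of the silhouette at the
#'   apex and at the base, in pixels.
#' @param center_x Column of the cone axis.
#'
#' @return An object of class `cone_geometry`: a list with the arguments
#'   above plus `cone_outline` (a polygon matrix with columns `x`, `y`),
#'   `net_edge` (`x0`, `x1`, `y`) and `midline_y`.
#' @examples
#' geom <- cone_geometry()
#' geom$midline_y
#' @export
cone_geometry <- function(frame_width = 128, frame_height = 96,
                          apex_y = 8, base_y = 88,
                          apex_halfwidth = 8, base_halfwidth = 52,
                          center_x = frame_width / 2) {
  stopifnot(frame_width >= 8, frame_height >= 8,
            apex_y >= 1, base_y <= frame_height, apex_y < base_y,
            apex_halfwidth >= 1, base_halfwidth > apex_halfwidth)
  if (center_x - base_halfwidth < 1 || center_x + base_halfwidth > frame_width)
    stop("cone silhouette does not fit inside the frame")
  outline <- cbind(
    x = c(center_x - apex_halfwidth, center_x + apex_halfwidth,
          center_x + base_halfwidth, center_x - base_halfwidth),
    y = c(apex_y, apex_y, base_y, base_y))
  g <- list(frame_width = frame_width, frame_height = frame_height,
            apex_y = apex_y, base_y = base_y,
            apex_halfwidth = apex_halfwidth,
            base_halfwidth = base_halfwidth, center_x = center_x,
            cone_outline = outline,
            net_edge = c(x0 = center_x - base_halfwidth,
                         x1 = center_x + base_halfwidth, y = base_y),
            midline_y = (apex_y + base_y) / 2)
  class(g) <- "cone_geometry"
  g
}

#' Half-width of the cone silhouette at a given row
#' @param geometry A [cone_geometry()].
#' @param y Row coordinate(s).
#' @return Half-width(s) in pixels.
#' @keywords internal
cone_halfwidth <- function(geometry, y) {
  with(geometry, apex_halfwidth + (base_halfwidth - apex_halfwidth) *
         (y - apex_y) / (base_y - apex_y))
}

#' Test whether points lie inside the cone silhouette
#' @param geometry A [cone_geometry()].
#' @param x,y Point coordinates (vectorised).
#' @return Logical vector; boundary points count as inside.
#' @export
in_cone <- function(geometry, x, y) {
  ok <- y >= geometry$apex_y & y <= geometry$base_y
  hw <- cone_halfwidth(geometry, pmin(pmax(y, geometry$apex_y),
                                      geometry$base_y))
  ok & abs(x - geometry$center_x) <= hw
}

#' Assign detections to the upper or lower half of the cone
#'
#' A centroid is `"top"` iff its `y` is strictly above `midline_y`
#' (remember `y` grows downward, so "above" means `y < midline_y`).  Points
#' exactly on the midline are assigned to `"bottom"`, the net-proximal
#' region.
#'
#' @param x,y Centroid coordinates (vectorised; `x` unused for the split but
#'   kept for interface symmetry).
#' @param geometry A [cone_geometry()].
#' @return Character vector of `"top"` / `"bottom"`.
#' @examples
#' g <- cone_geometry()
#' assign_region(g$center_x, g$apex_y, g)   # apex -> "top"
#' assign_region(g$center_x, g$base_y, g)   # net edge -> "bottom"
#' @export
assign_region <- function(x, y, geometry) {
  ifelse(y < geometry$midline_y, "top", "bottom")
}
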