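# Flat-screen viewing geometry: pixels <-> degrees of visual angle, and
# eccentricity-dependent pixel margins around AOI boxes.

#' Physical model of the wide three-panel display
#'
#' Describes the display used for wide-field gaze recording: three coplanar
#' monitor panels in a linear formation, treated as one continuous pixel grid
#' of `width_px` x `height_px`. The viewer sits at `viewing_distance_cm` from
#' the center of the central panel, so a horizontal pixel offset `x` (centered
#' coordinates) subtends `atan(x * pitch / d)` degrees of visual angle.
#'
#' Centered coordinates place (0,0) at the display center, +x rightward and
#' +y downward; all downstream gaze/AOI math uses this convention.
#'
#' The physical bezels between adjacent panels are represented twice: as a
#' pixel-space correction (`bezel_px` video pixels occluded per junction,
#' metadata used only by rendering) and as physical width (`bezel_cm` per
#' bezel edge) entering the field-of-view computation.
#'
#' @param width_px Total display width in pixels (default 5760 = 3 x 1920).
#' @param height_px Display height in pixels (default 1200).
#' @param pixel_pitch_cm Physical size of one pixel in cm. The default
#'   0.02692 corresponds to a 24-inch 16:10 panel (51.69 cm / 1920 px).
#' @param viewing_distance_cm Eye-to-screen-center distance in cm (default 65).
#' @param n_panels Number of panels in the row (default 3).
#' @param bezel_px Pixel-space bezel correction per junction (metadata).
#' @param bezel_cm Physical width of a single bezel edge in cm (default 0.68).
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(2880, geom)          # right edge of the display
#' field_of_view_deg(geom)        # ~101 degrees
#' @export
screen_geometry <- function(width_px = 5760L, height_px = 1200L,
                            pixel_pitch_cm = 0.02692,
                            viewing_distance_cm = 65,
                            n_panels = 3L,
                            bezel_px = 50L, bezel_cm = 0.68) {
  stopifnot(width_px > 0, height_px > 0, pixel_pitch_cm > 0,
            viewing_distance_cm > 0, n_panels >= 1,
            bezel_px >= 0, bezel_cm >= 0)
  if (width_px %% 2 != 0) {
    stop("width_px must be even so the display center falls on a pixel boundary")
  }
  panel_w <- width_px / n_panels
  junctions <- if (n_panels > 1) panel_w * seq_len(n_panels - 1) else numeric(0)
  structure(
    list(width_px = as.numeric(width_px),
         height_px = as.numeric(height_px),
         pixel_pitch_cm = pixel_pitch_cm,
         viewing_distance_cm = viewing_distance_cm,
         n_panels = as.integer(n_panels),
         bezel_px = as.numeric(bezel_px),
         bezel_cm = bezel_cm,
         junction_positions_px = junctions),
    class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g px, %d panel(s), pitch %.5f cm/px, d = %g cm\n",
              x$width_px, x$height_px, x$n_panels,
              x$pixel_pitch_cm, x$viewing_distance_cm))
  cat(sprintf("  horizontal field of view: %.1f deg\n", field_of_view_deg(x)))
  invisible(x)
}

#' Convert centered pixel offsets to degrees of visual angle
#'
#' Flat-screen tangent mapping: `theta = atan(px * pitch / d)`, signed.
#' Works identically for horizontal and vertical offsets since the panels
#' share one pixel pitch.
#'
#' @param px Pixel offsets from the display center (vectorized).
#' @param geom A [screen_geometry()].
#' @return Visual angles in degrees, same sign as `px`.
#' @export
px_to_deg <- function(px, geom) {
  atan(px * geom$pixel_pitch_cm / geom$viewing_distance_cm) * 180 / pi
}

#' Convert degrees of visual angle to centered pixel offsets
#'
#' Inverse of [px_to_deg()]: `px = (d / pitch) * tan(theta)`.
#'
#' @param deg Visual angles in degrees; must satisfy `abs(deg) < 90`.
#' @param geom A [screen_geometry()].
#' @return Pixel offsets from the display center.
#' @export
deg_to_px <- function(deg, geom) {
  if (any(abs(deg) >= 90)) {
    stop("deg_to_px is undefined at or beyond 90 degrees eccentricity")
  }
  tan(deg * pi / 180) * geom$viewing_distance_cm / geom$pixel_pitch_cm
}

#' Total horizontal field of view of the display
#'
#' Computed from the physical half-width of the panel row seen from the
#' viewing distance. With `include_bezels = TRUE` the four inter-panel bezel
#' edges (two per junction) add their physical width; the outer bezels lie
#' beyond the last pixel and are not counted.
#'
#' @param geom A [screen_geometry()].
#' @param include_bezels Include inter-panel bezel width (default TRUE).
#' @return Field of view in degrees.
#' @export
field_of_view_deg <- function(geom, include_bezels = TRUE) {
  panel_cm <- geom$width_px * geom$pixel_pitch_cm
  # two bezel edges per junction
  bezels_cm <- if (include_bezels) 2 * (geom$n_panels - 1) * geom$bezel_cm else 0
  half_cm <- (panel_cm + bezels_cm) / 2
  2 * atan(half_cm / geom$viewing_distance_cm) * 180 / pi
}

#' Eccentricity-dependent pixel margins around an AOI box
#'
#' Expands a visual-angle margin `margin_deg` into per-side pixel distances
#' for an AOI bounding box in centered display coordinates. Because the
#' display is flat and wide, a fixed visual angle covers more pixels towards
#' the periphery, so the left and right margins are computed separately at
#' the box's own edges:
#' \deqn{right = deg2px(px2deg(x_{right}) + m) - x_{right}}
#' \deqn{left  = x_{left} - deg2px(px2deg(x_{left}) - m)}
#' Top and bottom margins are both evaluated at the box's center
#' y-coordinate in the vertical direction (same pitch and distance) and are
#' equal. All margins are clamped at zero; `margin_deg = 0` yields exact
#' zeros. The expanded box may exceed the display bounds; matching handles
#' off-screen gaze separately.
#'
#' @param box A data.frame (one or more rows) with columns `x_left`,
#'   `x_right`, `y_top`, `y_bottom` in centered pixels.
#' @param margin_deg Margin in degrees of visual angle, scalar `>= 0`.
#' @param geom A [screen_geometry()].
#' @return A data.frame with columns `left_px`, `right_px`, `top_px`,
#'   `bottom_px`, one row per input box.
#' @export
margins_for_box <- function(box, margin_deg, geom) {
  stopifnot(is.numeric(margin_deg), length(margin_deg) == 1L, margin_deg >= 0)
  n <- length(box$x_left)
  if (margin_deg == 0) {
    z <- numeric(n)
    return(data.frame(left_px = z, right_px = z, top_px = z, bottom_px = z))
  }
  right <- deg_to_px(px_to_deg(box$x_right, geom) + margin_deg, geom) - box$x_right
  left <- box$x_left - deg_to_px(px_to_deg(box$x_left, geom) - margin_deg, geom)
  yc <- (box$y_top + box$y_bottom) / 2
  th <- abs(px_to_deg(yc, geom))
  tb <- deg_to_px(th + margin_deg, geom) - deg_to_px(th, geom)
  data.frame(left_px = pmax(left, 0), right_px = pmax(right, 0),
             top_px = pmax(tb, 0), bottom_px = pmax(tb, 0))
}
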