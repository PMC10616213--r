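# Toolkit configuration (YAML) and the fiducial-marker layout helper.

#' Toolkit configuration
#'
#' Bundles every tunable of the analysis chain: display geometry, gaze
#' preprocessing parameters, matching parameters, the margin sweep, and
#' overlay style. Defaults reproduce the validated wide-screen setup:
#' confidence gate 0.8, 75 ms interpolation limit, 100 ms gap pad, 100 ms
#' merge and minimum-dwell thresholds, 240 Hz resampling, 25 fps stimulus,
#' 65 cm viewing distance, 5760 x 1200 px display.
#'
#' @param geometry A [screen_geometry()].
#' @param preprocess A [preprocess_params()].
#' @param match A [match_params()].
#' @param margins_deg Margin sweep in degrees (default 0, 0.5, 1, 1.5, 2).
#' @param style An [overlay_style()].
#' @return An object of class `toolkit_config`.
#' @export
toolkit_config <- function(geometry = screen_geometry(),
                           preprocess = preprocess_params(),
                           match = match_params(),
                           margins_deg = c(0, 0.5, 1, 1.5, 2),
                           style = overlay_style()) {
  stopifnot(inherits(geometry, "screen_geometry"),
            inherits(preprocess, "preprocess_params"),
            inherits(match, "match_params"),
            is.numeric(margins_deg), all(margins_deg >= 0))
  structure(list(geometry = geometry, preprocess = preprocess,
                 match = match, margins_deg = margins_deg, style = style),
            class = "toolkit_config")
}

#' Read / write a toolkit configuration as YAML
#'
#' Only scalar fields are serialized; missing blocks fall back to the
#' defaults of the corresponding constructor, so partial configs are valid.
#'
#' @param config A [toolkit_config()].
#' @param path YAML file path.
#' @return `write_toolkit_config` returns `path` invisibly;
#'   `read_toolkit_config` returns a `toolkit_config`.
#' @export
write_toolkit_config <- function(config, path) {
  g <- config$geometry
  lst <- list(
    geometry = list(width_px = g$width_px, height_px = g$height_px,
                    pixel_pitch_cm = g$pixel_pitch_cm,
                    viewing_distance_cm = g$viewing_distance_cm,
                    n_panels = g$n_panels, bezel_px = g$bezel_px,
                    bezel_cm = g$bezel_cm),
    preprocess = unclass(config$preprocess),
    match = unclass(config$match),
    margins_deg = config$margins_deg,
    style = unclass(config$style))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_toolkit_config
#' @export
read_toolkit_config <- function(path) {
  lst <- yaml::read_yaml(path)
  toolkit_config(
    geometry = do.call(screen_geometry, as.list(lst$geometry %||% list())),
    preprocess = do.call(preprocess_params, as.list(lst$preprocess %||% list())),
    match = do.call(match_params, as.list(lst$match %||% list())),
    margins_deg = unlist(lst$margins_deg %||% c(0, 0.5, 1, 1.5, 2)),
    style = do.call(overlay_style, as.list(lst$style %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fiducial-marker placement layout for the display
#'
#' Computes the deterministic placement of the on-screen fiducial markers
#' used for surface tracking: four enlarged corner markers (better
#' detection at large viewing angles) plus smaller markers distributed
#' along the top and bottom edges. The default (22 markers of 80 px, the
#' four corners at 160 px) matches the validated 5760 x 1200 setup.
#'
#' @param geom A [screen_geometry()].
#' @param tag_width_px Width of the regular markers (default 80).
#' @param corner_width_px Width of the four corner markers (default 160).
#' @param n_onscreen Total number of on-screen markers (default 22).
#' @return A data.frame with columns `tag_id`, `x`, `y`, `width` in
#'   top-left display coordinates; empty for `n_onscreen = 0`.
#' @export
marker_layout <- function(geom = screen_geometry(), tag_width_px = 80,
                          corner_width_px = 160, n_onscreen = 22L) {
  stopifnot(tag_width_px > 0, corner_width_px > 0, n_onscreen >= 0)
  if (n_onscreen == 0) {
    return(data.frame(tag_id = integer(0), x = numeric(0), y = numeric(0),
                      width = numeric(0)))
  }
  W <- geom$width_px; H <- geom$height_px
  cw <- corner_width_px; tw <- tag_width_px
  corners <- data.frame(x = c(0, W - cw, 0, W - cw),
                        y = c(0, 0, H - cw, H - cw),
                        width = cw)
  n_corner <- min(4L, n_onscreen)
  placements <- corners[seq_len(n_corner), , drop = FALSE]
  n_rest <- n_onscreen - n_corner
  if (n_rest > 0) {
    n_top <- ceiling(n_rest / 2)
    n_bot <- n_rest - n_top
    edge_xs <- function(k) {
      if (k == 0) return(numeric(0))
      cw + (W - 2 * cw) * seq_len(k) / (k + 1) - tw / 2
    }
    placements <- rbind(placements,
                        data.frame(x = edge_xs(n_top), y = 0, width = tw),
                        if (n_bot > 0)
                          data.frame(x = edge_xs(n_bot), y = H - tw, width = tw))
  }
  placements <- data.frame(tag_id = seq_len(nrow(placements)) - 1L, placements)
  # pairwise disjointness by interval arithmetic
  n <- nrow(placements)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- placements[i, ]; b <- placements[j, ]
      if (a$x < b$x + b$width && b$x < a$x + a$width &&
          a$y < b$y + b$width && b$y < a$y + a$width) {
        stop("marker placements overlap (tags ", a$tag_id, " and ", b$tag_id,
             "); reduce the count or the marker width")
      }
    }
  }
  placements
}

#' Stamp marker placeholders onto video frames
#'
#' Draws each marker as a black square with a deterministic inner
#' checkerboard derived from its id — a stand-in pattern occupying the
#' exact marker footprint, for previewing layouts.
#'
#' @param video A list of frame arrays.
#' @param layout A [marker_layout()] data.frame.
#' @param geom A [screen_geometry()].
#' @param scale Display-to-video scale factor.
#' @return The video with markers stamped on every frame.
#' @export
stamp_markers <- function(video, layout, geom = screen_geometry(), scale = 1) {
  for (f in seq_along(video)) {
    h <- dim(video[[f]])[1]; w <- dim(video[[f]])[2]
    for (i in seq_len(nrow(layout))) {
      x0 <- max(1L, round(layout$x[i] * scale))
      y0 <- max(1L, round(layout$y[i] * scale))
      x1 <- min(w, round((layout$x[i] + layout$width[i]) * scale))
      y1 <- min(h, round((layout$y[i] + layout$width[i]) * scale))
      if (x0 > x1 || y0 > y1) next
      video[[f]][y0:y1, x0:x1, ] <- 0
      bits <- as.integer(intToBits(layout$tag_id[i] + 1L))[1:16]
      cell <- matrix(bits, 4, 4)
      for (r in y0:y1) for (cc in x0:x1) {
        ri <- ((r - y0) * 4L) %/% max(1L, (y1 - y0 + 1L)) + 1L
        ci <- ((cc - x0) * 4L) %/% max(1L, (x1 - x0 + 1L)) + 1L
        video[[f]][r, cc, ] <- cell[ri, ci]
      }
    }
  }
  video
}
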