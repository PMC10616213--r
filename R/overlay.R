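# Overlay rendering: AOI boxes (with margins) and gaze dots on video
# frames, for zero, one, or many participants.
#
# A "video" is a list of numeric arrays [height, width, 3] with values in
# [0,1] (RGB, top-left origin). Frame sequences can be read from / written
# to directories of PNG files; no encoded-video container is involved, so
# overlays are byte-deterministic.

#' The 26-color discriminative alphabet
#'
#' A fixed palette of 26 maximally discriminative colors (Green-Armytage's
#' "color alphabet") used to tell objects and participants apart in
#' overlays; entities beyond 26 cycle through the palette.
#'
#' @return A 26 x 3 numeric matrix of RGB values in \[0,1\], with color
#'   names as row names.
#' @export
color_alphabet <- function() {
  m <- matrix(c(
    240, 163, 255,   0, 117, 220, 153,  63,   0,  76,   0,  92,
     25,  25,  25,   0,  92,  49,  43, 206,  72, 255, 204, 153,
    128, 128, 128, 148, 255, 181, 143, 124,   0, 157, 204,   0,
    194,   0, 136,   0,  51, 128, 255, 164,   5, 255, 168, 187,
     66, 102,   0, 255,   0,  16,  94, 241, 242,   0, 153, 143,
    224, 255, 102, 116,  10, 255, 153,   0,   0, 255, 255, 128,
    255, 225,   0, 255,  80,   5), ncol = 3, byrow = TRUE) / 255
  rownames(m) <- c("amethyst", "blue", "caramel", "damson", "ebony",
                   "forest", "green", "honeydew", "iron", "jade", "khaki",
                   "lime", "mallow", "navy", "orpiment", "pink", "quagmire",
                   "red", "sky", "turquoise", "uranium", "violet", "wine",
                   "xanthin", "yellow", "zinnia")
  m
}

#' Assign discriminative colors to entities
#'
#' Deterministic: the i-th entity gets the i-th alphabet color, cycling
#' after 26.
#'
#' @param ids Character vector of entity identifiers.
#' @return A matrix of RGB rows named by `ids`.
#' @export
assign_colors <- function(ids) {
  pal <- color_alphabet()
  out <- pal[((seq_along(ids) - 1L) %% nrow(pal)) + 1L, , drop = FALSE]
  rownames(out) <- ids
  out
}

#' Overlay rendering style
#'
#' @param box_thickness Box outline thickness in video pixels (default 2).
#' @param gaze_radius Gaze dot radius in video pixels (default 3).
#' @param show_margins Also draw the margin-expanded box (default TRUE).
#' @return An object of class `overlay_style`.
#' @export
overlay_style <- function(box_thickness = 2L, gaze_radius = 3L,
                          show_margins = TRUE) {
  stopifnot(box_thickness >= 1, gaze_radius >= 1)
  structure(list(box_thickness = as.integer(box_thickness),
                 gaze_radius = as.integer(gaze_radius),
                 show_margins = isTRUE(show_margins)),
            class = "overlay_style")
}

#' Create a blank video
#'
#' @param n_frames Number of frames.
#' @param width,height Frame size in pixels.
#' @param bg Background gray level in \[0,1\] (default 0.5).
#' @return A list of frame arrays.
#' @export
blank_video <- function(n_frames, width, height, bg = 0.5) {
  lapply(seq_len(n_frames), function(i) array(bg, dim = c(height, width, 3)))
}

.draw_rect <- function(frame, x0, y0, x1, y1, rgb, thickness) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- round(x0); x1 <- round(x1); y0 <- round(y0); y1 <- round(y1)
  for (k in 0:(thickness - 1L)) {
    xs <- max(1L, x0 - k):min(w, x1 + k)
    ys <- max(1L, y0 - k):min(h, y1 + k)
    for (c in 1:3) {
      if (y0 - k >= 1 && y0 - k <= h) frame[y0 - k, xs, c] <- rgb[c]
      if (y1 + k >= 1 && y1 + k <= h) frame[y1 + k, xs, c] <- rgb[c]
      if (x0 - k >= 1 && x0 - k <= w) frame[ys, x0 - k, c] <- rgb[c]
      if (x1 + k >= 1 && x1 + k <= w) frame[ys, x1 + k, c] <- rgb[c]
    }
  }
  frame
}

.draw_disc <- function(frame, cx, cy, radius, rgb) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  xs <- max(1L, floor(cx - radius)):min(w, ceiling(cx + radius))
  ys <- max(1L, floor(cy - radius)):min(h, ceiling(cy + radius))
  if (length(xs) == 0 || length(ys) == 0) return(frame)
  for (y in ys) {
    dx <- sqrt(max(0, radius^2 - (y - cy)^2))
    sel <- xs[xs >= cx - dx & xs <= cx + dx]
    if (length(sel) > 0) for (c in 1:3) frame[y, sel, c] <- rgb[c]
  }
  frame
}

.centered_to_video_xy <- function(x, y, geom, scale) {
  list(x = (x + geom$width_px / 2) * scale,
       y = (y + geom$height_px / 2) * scale)
}

#' Overlay AOI boxes on video frames
#'
#' Draws, on every frame, each object's box and (optionally) its
#' margin-expanded box, in the object's alphabet color. Frame count, size
#' and implicit rate are preserved; identical inputs yield byte-identical
#' frame buffers. AOI frames beyond the video end are skipped with a
#' warning.
#'
#' @param video A list of frame arrays (see [blank_video()]).
#' @param trajectories A list of [aoi_trajectory()] objects in centered
#'   display coordinates.
#' @param margin_deg Visual-angle margin drawn around each box (ignored
#'   when `style$show_margins` is FALSE).
#' @param geom A [screen_geometry()].
#' @param style An [overlay_style()].
#' @param scale Display-to-video scale factor: video frames are
#'   `scale * geom$width_px` wide (default 1, i.e. native resolution).
#' @return The video with overlays drawn.
#' @export
overlay_aois <- function(video, trajectories, margin_deg = 0,
                         geom = screen_geometry(), style = overlay_style(),
                         scale = 1) {
  n <- length(video)
  colors <- assign_colors(vapply(trajectories, function(tr) tr$object_id, ""))
  skipped <- 0L
  for (i in seq_along(trajectories)) {
    traj <- trajectories[[i]]
    rgb <- colors[i, ]
    m <- if (style$show_margins && margin_deg > 0) {
      margins_for_box(traj$boxes, margin_deg, geom)
    } else NULL
    for (j in seq_len(nrow(traj$boxes))) {
      f <- traj$boxes$frame[j]
      if (f + 1L > n) { skipped <- skipped + 1L; next }
      b <- traj$boxes[j, ]
      p0 <- .centered_to_video_xy(b$x_left, b$y_top, geom, scale)
      p1 <- .centered_to_video_xy(b$x_right, b$y_bottom, geom, scale)
      video[[f + 1L]] <- .draw_rect(video[[f + 1L]], p0$x, p0$y, p1$x, p1$y,
                                    rgb, style$box_thickness)
      if (!is.null(m)) {
        q0 <- .centered_to_video_xy(b$x_left - m$left_px[j],
                                    b$y_top - m$top_px[j], geom, scale)
        q1 <- .centered_to_video_xy(b$x_right + m$right_px[j],
                                    b$y_bottom + m$bottom_px[j], geom, scale)
        video[[f + 1L]] <- .draw_rect(video[[f + 1L]], q0$x, q0$y, q1$x, q1$y,
                                      rgb, 1L)
      }
    }
  }
  if (skipped > 0) {
    warning(skipped, " AOI frame(s) beyond the video end were skipped")
  }
  video
}

#' Overlay gaze of one or many participants on video frames
#'
#' On each frame, draws the (up to ~10 at 240 Hz) valid gaze samples whose
#' timestamps map to that frame as filled dots in the participant's
#' alphabet color, on top of the AOI overlay. Invalid (gap) samples are
#' not drawn — off-screen or blink samples simply disappear from the
#' rendering. An empty gaze stream produces the AOI-only overlay with a
#' warning.
#'
#' @param video A list of frame arrays.
#' @param trajectories AOI trajectories (drawn first).
#' @param gaze One preprocessed gaze data.frame
#'   (`overlay_single_participant`) or a named list of them
#'   (`overlay_multiple_participants`).
#' @param margin_deg Visual-angle margin for the AOI overlay.
#' @param geom A [screen_geometry()].
#' @param style An [overlay_style()].
#' @param scale Display-to-video scale factor.
#' @param t0 Video start time in the gaze timebase.
#' @param fps Video frame rate (default 25).
#' @return The video with overlays drawn.
#' @export
overlay_single_participant <- function(video, trajectories, gaze,
                                       margin_deg = 0,
                                       geom = screen_geometry(),
                                       style = overlay_style(), scale = 1,
                                       t0 = 0, fps = 25) {
  overlay_multiple_participants(video, trajectories, list(P1 = gaze),
                                margin_deg, geom, style, scale, t0, fps)
}

#' @rdname overlay_single_participant
#' @export
overlay_multiple_participants <- function(video, trajectories, gaze,
                                          margin_deg = 0,
                                          geom = screen_geometry(),
                                          style = overlay_style(), scale = 1,
                                          t0 = 0, fps = 25) {
  video <- overlay_aois(video, trajectories, margin_deg, geom, style, scale)
  if (is.null(names(gaze))) names(gaze) <- sprintf("P%02d", seq_along(gaze))
  colors <- assign_colors(names(gaze))
  n <- length(video)
  for (p in seq_along(gaze)) {
    g <- gaze[[p]]
    g <- g[g$valid & g$t >= t0, , drop = FALSE]
    if (nrow(g) == 0) {
      warning("empty gaze stream for participant '", names(gaze)[p],
              "'; AOI-only overlay")
      next
    }
    f <- frame_of(g$t, fps, t0)
    keep <- f < n
    g <- g[keep, , drop = FALSE]
    f <- f[keep]
    pos <- .centered_to_video_xy(g$x, g$y, geom, scale)
    for (i in seq_len(nrow(g))) {
      video[[f[i] + 1L]] <- .draw_disc(video[[f[i] + 1L]], pos$x[i], pos$y[i],
                                       style$gaze_radius, colors[p, ])
    }
  }
  video
}

#' Read / write a video as a directory of PNG frames
#'
#' Frames are stored as zero-padded `frame_000000.png`, ... — a lossless,
#' text-tool-friendly interchange format for the overlay tools.
#'
#' @param video A list of frame arrays.
#' @param dir Directory path.
#' @return `write_video_frames` returns `dir` invisibly;
#'   `read_video_frames` returns the list of frame arrays.
#' @export
write_video_frames <- function(video, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(video)) {
    png::writePNG(video[[i]], file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname write_video_frames
#' @export
read_video_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
}
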