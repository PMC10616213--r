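# Per-frame AOI bounding boxes: construction, keyframe interpolation,
# semi-automatic tracking, table serialization, and trajectory summaries.
#
# Boxes live in centered display coordinates ((0,0) at screen center,
# +y downward) and use 0-based video frame indices; AOI visibility is the
# closed frame interval [first_frame, last_frame].

#' Construct one AOI bounding box
#'
#' @param frame 0-based video frame index.
#' @param x_left,y_top,x_right,y_bottom Box edges in centered display
#'   pixels; `x_left < x_right`, `y_top < y_bottom`.
#' @param object_id Object identifier string.
#' @param label Optional custom label.
#' @return A one-row data.frame.
#' @export
aoi_box <- function(frame, x_left, y_top, x_right, y_bottom,
                    object_id = "object", label = "") {
  stopifnot(frame >= 0, x_left < x_right, y_top < y_bottom)
  data.frame(frame = as.integer(frame),
             x_left = x_left, y_top = y_top,
             x_right = x_right, y_bottom = y_bottom,
             object_id = object_id, label = label,
             stringsAsFactors = FALSE)
}

#' Build an AOI trajectory from per-frame boxes
#'
#' @param boxes A data.frame of boxes (one per frame, frames contiguous).
#' @param object_id Object identifier; defaults to the boxes' id.
#' @param fps Video frame rate (default 25).
#' @return An object of class `aoi_trajectory` with fields `object_id`,
#'   `boxes`, `first_frame`, `last_frame`, `fps`.
#' @export
aoi_trajectory <- function(boxes, object_id = boxes$object_id[1], fps = 25) {
  stopifnot(nrow(boxes) >= 1, fps > 0)
  boxes <- boxes[order(boxes$frame), ]
  if (anyDuplicated(boxes$frame)) stop("duplicate frame numbers in trajectory")
  if (!all(diff(boxes$frame) == 1)) {
    stop("trajectory boxes must cover a contiguous frame range")
  }
  if (any(boxes$x_left >= boxes$x_right) || any(boxes$y_top >= boxes$y_bottom)) {
    stop("degenerate box: x_left must be < x_right and y_top < y_bottom")
  }
  structure(list(object_id = object_id,
                 boxes = boxes,
                 first_frame = boxes$frame[1],
                 last_frame = boxes$frame[nrow(boxes)],
                 fps = fps),
            class = "aoi_trajectory")
}

#' @export
print.aoi_trajectory <- function(x, ...) {
  cat(sprintf("<aoi_trajectory> '%s': frames %d-%d (%.2f s at %g fps)\n",
              x$object_id, x$first_frame, x$last_frame,
              aoi_duration_s(x), x$fps))
  invisible(x)
}

#' Duration of AOI visibility in seconds
#'
#' `(last_frame - first_frame + 1) / fps` — the closed frame interval.
#'
#' @param traj An [aoi_trajectory()].
#' @return Duration in seconds.
#' @export
aoi_duration_s <- function(traj) {
  (traj$last_frame - traj$first_frame + 1) / traj$fps
}

#' Interpolate AOI boxes between keyframes
#'
#' Produces one box per frame between the first and last keyframe by linear
#' interpolation of each edge coordinate, rounded to the nearest integer
#' pixel; keyframes are reproduced exactly. This is the manual-annotation
#' workhorse: draw a box on a handful of frames and let the trajectory be
#' filled in.
#'
#' @param keyframes A data.frame of at least two boxes with strictly
#'   increasing `frame`.
#' @param fps Video frame rate (default 25).
#' @return An [aoi_trajectory()].
#' @export
interpolate_boxes <- function(keyframes, fps = 25) {
  if (nrow(keyframes) < 2) stop("at least 2 keyframes are required")
  keyframes <- keyframes[order(keyframes$frame), ]
  if (anyDuplicated(keyframes$frame)) stop("duplicate keyframe frame numbers")
  frames <- keyframes$frame[1]:keyframes$frame[nrow(keyframes)]
  interp <- function(v) {
    round(stats::approx(keyframes$frame, v, xout = frames)$y)
  }
  boxes <- data.frame(frame = frames,
                      x_left = interp(keyframes$x_left),
                      y_top = interp(keyframes$y_top),
                      x_right = interp(keyframes$x_right),
                      y_bottom = interp(keyframes$y_bottom),
                      object_id = keyframes$object_id[1],
                      label = keyframes$label[1],
                      stringsAsFactors = FALSE)
  kf <- match(keyframes$frame, frames)
  boxes[kf, c("x_left", "y_top", "x_right", "y_bottom")] <-
    keyframes[, c("x_left", "y_top", "x_right", "y_bottom")]
  aoi_trajectory(boxes, fps = fps)
}

# --- semi-automatic tracking -------------------------------------------------

.resize_nn <- function(m, nr, nc) {
  m[round(seq(1, nrow(m), length.out = nr)),
    round(seq(1, ncol(m), length.out = nc)), drop = FALSE]
}

.ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Track an object through video frames
#'
#' Semi-automatic rectangle tracking with size adaptation. Starting from an
#' initial box on the object's first visible frame, each subsequent frame is
#' searched in a local window around the previous box center for the best
#' placement of the previous frame's box content, at several relative
#' scales, by normalized cross-correlation; the winning (scale, offset)
#' moves and rescales the box. Objects approaching or receding therefore
#' grow and shrink with the track. The tracker is deterministic.
#'
#' If the best correlation falls below `min_corr` (e.g., the object left the
#' scene or covers too much of it), tracking halts with status `"lost"` at
#' that frame. Keyframe `corrections` (a list of boxes) override the track
#' at their frame and re-seed the template, resuming automatic tracking; a
#' span lost between the last tracked frame and a correction is bridged by
#' linear box interpolation so the trajectory stays per-frame contiguous.
#'
#' Frames are grayscale matrices (rows = y, columns = x, values in \[0,1\])
#' in top-left video coordinates; the initial box and corrections are given
#' in the same coordinates as `x_left`/`y_top`/`x_right`/`y_bottom` column
#' offsets into the matrices (1-based). The returned trajectory is in those
#' native video coordinates; convert with [video_to_centered()] before
#' saving.
#'
#' @param frames List of grayscale frame matrices, frame 0 first.
#' @param init A one-row box data.frame (see [aoi_box()]) with `frame` set
#'   to the first visible frame.
#' @param corrections Optional list of override boxes keyed by their `frame`.
#' @param search_radius Search half-width in pixels (default 8).
#' @param scales Relative scales tried per frame
#'   (default `c(0.95, 0.98, 1, 1.02, 1.05)`).
#' @param min_corr Correlation threshold below which the track is lost
#'   (default 0.5).
#' @param refresh_corr The reference template is kept until the match
#'   correlation drops below this value or a scale step is taken (default
#'   0.9); a slow update lets gradual size changes accumulate until they
#'   become visible to the correlation.
#' @param fps Video frame rate (default 25).
#' @return An [aoi_trajectory()] (video coordinates) with attributes
#'   `status` (`"tracked"` or `"lost"`) and `lost_frame`.
#' @export
track_object <- function(frames, init, corrections = NULL,
                         search_radius = 8L, scales = c(0.95, 0.98, 1, 1.02, 1.05),
                         min_corr = 0.5, refresh_corr = 0.9, fps = 25) {
  stopifnot(length(frames) >= 1, init$frame >= 0,
            init$frame < length(frames))
  corr_frames <- if (is.null(corrections)) integer(0) else
    vapply(corrections, function(b) as.integer(b$frame), 0L)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  clampx <- function(v) pmin(pmax(v, 1), w)
  clampy <- function(v) pmin(pmax(v, 1), h)
  # the template carries a context ring around the box: the object's
  # boundary position inside the template is what makes scale changes
  # visible to the correlation
  pad_for <- function(b) {
    list(px = max(2L, round(0.25 * (b$x_right - b$x_left))),
         py = max(2L, round(0.25 * (b$y_bottom - b$y_top))))
  }
  seed_template <- function(img, b) {
    pad <- pad_for(b)
    x0 <- clampx(round(b$x_left) - pad$px)
    x1 <- clampx(round(b$x_right) + pad$px)
    y0 <- clampy(round(b$y_top) - pad$py)
    y1 <- clampy(round(b$y_bottom) + pad$py)
    list(m = img[y0:y1, x0:x1, drop = FALSE], pad = pad)
  }
  cur <- init
  template <- seed_template(frames[[init$frame + 1L]], cur)
  boxes <- list(cur)
  status <- "tracked"
  lost_frame <- NA_integer_
  fseq <- seq.int(init$frame + 1L, length.out = length(frames) - init$frame - 1L)
  for (f in fseq) {
    img <- frames[[f + 1L]]
    ov <- match(f, corr_frames)
    if (!is.na(ov)) {
      prev_f <- boxes[[length(boxes)]]$frame
      nxt <- corrections[[ov]]
      if (f > prev_f + 1L) {
        # bridge the lost span by linear interpolation to the correction
        gap <- interpolate_boxes(rbind(boxes[[length(boxes)]], nxt), fps = fps)
        mid <- gap$boxes[gap$boxes$frame > prev_f & gap$boxes$frame < f, ,
                         drop = FALSE]
        for (r in seq_len(nrow(mid))) boxes[[length(boxes) + 1L]] <- mid[r, ]
      }
      cur <- nxt
      template <- seed_template(img, cur)
      boxes[[length(boxes) + 1L]] <- cur
      status <- "tracked"
      next
    }
    if (status == "lost") next
    # candidate placements are anchored at the current box corner so that
    # the unshifted scale-1 candidate covers the template's footprint
    bx0 <- clampx(round(cur$x_left) - template$pad$px)
    by0 <- clampy(round(cur$y_top) - template$pad$py)
    tw0 <- ncol(template$m); th0 <- nrow(template$m)
    best <- list(corr = -Inf)
    for (s in scales) {
      tw <- max(2L, round(tw0 * s))
      th <- max(2L, round(th0 * s))
      tv <- as.vector(.resize_nn(template$m, th, tw))
      # keep scaled candidates centered on the previous region
      ox <- round((tw - tw0) / 2); oy <- round((th - th0) / 2)
      for (dy in -search_radius:search_radius) {
        for (dx in -search_radius:search_radius) {
          x0 <- bx0 - ox + dx; y0 <- by0 - oy + dy
          x1 <- x0 + tw - 1L; y1 <- y0 + th - 1L
          if (x0 < 1 || y0 < 1 || x1 > w || y1 > h) next
          cc <- .ncc(tv, as.vector(img[y0:y1, x0:x1]))
          if (is.finite(cc) && cc > best$corr) {
            best <- list(corr = cc, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                         sx = tw / tw0, sy = th / th0)
          }
        }
      }
    }
    if (!is.finite(best$corr) || best$corr < min_corr) {
      status <- "lost"
      if (is.na(lost_frame)) lost_frame <- f
      next
    }
    # strip the (scaled) context ring off the matched region
    mx <- round(template$pad$px * best$sx)
    my <- round(template$pad$py * best$sy)
    cur <- data.frame(frame = f,
                      x_left = best$x0 + mx, y_top = best$y0 + my,
                      x_right = best$x1 - mx, y_bottom = best$y1 - my,
                      object_id = init$object_id, label = init$label,
                      stringsAsFactors = FALSE)
    # slow template update: keep the reference appearance until a scale
    # step is taken or the match degrades, so gradual size changes can
    # accumulate far enough to be seen against it
    if (best$sx != 1 || best$sy != 1 || best$corr < refresh_corr) {
      template <- seed_template(img, cur)
    }
    boxes[[length(boxes) + 1L]] <- cur
  }
  out <- do.call(rbind, boxes)
  out[, c("x_left", "y_top", "x_right", "y_bottom")] <-
    round(out[, c("x_left", "y_top", "x_right", "y_bottom")])
  traj <- aoi_trajectory(out, fps = fps)
  attr(traj, "status") <- status
  attr(traj, "lost_frame") <- lost_frame
  traj
}

#' Convert boxes between top-left video and centered display coordinates
#'
#' Annotation happens in native video pixel coordinates (origin top-left);
#' saved AOI tables and all gaze/AOI matching use centered coordinates with
#' (0,0) at the display center.
#'
#' @param boxes A box data.frame.
#' @param geom A [screen_geometry()].
#' @return The converted box data.frame.
#' @export
video_to_centered <- function(boxes, geom) {
  boxes$x_left <- boxes$x_left - geom$width_px / 2
  boxes$x_right <- boxes$x_right - geom$width_px / 2
  boxes$y_top <- boxes$y_top - geom$height_px / 2
  boxes$y_bottom <- boxes$y_bottom - geom$height_px / 2
  boxes
}

#' @rdname video_to_centered
#' @export
centered_to_video <- function(boxes, geom) {
  boxes$x_left <- boxes$x_left + geom$width_px / 2
  boxes$x_right <- boxes$x_right + geom$width_px / 2
  boxes$y_top <- boxes$y_top + geom$height_px / 2
  boxes$y_bottom <- boxes$y_bottom + geom$height_px / 2
  boxes
}

#' Write / read an AOI table
#'
#' CSV with columns `frame`, `x_left`, `y_top`, `x_right`, `y_bottom`,
#' `object_id`, `label`, in centered display coordinates. Reading validates
#' each row (`x_left < x_right`, `y_top < y_bottom`; violating rows are
#' rejected with their row number) and warns about coordinates outside the
#' display plus a configurable allowance. `read_aoi_table(write_aoi_table(x))`
#' is the identity.
#'
#' @param trajectories A list of [aoi_trajectory()] objects.
#' @param path CSV path.
#' @param fps Frame rate assigned to trajectories on read (default 25).
#' @param geom A [screen_geometry()] used for the bounds warning.
#' @param bounds_allowance_px Allowance beyond the display edge before a
#'   coordinate triggers a warning (default 200).
#' @return `write_aoi_table` returns `path` invisibly; `read_aoi_table`
#'   returns a named list of trajectories.
#' @export
write_aoi_table <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) tr$boxes))
  utils::write.csv(rows[, c("frame", "x_left", "y_top", "x_right",
                            "y_bottom", "object_id", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aoi_table
#' @export
read_aoi_table <- function(path, fps = 25, geom = screen_geometry(),
                           bounds_allowance_px = 200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_left", "y_top", "x_right", "y_bottom", "object_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("AOI table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$object_id <- as.character(df$object_id)
  df$label <- if (is.null(df$label)) "" else {
    lbl <- as.character(df$label)
    lbl[is.na(lbl)] <- ""
    lbl
  }
  bad <- df$x_left >= df$x_right | df$y_top >= df$y_bottom | df$frame < 0
  if (any(bad)) {
    stop("invalid AOI row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "),
         " (x_left must be < x_right and y_top < y_bottom)")
  }
  hw <- geom$width_px / 2 + bounds_allowance_px
  hh <- geom$height_px / 2 + bounds_allowance_px
  if (any(df$x_left < -hw | df$x_right > hw | df$y_top < -hh | df$y_bottom > hh)) {
    warning("AOI coordinates extend beyond the display by more than ",
            bounds_allowance_px, " px")
  }
  lapply(split(df, df$object_id), aoi_trajectory, fps = fps)
}

#' Summarize an AOI trajectory
#'
#' Reports the box size distribution (median / min / max width and height in
#' pixels) and the mean angular velocity: the visual-angle separation
#' between the trajectory's start and end midpoints divided by the
#' visibility duration, signed by the horizontal direction of travel —
#' negative for objects moving right-to-left.
#'
#' @param traj An [aoi_trajectory()] in centered coordinates.
#' @param geom A [screen_geometry()].
#' @return A one-row data.frame of summary statistics.
#' @export
trajectory_summary <- function(traj, geom = screen_geometry()) {
  b <- traj$boxes
  wpx <- b$x_right - b$x_left
  hpx <- b$y_bottom - b$y_top
  c1 <- c((b$x_left[1] + b$x_right[1]) / 2, (b$y_top[1] + b$y_bottom[1]) / 2)
  n <- nrow(b)
  c2 <- c((b$x_left[n] + b$x_right[n]) / 2, (b$y_top[n] + b$y_bottom[n]) / 2)
  dth <- sqrt((px_to_deg(c2[1], geom) - px_to_deg(c1[1], geom))^2 +
                (px_to_deg(c2[2], geom) - px_to_deg(c1[2], geom))^2)
  dir <- if (c2[1] < c1[1]) -1 else 1
  data.frame(object_id = traj$object_id,
             duration_s = aoi_duration_s(traj),
             width_median = stats::median(wpx), width_min = min(wpx),
             width_max = max(wpx),
             height_median = stats::median(hpx), height_min = min(hpx),
             height_max = max(hpx),
             velocity_deg_s = dir * dth / aoi_duration_s(traj),
             stringsAsFactors = FALSE)
}
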