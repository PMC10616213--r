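# Reading per-surface gaze exports, pooling the nine surfaces into one
# centered-coordinate gaze stream, and checking per-scene sync markers.

.surface_export_cols <- c("gaze_timestamp", "world_index", "x_norm", "y_norm",
                          "on_surf", "confidence")

#' Default nine-surface layout of the wide display
#'
#' The display is divided into nine equal vertical strips, each spanning the
#' full height. Narrow surfaces improve the accuracy of marker-based gaze
#' mapping on a very wide screen; nine strips of 640 x 1200 px is the layout
#' used for the 5760 x 1200 setup.
#'
#' Rectangles are given in top-left display coordinates (`x0`, `y0`, `w`,
#' `h`); surface 1 is leftmost.
#'
#' @param geom A [screen_geometry()].
#' @param n_surfaces Number of vertical strips (default 9).
#' @return A data.frame with columns `surface`, `name`, `x0`, `y0`, `w`, `h`.
#' @export
surface_layout <- function(geom = screen_geometry(), n_surfaces = 9L) {
  stopifnot(n_surfaces >= 1, geom$width_px %% n_surfaces == 0)
  w <- geom$width_px / n_surfaces
  data.frame(surface = seq_len(n_surfaces),
             name = sprintf("Surface%d", seq_len(n_surfaces)),
             x0 = (seq_len(n_surfaces) - 1) * w,
             y0 = 0,
             w = w,
             h = geom$height_px)
}

#' Read one surface gaze export file
#'
#' Reads a per-surface gaze CSV in the Pupil Player Surface Tracker dialect.
#' The file must contain at least the columns `gaze_timestamp`,
#' `world_index`, `x_norm`, `y_norm`, `on_surf`, `confidence`; extra columns
#' (e.g. `world_timestamp`, `x_scaled`, `y_scaled`) are ignored. `x_norm` and
#' `y_norm` are surface-normalized coordinates (y bottom-up, the native
#' convention of the exporter) and may fall outside \[0,1\] when the gaze is
#' off the surface.
#'
#' Malformed rows — non-finite timestamp, confidence outside \[0,1\],
#' negative frame index, or `on_surf` true with non-finite coordinates — are
#' skipped with a warning; the number skipped is attached as attribute
#' `n_skipped`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of well-formed records in file order.
#' @export
read_surface_export <- function(path) {
  if (!file.exists(path)) stop("surface export file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.surface_export_cols, names(df))
  if (length(missing) > 0) {
    stop("surface export is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("surface export file is empty: ", path)
    out <- df[, .surface_export_cols]
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  ts <- num(df$gaze_timestamp)
  wi <- num(df$world_index)
  xn <- num(df$x_norm)
  yn <- num(df$y_norm)
  conf <- num(df$confidence)
  on_surf <- .parse_logical(df$on_surf)
  bad <- !is.finite(ts) | !is.finite(wi) | wi < 0 |
    !is.finite(conf) | conf < 0 | conf > 1 | is.na(on_surf) |
    (on_surf %in% TRUE & (!is.finite(xn) | !is.finite(yn)))
  if (any(bad)) {
    warning(sprintf("%d malformed row(s) skipped in %s", sum(bad), path))
  }
  keep <- !bad
  out <- data.frame(gaze_timestamp = ts[keep], world_index = as.integer(wi[keep]),
                    x_norm = xn[keep], y_norm = yn[keep],
                    on_surf = on_surf[keep], confidence = conf[keep])
  attr(out, "n_skipped") <- sum(bad)
  out
}

.parse_logical <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "1.0")] <- TRUE
  out[s %in% c("false", "f", "0", "0.0")] <- FALSE
  out
}

#' Pool nine per-surface gaze streams into one centered gaze stream
#'
#' For each unique gaze timestamp across the nine surface files, one gaze
#' sample is produced. If at least one surface registered the gaze on itself
#' (`on_surf`), the record from the surface whose normalized point lies
#' deepest inside the unit square is taken (depth =
#' `min(x_norm, 1 - x_norm, y_norm, 1 - y_norm)`), ties broken by the lowest
#' surface index; otherwise the least-out-of-bounds surface supplies the
#' coordinates and the sample is flagged off-screen. Normalized coordinates
#' are mapped into the surface's display rectangle (y flipped from the
#' exporter's bottom-up convention) and shifted so the display center is
#' (0,0), +y downward.
#'
#' The result is independent of the order in which the surface streams are
#' supplied: a named list is matched against `layout$name`, an unnamed list
#' is taken positionally as surfaces 1..9.
#'
#' @param per_surface List of 9 data.frames as from [read_surface_export()].
#' @param layout A [surface_layout()] with nine rows.
#' @param geom A [screen_geometry()].
#' @param t0 Task start time in the export timebase; output `t` is relative
#'   to it (default 0, i.e. timestamps used as-is). Typically the first
#'   registration of the dummy full-screen surface.
#' @return A data.frame with columns `t`, `x`, `y`, `confidence`,
#'   `on_screen`, `valid` — one row per unique timestamp, time-ordered.
#' @export
pool_surfaces <- function(per_surface, layout, geom, t0 = 0) {
  if (nrow(layout) != 9L) stop("surface layout must have exactly 9 surfaces")
  if (length(per_surface) != 9L) stop("expected 9 per-surface gaze streams")
  if (!is.null(names(per_surface)) && all(names(per_surface) %in% layout$name)) {
    per_surface <- per_surface[layout$name]
  }
  parts <- vector("list", 9L)
  for (i in seq_len(9L)) {
    df <- per_surface[[i]]
    if (nrow(df) > 0) df$.surface <- layout$surface[i]
    parts[[i]] <- df
  }
  all <- do.call(rbind, parts[vapply(parts, nrow, 0L) > 0])
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      confidence = numeric(0), on_screen = logical(0),
                      valid = logical(0)))
  }
  depth <- pmin(all$x_norm, 1 - all$x_norm, all$y_norm, 1 - all$y_norm)
  depth[!is.finite(depth)] <- -Inf
  ord <- order(all$gaze_timestamp, -as.integer(all$on_surf), -depth, all$.surface)
  all <- all[ord, ]
  pick <- all[!duplicated(all$gaze_timestamp), ]
  li <- match(pick$.surface, layout$surface)
  xv <- layout$x0[li] + pick$x_norm * layout$w[li]
  yv <- layout$y0[li] + (1 - pick$y_norm) * layout$h[li]
  data.frame(t = pick$gaze_timestamp - t0,
             x = xv - geom$width_px / 2,
             y = yv - geom$height_px / 2,
             confidence = pick$confidence,
             on_screen = pick$on_surf,
             valid = TRUE)
}

#' Write / read a pooled gaze stream as CSV
#'
#' Columns `t`, `x`, `y`, `confidence`, `on_screen` (UTF-8, header row, '.'
#' decimal separator). Invalid (gap) samples are written with empty
#' coordinate fields and read back with `valid = FALSE`.
#'
#' @param gaze A pooled gaze data.frame.
#' @param path Output/input CSV path.
#' @return `write_gaze_csv` returns `path` invisibly; `read_gaze_csv`
#'   returns the gaze data.frame.
#' @export
write_gaze_csv <- function(gaze, path) {
  out <- gaze[, c("t", "x", "y", "confidence", "on_screen")]
  if (!is.null(gaze$valid)) {
    out$x[!gaze$valid] <- NA_real_
    out$y[!gaze$valid] <- NA_real_
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "confidence", "on_screen")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("gaze CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$on_screen <- .parse_logical(df$on_screen)
  df$valid <- is.finite(df$x) & is.finite(df$y)
  df[, c(need, "valid")]
}

#' Check per-scene synchronization markers
#'
#' Between scenes, a unique fiducial marker is shown so that the moment its
#' surface is first registered in the eye-tracking data can be compared with
#' the scheduled scene onset, giving a per-scene estimate of presentation /
#' recording latency.
#'
#' The detected onset for scene `i` is the first marker registration for
#' that scene after the previous scene's detected onset. A scene whose
#' marker is never registered gets a missing (`NA`) discrepancy, not zero.
#'
#' @param markers A data.frame of marker registrations with columns `scene`
#'   (1-based scene index) and `gaze_timestamp` (seconds).
#' @param expected_onsets Strictly increasing scheduled scene onsets (s).
#' @return A data.frame with columns `scene`, `expected_onset_s`,
#'   `detected_onset_s`, `discrepancy_ms` (detected minus expected).
#' @export
check_sync_markers <- function(markers, expected_onsets) {
  stopifnot(is.numeric(expected_onsets), length(expected_onsets) >= 1)
  if (any(diff(expected_onsets) <= 0)) {
    stop("expected_onsets must be strictly increasing")
  }
  n <- length(expected_onsets)
  detected <- rep(NA_real_, n)
  prev <- -Inf
  for (i in seq_len(n)) {
    ts <- markers$gaze_timestamp[markers$scene == i & markers$gaze_timestamp > prev]
    if (length(ts) > 0) {
      detected[i] <- min(ts)
      prev <- detected[i]
    } else {
      prev <- expected_onsets[i]
    }
  }
  data.frame(scene = seq_len(n),
             expected_onset_s = expected_onsets,
             detected_onset_s = detected,
             discrepancy_ms = (detected - expected_onsets) * 1000)
}

#' Worst-case marker-onset detection latency
#'
#' The start of a scene is detected through the world camera registering the
#' scene's fiducial marker; with a camera running at `world_fps` frames per
#' second the marker can appear up to one frame period after the true onset.
#'
#' @param world_fps World (scene) camera frame rate (default 30).
#' @return Worst-case latency in whole milliseconds (one frame period).
#' @export
sync_latency_bound_ms <- function(world_fps = 30) {
  stopifnot(world_fps > 0)
  floor(1000 / world_fps)
}
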