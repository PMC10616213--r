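# Fully synthetic, ground-truthed scenario generation: scripted AOI
# trajectories, per-surface gaze exports in the surface-tracker dialect,
# and analytically derived expected metrics. Every stage of the toolkit is
# testable against these fixtures without any recorded data.

#' Script one moving object
#'
#' Objects move along a linear path (optionally bowed by `curve_px`, a
#' parabolic vertical deflection peaking mid-trajectory) between an
#' appearance and a disappearance time, while their box size ramps
#' linearly — emulating vehicles, cyclists, signs, etc. approaching or
#' receding in a traffic scene. All coordinates are centered display
#' pixels.
#'
#' @param object_id Identifier string.
#' @param appear_s,disappear_s Visibility interval in seconds.
#' @param x_start,x_end,y_start,y_end Path of the box center.
#' @param w_start,w_end,h_start,h_end Box size ramp in pixels.
#' @param curve_px Parabolic vertical deflection amplitude (default 0).
#' @param allow_offscreen Permit the box to leave the display without an
#'   error (default FALSE).
#' @return A list describing the object script.
#' @export
scenario_object <- function(object_id = "object1", appear_s = 0,
                            disappear_s = 10,
                            x_start = -500, x_end = 500,
                            y_start = 0, y_end = 0,
                            w_start = 200, w_end = 200,
                            h_start = 150, h_end = 150,
                            curve_px = 0, allow_offscreen = FALSE) {
  stopifnot(disappear_s > appear_s, w_start > 0, w_end > 0,
            h_start > 0, h_end > 0)
  list(object_id = object_id, appear_s = appear_s, disappear_s = disappear_s,
       x_start = x_start, x_end = x_end, y_start = y_start, y_end = y_end,
       w_start = w_start, w_end = w_end, h_start = h_start, h_end = h_end,
       curve_px = curve_px, allow_offscreen = allow_offscreen)
}

.object_state <- function(obj, t) {
  s <- (t - obj$appear_s) / (obj$disappear_s - obj$appear_s)
  s <- pmin(pmax(s, 0), 1)
  list(cx = obj$x_start + s * (obj$x_end - obj$x_start),
       cy = obj$y_start + s * (obj$y_end - obj$y_start) +
         obj$curve_px * 4 * s * (1 - s),
       w = obj$w_start + s * (obj$w_end - obj$w_start),
       h = obj$h_start + s * (obj$h_end - obj$h_start))
}

#' Script a complete synthetic recording scenario
#'
#' Defines the study conditions a synthetic recording emulates: a 25 fps
#' stimulus with scripted moving objects, gaze produced by two 120 Hz eye
#' cameras in anti-phase (an effective 240 Hz interleaved stream), smooth
#' pursuit of a target object with an optional lag, Gaussian angular noise
#' applied in degrees and projected through the flat-screen tangent model
#' (so pixel noise grows towards the periphery), scripted blinks (runs of
#' low-confidence samples) and off-screen excursions, and an optional
#' eccentricity-dependent accuracy-loss gain.
#'
#' @param duration_s Recording length in seconds (default 10).
#' @param fps Stimulus frame rate (default 25).
#' @param eye_rate_hz Per-eye-camera sampling rate (default 120).
#' @param objects List of [scenario_object()] scripts.
#' @param gaze_target `object_id` of the pursued object.
#' @param pursuit_lag_ms Pursuit lag of the gaze behind the target (ms).
#' @param noise_sigma_deg Angular gaze noise SD in degrees.
#' @param blinks data.frame with `onset_s`, `duration_s` — low-confidence
#'   runs.
#' @param off_screen data.frame with `onset_s`, `duration_s` — intervals in
#'   which the gaze is pushed beyond the display edge.
#' @param eccentric_noise_gain Relative noise increase per 50 deg of
#'   horizontal eccentricity (default 0; 1 doubles the noise at 50 deg).
#' @param timing_jitter_ms SD of timestamp jitter around the nominal
#'   anti-phase grid (default 0 — exact grid).
#' @param seed RNG seed; a fixed seed makes the generated files
#'   byte-identical across runs.
#' @return An object of class `scenario_script`.
#' @export
scenario_script <- function(duration_s = 10, fps = 25, eye_rate_hz = 120,
                            objects = list(scenario_object()),
                            gaze_target = objects[[1]]$object_id,
                            pursuit_lag_ms = 0, noise_sigma_deg = 0,
                            blinks = data.frame(onset_s = numeric(0),
                                                duration_s = numeric(0)),
                            off_screen = data.frame(onset_s = numeric(0),
                                                    duration_s = numeric(0)),
                            eccentric_noise_gain = 0,
                            timing_jitter_ms = 0, seed = 1L) {
  stopifnot(duration_s > 0, fps > 0, eye_rate_hz > 0, noise_sigma_deg >= 0,
            eccentric_noise_gain >= 0, timing_jitter_ms >= 0)
  for (sch in list(blinks, off_screen)) {
    if (nrow(sch) > 0 &&
        any(sch$onset_s < 0 | sch$onset_s + sch$duration_s > duration_s)) {
      stop("blink / off-screen schedules must lie within the recording")
    }
  }
  structure(list(duration_s = duration_s, fps = fps,
                 eye_rate_hz = eye_rate_hz, objects = objects,
                 gaze_target = gaze_target,
                 pursuit_lag_ms = pursuit_lag_ms,
                 noise_sigma_deg = noise_sigma_deg,
                 blinks = blinks, off_screen = off_screen,
                 eccentric_noise_gain = eccentric_noise_gain,
                 timing_jitter_ms = timing_jitter_ms,
                 seed = as.integer(seed)),
            class = "scenario_script")
}

.scenario_trajectories <- function(script, geom) {
  out <- list()
  for (obj in script$objects) {
    f0 <- round(obj$appear_s * script$fps)
    f1 <- round(obj$disappear_s * script$fps) - 1L
    frames <- f0:f1
    st <- .object_state(obj, frames / script$fps)
    boxes <- data.frame(frame = frames,
                        x_left = round(st$cx - st$w / 2),
                        y_top = round(st$cy - st$h / 2),
                        x_right = round(st$cx + st$w / 2),
                        y_bottom = round(st$cy + st$h / 2),
                        object_id = obj$object_id, label = "synthetic",
                        stringsAsFactors = FALSE)
    if (!obj$allow_offscreen &&
        (any(boxes$x_left < -geom$width_px / 2) ||
         any(boxes$x_right > geom$width_px / 2) ||
         any(boxes$y_top < -geom$height_px / 2) ||
         any(boxes$y_bottom > geom$height_px / 2))) {
      stop("object '", obj$object_id,
           "' leaves the display; script it with allow_offscreen = TRUE")
    }
    out[[obj$object_id]] <- aoi_trajectory(boxes, fps = script$fps)
  }
  out
}

# interval helpers (rows: start, end), used for analytic ground truth
.spans_union <- function(spans) {
  if (nrow(spans) == 0) return(spans)
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    k <- nrow(out)
    if (spans$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], spans$end[i])
    } else {
      out <- rbind(out, spans[i, , drop = FALSE])
    }
  }
  out
}

.spans_subtract <- function(lo, hi, spans) {
  segs <- data.frame(start = lo, end = hi)
  for (i in seq_len(nrow(spans))) {
    nxt <- list()
    for (j in seq_len(nrow(segs))) {
      a <- segs$start[j]; b <- segs$end[j]
      s <- spans$start[i]; e <- spans$end[i]
      if (e <= a || s >= b) {
        nxt[[length(nxt) + 1L]] <- data.frame(start = a, end = b)
      } else {
        if (s > a) nxt[[length(nxt) + 1L]] <- data.frame(start = a, end = s)
        if (e < b) nxt[[length(nxt) + 1L]] <- data.frame(start = e, end = b)
      }
    }
    segs <- if (length(nxt) > 0) do.call(rbind, nxt) else
      data.frame(start = numeric(0), end = numeric(0))
    if (nrow(segs) == 0) break
  }
  segs
}

.expected_metrics <- function(obj, script, pre = preprocess_params(),
                              mp = match_params()) {
  gaps <- rbind(
    if (nrow(script$blinks) > 0)
      data.frame(start = script$blinks$onset_s,
                 end = script$blinks$onset_s + script$blinks$duration_s)
    else NULL,
    if (nrow(script$off_screen) > 0)
      data.frame(start = script$off_screen$onset_s,
                 end = script$off_screen$onset_s + script$off_screen$duration_s)
    else NULL)
  if (is.null(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  gaps <- .spans_union(gaps)
  # short gaps are healed by interpolation; the rest get the +/- pad
  gaps <- gaps[gaps$end - gaps$start >= pre$max_interp_gap_ms / 1000, ,
               drop = FALSE]
  if (nrow(gaps) > 0) {
    gaps$start <- gaps$start - pre$gap_pad_ms / 1000
    gaps$end <- gaps$end + pre$gap_pad_ms / 1000
    gaps <- .spans_union(gaps)
  }
  lo <- max(obj$appear_s, 0)
  hi <- min(obj$disappear_s, script$duration_s)
  visits <- .spans_subtract(lo, hi, gaps)
  # merge short inter-visit gaps, then drop short dwells
  if (nrow(visits) > 1) {
    merged <- visits[1, , drop = FALSE]
    for (i in seq_len(nrow(visits))[-1]) {
      k <- nrow(merged)
      if ((visits$start[i] - merged$end[k]) * 1000 < mp$min_intervisit_gap_ms) {
        merged$end[k] <- visits$end[i]
      } else {
        merged <- rbind(merged, visits[i, , drop = FALSE])
      }
    }
    visits <- merged
  }
  visits <- visits[(visits$end - visits$start) * 1000 >= mp$min_dwell_ms, ,
                   drop = FALSE]
  appearance <- obj$disappear_s - obj$appear_s
  dwell <- sum(visits$end - visits$start)
  list(object_id = obj$object_id,
       visits = data.frame(t_entry = visits$start, t_exit = visits$end),
       invalid_spans = gaps,
       appearance_s = appearance,
       total_dwell_s = dwell,
       dwell_pct = 100 * dwell / appearance,
       time_to_first_entry_s = if (nrow(visits) > 0)
         visits$start[1] - obj$appear_s else NA_real_,
       t_last_exit_s = if (nrow(visits) > 0)
         visits$end[nrow(visits)] else NA_real_)
}

#' Generate a complete synthetic scenario
#'
#' Produces everything one recorded trial would provide, plus the truth
#' behind it:
#' \itemize{
#'   \item nine per-surface gaze export data.frames in the surface-tracker
#'     CSV dialect (interleaved anti-phase eye streams, confidence drops
#'     during scripted blinks, `on_surf = FALSE` everywhere during
#'     off-screen excursions),
#'   \item AOI trajectories for every scripted object,
#'   \item the true gaze path in centered coordinates,
#'   \item analytically derived expected pipeline results per object
#'     (visit intervals, total dwell, dwell percentage, time to first
#'     entry) under the default preprocessing and matching parameters —
#'     exact for noiseless pursuit scripts.
#' }
#' Identical seeds give identical output.
#'
#' @param script A [scenario_script()].
#' @param geom A [screen_geometry()].
#' @param layout A [surface_layout()].
#' @return An object of class `aoi_scenario`: a list with elements
#'   `script`, `geom`, `layout`, `surfaces`, `trajectories`, `gaze_truth`,
#'   `ground_truth`.
#' @export
generate_scenario <- function(script, geom = screen_geometry(),
                              layout = surface_layout(geom)) {
  stopifnot(inherits(script, "scenario_script"))
  set.seed(script$seed)
  trajectories <- .scenario_trajectories(script, geom)
  target <- NULL
  for (obj in script$objects) {
    if (obj$object_id == script$gaze_target) target <- obj
  }
  if (is.null(target)) stop("gaze_target does not name a scripted object")

  n_eye <- floor(script$duration_s * script$eye_rate_hz)
  t0 <- (seq_len(n_eye) - 1L) / script$eye_rate_hz
  t1 <- t0 + 1 / (2 * script$eye_rate_hz)
  t <- c(t0, t1)
  eye <- rep(0:1, each = n_eye)
  if (script$timing_jitter_ms > 0) {
    t <- t + stats::rnorm(length(t), 0, script$timing_jitter_ms / 1000)
    t <- pmax(t, 0)
  }
  ord <- order(t)
  t <- t[ord]; eye <- eye[ord]
  # collapse accidental timestamp ties from jitter
  while (any(diff(t) <= 0)) t[c(FALSE, diff(t) <= 0)] <-
      t[c(FALSE, diff(t) <= 0)] + 1e-6

  st <- .object_state(target, t - script$pursuit_lag_ms / 1000)
  x <- st$cx
  y <- st$cy
  if (script$noise_sigma_deg > 0) {
    thx <- px_to_deg(x, geom)
    thy <- px_to_deg(y, geom)
    sigma <- script$noise_sigma_deg *
      (1 + script$eccentric_noise_gain * abs(thx) / 50)
    x <- deg_to_px(pmin(pmax(thx + stats::rnorm(length(t), 0, sigma), -89), 89), geom)
    y <- deg_to_px(pmin(pmax(thy + stats::rnorm(length(t), 0, sigma), -89), 89), geom)
  }
  conf <- rep(0.99, length(t))
  blink <- rep(FALSE, length(t))
  for (i in seq_len(nrow(script$blinks))) {
    sel <- t >= script$blinks$onset_s[i] &
      t < script$blinks$onset_s[i] + script$blinks$duration_s[i]
    blink <- blink | sel
  }
  conf[blink] <- 0.2
  off <- rep(FALSE, length(t))
  for (i in seq_len(nrow(script$off_screen))) {
    sel <- t >= script$off_screen$onset_s[i] &
      t < script$off_screen$onset_s[i] + script$off_screen$duration_s[i]
    off <- off | sel
  }
  # push off-screen samples just past the nearer display edge
  x[off] <- ifelse(x[off] >= 0, geom$width_px / 2 + 60,
                   -geom$width_px / 2 - 60)

  xv <- x + geom$width_px / 2
  yv <- y + geom$height_px / 2
  world_index <- pmax(0L, as.integer(floor(t * 30)))
  surfaces <- list()
  for (i in seq_len(nrow(layout))) {
    xn <- (xv - layout$x0[i]) / layout$w[i]
    yn <- 1 - (yv - layout$y0[i]) / layout$h[i]
    on_surf <- xn >= 0 & xn <= 1 & yn >= 0 & yn <= 1
    surfaces[[layout$name[i]]] <- data.frame(
      world_timestamp = world_index / 30,
      world_index = world_index,
      gaze_timestamp = t,
      x_norm = xn, y_norm = yn,
      x_scaled = xn * layout$w[i], y_scaled = yn * layout$h[i],
      on_surf = on_surf, confidence = conf)
  }
  ground_truth <- lapply(script$objects, .expected_metrics, script = script)
  names(ground_truth) <- vapply(script$objects, `[[`, "", "object_id")
  structure(list(script = script, geom = geom, layout = layout,
                 surfaces = surfaces, trajectories = trajectories,
                 gaze_truth = data.frame(t = t, eye = eye, x = x, y = y,
                                         confidence = conf, blink = blink,
                                         off_screen = off),
                 ground_truth = ground_truth),
            class = "aoi_scenario")
}

#' Write a generated scenario to disk
#'
#' Writes the nine per-surface gaze CSVs (`gaze_positions_on_surface_<name>.csv`),
#' the AOI table (`aois.csv`) and the true gaze path (`gaze_truth.csv`)
#' into a directory.
#'
#' @param scenario An `aoi_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(scenario$surfaces)) {
    utils::write.csv(scenario$surfaces[[nm]],
                     file.path(dir, sprintf("gaze_positions_on_surface_%s.csv", nm)),
                     row.names = FALSE)
  }
  write_aoi_table(scenario$trajectories, file.path(dir, "aois.csv"))
  utils::write.csv(scenario$gaze_truth, file.path(dir, "gaze_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline on a generated scenario
#'
#' Pools the scenario's nine surface streams, preprocesses the gaze, and
#' computes AOI metrics at one margin — the exact chain a recorded trial
#' goes through.
#'
#' @param scenario An `aoi_scenario`.
#' @param margin_deg Visual-angle margin (default 0).
#' @param pre A [preprocess_params()].
#' @param mp A [match_params()].
#' @return A list with `metrics` (per-object data.frame), `gaze` (the
#'   preprocessed stream) and `stats` (gap statistics).
#' @export
analyze_scenario <- function(scenario, margin_deg = 0,
                             pre = preprocess_params(),
                             mp = match_params()) {
  pooled <- pool_surfaces(scenario$surfaces, scenario$layout, scenario$geom)
  prep <- preprocess_gaze(pooled, pre)
  metrics <- match_gaze_aois(prep$gaze, scenario$trajectories, margin_deg,
                             scenario$geom, mp)
  list(metrics = metrics, gaze = prep$gaze, stats = prep$stats)
}

#' Synthetic per-scene sync marker registrations
#'
#' Emulates the registration of each scene's unique marker by a world
#' camera running at `world_fps`: the marker appears `lag_ms` after the
#' scheduled onset and is first registered at the next world frame.
#'
#' @param expected_onsets Scheduled scene onsets (s), strictly increasing.
#' @param lag_ms Injected presentation lag in ms (default 0).
#' @param world_fps World camera frame rate (default 30).
#' @param n_samples Registrations emitted per marker (default 5).
#' @return A data.frame with columns `scene`, `gaze_timestamp`.
#' @export
synth_sync_markers <- function(expected_onsets, lag_ms = 0, world_fps = 30,
                               n_samples = 5L) {
  rows <- lapply(seq_along(expected_onsets), function(i) {
    first <- ceiling((expected_onsets[i] + lag_ms / 1000) * world_fps) / world_fps
    data.frame(scene = i,
               gaze_timestamp = first + (seq_len(n_samples) - 1L) / world_fps)
  })
  do.call(rbind, rows)
}

#' Render scenario frames as a synthetic video
#'
#' Draws each scripted object as a filled gray rectangle on a uniform
#' background — a minimal stimulus for tracker and overlay testing.
#'
#' @param script A [scenario_script()].
#' @param geom A [screen_geometry()].
#' @param scale Display-to-video scale factor (default 0.05, i.e. a
#'   288 x 60 px canvas for the default display).
#' @param bg Background gray level (default 0.8).
#' @param fg Object gray level (default 0.2).
#' @return A list of frame arrays (see [blank_video()]).
#' @export
render_scenario_frames <- function(script, geom = screen_geometry(),
                                   scale = 0.05, bg = 0.8, fg = 0.2) {
  w <- round(geom$width_px * scale)
  h <- round(geom$height_px * scale)
  n <- round(script$duration_s * script$fps)
  video <- blank_video(n, w, h, bg)
  trajectories <- .scenario_trajectories(script, geom)
  for (traj in trajectories) {
    for (j in seq_len(nrow(traj$boxes))) {
      f <- traj$boxes$frame[j] + 1L
      if (f > n) next
      b <- traj$boxes[j, ]
      x0 <- max(1L, round((b$x_left + geom$width_px / 2) * scale))
      x1 <- min(w, round((b$x_right + geom$width_px / 2) * scale))
      y0 <- max(1L, round((b$y_top + geom$height_px / 2) * scale))
      y1 <- min(h, round((b$y_bottom + geom$height_px / 2) * scale))
      if (x0 <= x1 && y0 <= y1) video[[f]][y0:y1, x0:x1, ] <- fg
    }
  }
  video
}
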