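# Frame-by-frame matching of gaze samples to AOI boxes, visit extraction,
# the 100 ms merge / minimum-dwell rules, and dwell / entry metrics.

#' Matching parameters
#'
#' A gaze sample belongs to the video frame whose half-open time interval
#' contains it. Short exits are treated as precision noise: if the time
#' between an exit and the next entry is shorter than
#' `min_intervisit_gap_ms`, the two visits are pooled (the bridged time
#' counts toward dwell); a pooled visit still shorter than `min_dwell_ms`
#' is discarded, since a meaningful dwell must contain at least one
#' fixation (~100 ms).
#'
#' @param fps Stimulus video frame rate (default 25).
#' @param min_intervisit_gap_ms Merge threshold between visits (default 100).
#' @param min_dwell_ms Minimum retained dwell duration (default 100).
#' @return An object of class `match_params`.
#' @export
match_params <- function(fps = 25, min_intervisit_gap_ms = 100,
                         min_dwell_ms = 100) {
  stopifnot(fps > 0, min_intervisit_gap_ms > 0, min_dwell_ms > 0)
  structure(list(fps = fps,
                 min_intervisit_gap_ms = min_intervisit_gap_ms,
                 min_dwell_ms = min_dwell_ms),
            class = "match_params")
}

#' Video frame index of a time point
#'
#' `floor((t - t0) * fps)` with half-open frame intervals
#' `[k/fps, (k+1)/fps)`.
#'
#' @param t Time(s) in seconds; must be `>= t0`.
#' @param fps Video frame rate.
#' @param t0 Video start time (default 0).
#' @return Integer frame indices (0-based).
#' @export
frame_of <- function(t, fps = 25, t0 = 0) {
  if (any(t < t0)) stop("frame_of: t must be >= t0")
  as.integer(floor((t - t0) * fps + 1e-9))
}

#' Test gaze samples against a margin-expanded AOI box
#'
#' A sample hits iff its coordinates fall inside the box expanded by the
#' per-side pixel margins, with closed boundaries on all sides. Gap
#' (invalid) samples must be excluded by the caller.
#'
#' @param sample A gaze data.frame (columns `x`, `y`, `valid`).
#' @param box Box row(s) aligned with the samples (recycled if one row).
#' @param margins Margin row(s) as from [margins_for_box()].
#' @return A logical vector of hit verdicts.
#' @export
hit_test <- function(sample, box, margins) {
  if (any(!sample$valid)) {
    stop("hit_test requires valid samples; exclude gap samples first")
  }
  sample$x >= box$x_left - margins$left_px &
    sample$x <= box$x_right + margins$right_px &
    sample$y >= box$y_top - margins$top_px &
    sample$y <= box$y_bottom + margins$bottom_px
}

#' Per-sample hit series of a gaze stream against one AOI trajectory
#'
#' Restricts the gaze stream to the AOI's visible frame range, looks up the
#' frame's box for each sample, expands it by the visual-angle margin, and
#' tests each valid sample. Invalid samples get `hit = FALSE` but keep
#' `valid = FALSE` so that visit extraction can treat them as gaps.
#'
#' @param gaze A preprocessed, uniformly sampled gaze data.frame.
#' @param traj An [aoi_trajectory()] in centered coordinates.
#' @param margin_deg Visual-angle margin in degrees.
#' @param geom A [screen_geometry()].
#' @param t0 Video start time in the gaze timebase (default 0).
#' @return The restricted gaze data.frame with an added logical `hit`.
#' @export
aoi_hit_series <- function(gaze, traj, margin_deg, geom, t0 = 0) {
  gaze <- gaze[gaze$t >= t0, , drop = FALSE]
  f <- frame_of(gaze$t, traj$fps, t0)
  sel <- f >= traj$first_frame & f <= traj$last_frame
  g <- gaze[sel, , drop = FALSE]
  if (nrow(g) == 0) {
    g$hit <- logical(0)
    return(g)
  }
  boxes <- traj$boxes[match(f[sel], traj$boxes$frame), , drop = FALSE]
  m <- margins_for_box(boxes, margin_deg, geom)
  hit <- g$x >= boxes$x_left - m$left_px & g$x <= boxes$x_right + m$right_px &
    g$y >= boxes$y_top - m$top_px & g$y <= boxes$y_bottom + m$bottom_px
  g$hit <- !is.na(hit) & hit & g$valid
  g
}

#' Extract visits from a hit series
#'
#' A visit opens at the first hit sample following a non-hit (or the start
#' of the series) and closes at the last hit sample before a non-hit (or
#' the end); gap samples end a visit exactly like non-hits. Entry and exit
#' times are the opening and closing sample timestamps.
#'
#' @param t Sample timestamps (uniform grid).
#' @param hit Logical hit verdicts.
#' @param valid Logical validity flags (gap samples `FALSE`).
#' @return A data.frame of visits: `t_entry`, `t_exit`, `duration_s`.
#' @export
extract_visits <- function(t, hit, valid = rep(TRUE, length(hit))) {
  eff <- !is.na(hit) & hit & valid
  if (!any(eff)) {
    return(data.frame(t_entry = numeric(0), t_exit = numeric(0),
                      duration_s = numeric(0)))
  }
  r <- rle(eff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  data.frame(t_entry = t[s], t_exit = t[e], duration_s = t[e] - t[s])
}

#' Merge nearby visits and drop sub-threshold dwells
#'
#' Two-stage rule: (1) in a left-to-right pass, while the gap between the
#' current visit's exit and the next visit's entry is shorter than
#' `min_intervisit_gap_ms`, the gap and the next visit are absorbed into
#' the current visit — the bridged time counts toward the dwell; (2) any
#' visit that after merging still lasts less than `min_dwell_ms` is
#' removed.
#'
#' @param visits Time-ordered, non-overlapping visits
#'   (see [extract_visits()]).
#' @param params A [match_params()].
#' @return The merged and filtered visits data.frame.
#' @export
merge_and_filter <- function(visits, params = match_params()) {
  n <- nrow(visits)
  if (n > 1 && any(visits$t_entry[-1] < visits$t_exit[-n])) {
    stop("visits must be non-overlapping and time-ordered")
  }
  if (n > 0) {
    merged <- visits[1, , drop = FALSE]
    for (i in seq_len(n)[-1]) {
      gap_ms <- (visits$t_entry[i] - merged$t_exit[nrow(merged)]) * 1000
      # 1e-9 ms guard keeps exact grid-quantized ties on the no-merge side
      if (gap_ms < params$min_intervisit_gap_ms - 1e-9) {
        merged$t_exit[nrow(merged)] <- visits$t_exit[i]
      } else {
        merged <- rbind(merged, visits[i, , drop = FALSE])
      }
    }
    merged$duration_s <- merged$t_exit - merged$t_entry
    visits <- merged
  }
  visits[visits$duration_s * 1000 >= params$min_dwell_ms - 1e-9, , drop = FALSE]
}

#' Dwell and entry metrics for one AOI
#'
#' Computes, from the retained visits of one object: the total dwell time
#' (sum of visit durations), the dwell percentage (100 x total dwell /
#' total appearance time), the time to first entry (first retained entry
#' minus the object's first appearance), the last exit time, and the visit
#' count. With no retained visits the dwell is 0 and the entry time is
#' missing. Dwell percentages are reported uncapped; padding/merging
#' arithmetic can push them marginally above 100, in which case a warning
#' is raised.
#'
#' @param visits Visits after [merge_and_filter()].
#' @param traj The object's [aoi_trajectory()].
#' @param params A [match_params()].
#' @param t0 Video start time in the gaze timebase (default 0).
#' @return A one-row data.frame of metrics.
#' @export
summarize_aoi <- function(visits, traj, params = match_params(), t0 = 0) {
  appearance_s <- aoi_duration_s(traj)
  t_appear <- t0 + traj$first_frame / traj$fps
  n_visits <- nrow(visits)
  total_dwell_s <- sum(visits$duration_s)
  dwell_pct <- 100 * total_dwell_s / appearance_s
  if (dwell_pct > 100 + 1e-9) {
    warning(sprintf("dwell_pct %.2f%% exceeds 100%% for '%s' (pad/merge arithmetic); reported uncapped",
                    dwell_pct, traj$object_id))
  }
  data.frame(object_id = traj$object_id,
             appearance_s = appearance_s,
             n_visits = n_visits,
             total_dwell_s = total_dwell_s,
             dwell_pct = dwell_pct,
             time_to_first_entry_s = if (n_visits > 0) visits$t_entry[1] - t_appear else NA_real_,
             t_last_exit_s = if (n_visits > 0) visits$t_exit[n_visits] else NA_real_,
             stringsAsFactors = FALSE)
}

#' Match one gaze stream against AOI trajectories
#'
#' Runs the complete matching chain — hit series, visit extraction, merge
#' and minimum-dwell filtering, summary — for every object at one margin.
#'
#' @param gaze A preprocessed gaze data.frame (uniform sampling).
#' @param trajectories A list of [aoi_trajectory()] objects.
#' @param margin_deg Visual-angle margin in degrees.
#' @param geom A [screen_geometry()].
#' @param params A [match_params()].
#' @param t0 Video start time in the gaze timebase (default 0).
#' @return A data.frame with one metrics row per object, plus a
#'   `margin_deg` column.
#' @export
match_gaze_aois <- function(gaze, trajectories, margin_deg,
                            geom = screen_geometry(),
                            params = match_params(), t0 = 0) {
  rows <- lapply(trajectories, function(traj) {
    hs <- aoi_hit_series(gaze, traj, margin_deg, geom, t0)
    visits <- merge_and_filter(extract_visits(hs$t, hs$hit, hs$valid), params)
    summarize_aoi(visits, traj, params, t0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$margin_deg <- margin_deg
  out[, c("object_id", "margin_deg", setdiff(names(out), c("object_id", "margin_deg")))]
}

#' Batch metrics over participants, objects and margins
#'
#' Produces the long-format table behind margin-sweep analyses: one row per
#' (participant, object, margin). Row order is deterministic — participants
#' in input order, objects in input order, margins ascending. A declared
#' object with no AOI trajectory yields a row of missing metrics and a
#' message.
#'
#' @param gaze_streams Named list of preprocessed gaze data.frames, one per
#'   participant.
#' @param trajectories Named list of [aoi_trajectory()] objects.
#' @param margins_deg Margins to sweep (degrees).
#' @param geom A [screen_geometry()].
#' @param params A [match_params()].
#' @param object_ids Objects to report (default: names of `trajectories`).
#' @param t0 Video start time in the gaze timebase (default 0).
#' @return A long-format data.frame of metrics.
#' @export
run_batch <- function(gaze_streams, trajectories,
                      margins_deg = c(0, 0.5, 1, 1.5, 2),
                      geom = screen_geometry(), params = match_params(),
                      object_ids = names(trajectories), t0 = 0) {
  if (is.null(names(gaze_streams))) {
    names(gaze_streams) <- sprintf("P%02d", seq_along(gaze_streams))
  }
  margins_deg <- sort(margins_deg)
  out <- list()
  for (p in names(gaze_streams)) {
    for (oid in object_ids) {
      traj <- trajectories[[oid]]
      for (m in margins_deg) {
        if (is.null(traj)) {
          message("no AOI trajectory for declared object '", oid, "'")
          row <- data.frame(object_id = oid, margin_deg = m,
                            appearance_s = NA_real_, n_visits = NA_integer_,
                            total_dwell_s = NA_real_, dwell_pct = NA_real_,
                            time_to_first_entry_s = NA_real_,
                            t_last_exit_s = NA_real_,
                            stringsAsFactors = FALSE)
        } else {
          row <- match_gaze_aois(gaze_streams[[p]], list(traj), m, geom,
                                 params, t0)
        }
        row <- cbind(participant = p, row, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
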