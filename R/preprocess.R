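# Gaze-signal cleaning: spike-median filtering, confidence / on-screen
# gating, short-gap interpolation, gap padding, and uniform resampling.
#
# The pipeline order is fixed:
#   median_filter -> classify_gaps -> interpolate_short_gaps ->
#   extend_gaps -> resample_uniform
# and is applied by preprocess_gaze().

#' Preprocessing parameters
#'
#' Defaults follow the validated wide-screen setup: a 3-sample median window
#' for one-sample spike reduction, a pupil-detection confidence threshold of
#' 0.8 (samples strictly below it, e.g. during blinks, become gaps), linear
#' interpolation of gaps shorter than 75 ms, padding of the remaining gaps
#' by +/- 100 ms (partial pupil occlusion around blinks), and resampling of
#' the combined anti-phase 2 x 120 Hz eye streams to a uniform 240 Hz.
#'
#' @param median_window Median filter window in samples, odd (default 3).
#' @param confidence_threshold Confidence gate in \[0,1\] (default 0.8);
#'   strictly-below comparison, 0.8 itself is kept.
#' @param max_interp_gap_ms Gaps shorter than this are filled by linear
#'   interpolation (default 75 ms; strict `<`, ties are not filled).
#' @param gap_pad_ms Padding applied around remaining gaps, inclusive at
#'   both ends (default 100 ms).
#' @param target_rate_hz Uniform output sampling rate (default 240 Hz).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_window = 3L, confidence_threshold = 0.8,
                              max_interp_gap_ms = 75, gap_pad_ms = 100,
                              target_rate_hz = 240) {
  stopifnot(median_window >= 1, median_window %% 2 == 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            max_interp_gap_ms >= 0, gap_pad_ms >= 0, target_rate_hz > 0)
  structure(list(median_window = as.integer(median_window),
                 confidence_threshold = confidence_threshold,
                 max_interp_gap_ms = max_interp_gap_ms,
                 gap_pad_ms = gap_pad_ms,
                 target_rate_hz = target_rate_hz),
            class = "preprocess_params")
}

#' Running-median spike filter
#'
#' Replaces `x` and `y` independently by the running median over a centered
#' window, removing one-sample spikes while preserving signal features
#' better than a moving average. Boundary samples with fewer than `window`
#' neighbors are passed through unchanged; timestamps, confidence and flags
#' are untouched.
#'
#' @param gaze A pooled gaze data.frame (finite coordinates).
#' @param window Odd window length in samples.
#' @return The filtered gaze data.frame.
#' @export
median_filter <- function(gaze, window = 3L) {
  if (window %% 2 == 0) stop("median filter window must be odd")
  n <- nrow(gaze)
  if (window == 1L || n < window) return(gaze)
  gaze$x <- as.numeric(stats::runmed(gaze$x, window, endrule = "keep"))
  gaze$y <- as.numeric(stats::runmed(gaze$y, window, endrule = "keep"))
  gaze
}

#' Gate samples by confidence and on-screen status
#'
#' Marks as gap samples (`valid = FALSE`, coordinates set missing) every
#' sample whose pupil-detection confidence is strictly below `threshold`
#' (typically blinks) or whose gaze was not registered on the display.
#'
#' @param gaze A pooled gaze data.frame.
#' @param threshold Confidence threshold (default 0.8; strict `<`).
#' @return The gaze data.frame with updated `valid`, `x`, `y`.
#' @export
classify_gaps <- function(gaze, threshold = 0.8) {
  invalid <- (gaze$confidence < threshold) | !gaze$on_screen
  gaze$valid <- !invalid
  gaze$x[invalid] <- NA_real_
  gaze$y[invalid] <- NA_real_
  gaze
}

.invalid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[!r$values], end = ends[!r$values])
}

#' Fill short gaps by linear interpolation
#'
#' A maximal run of invalid samples whose duration — measured from the last
#' valid sample before the run to the first valid sample after it — is
#' strictly shorter than `max_gap_ms` is filled by linear interpolation in
#' time between the flanking valid samples, and marked valid. Longer runs
#' are left missing, as are runs touching either end of the stream.
#'
#' @param gaze A time-ordered gaze data.frame.
#' @param max_gap_ms Maximum (exclusive) fillable gap duration (default 75).
#' @return The gaze data.frame with short gaps filled.
#' @export
interpolate_short_gaps <- function(gaze, max_gap_ms = 75) {
  runs <- .invalid_runs(gaze$valid)
  if (nrow(runs) == 0) return(gaze)
  n <- nrow(gaze)
  for (k in seq_len(nrow(runs))) {
    p <- runs[k, "start"] - 1L
    q <- runs[k, "end"] + 1L
    if (p < 1L || q > n) next
    # 1e-6 ms guard so grid-quantized durations compare as the exact tie
    if ((gaze$t[q] - gaze$t[p]) * 1000 >= max_gap_ms - 1e-6) next
    idx <- runs[k, "start"]:runs[k, "end"]
    w <- (gaze$t[idx] - gaze$t[p]) / (gaze$t[q] - gaze$t[p])
    gaze$x[idx] <- gaze$x[p] + w * (gaze$x[q] - gaze$x[p])
    gaze$y[idx] <- gaze$y[p] + w * (gaze$y[q] - gaze$y[p])
    gaze$valid[idx] <- TRUE
  }
  gaze
}

#' Extend remaining gaps by a symmetric pad
#'
#' Around every remaining gap, samples within `pad_ms` (inclusive) of an
#' invalid sample are themselves marked invalid: near a blink the pupil may
#' be partially occluded and the reported gaze unreliable. Applied after
#' [interpolate_short_gaps()], so only unfilled gaps are padded.
#'
#' @param gaze A time-ordered gaze data.frame.
#' @param pad_ms Pad half-width in ms (default 100; closed interval).
#' @return The gaze data.frame with padded gaps.
#' @export
extend_gaps <- function(gaze, pad_ms = 100) {
  runs <- .invalid_runs(gaze$valid)
  if (nrow(runs) == 0) return(gaze)
  pad <- pad_ms / 1000
  invalid <- !gaze$valid
  for (k in seq_len(nrow(runs))) {
    ta <- gaze$t[runs[k, "start"]]
    tb <- gaze$t[runs[k, "end"]]
    invalid <- invalid | (gaze$t >= ta - pad & gaze$t <= tb + pad)
  }
  gaze$valid <- !invalid
  gaze$x[invalid] <- NA_real_
  gaze$y[invalid] <- NA_real_
  gaze
}

#' Resample the gaze stream to a uniform rate
#'
#' The two eye cameras sample at 120 Hz each in anti-phase; their fused
#' stream is nominally 240 Hz but not exactly uniform. This resamples onto
#' an exact uniform grid from the first to the last input timestamp using
#' shape-preserving piecewise cubic Hermite interpolation (Fritsch–Carlson
#' monotone cubics, so linear input is reproduced exactly and monotone
#' segments never overshoot), computed independently per contiguous valid
#' segment. Grid points falling inside an invalid span — or inside a valid
#' segment with fewer than two samples — are emitted as invalid; resampling
#' never bridges a gap. Confidence and the on-screen flag are carried by
#' nearest neighbor.
#'
#' @param gaze A time-ordered gaze data.frame with strictly increasing `t`.
#' @param rate Target sampling rate in Hz (default 240).
#' @return A uniformly sampled gaze data.frame.
#' @export
resample_uniform <- function(gaze, rate = 240) {
  n <- nrow(gaze)
  stopifnot(n >= 2, rate > 0)
  t <- gaze$t
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  n_out <- floor((t[n] - t[1]) * rate + 1e-9) + 1L
  tg <- t[1] + (seq_len(n_out) - 1L) / rate
  out <- data.frame(t = tg, x = NA_real_, y = NA_real_,
                    confidence = NA_real_, on_screen = NA, valid = FALSE)
  r <- rle(gaze$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (e - s < 1L) next  # a lone valid sample cannot anchor interpolation
    sel <- tg >= t[s] - 1e-12 & tg <= t[e] + 1e-12
    if (!any(sel)) next
    fx <- stats::splinefun(t[s:e], gaze$x[s:e], method = "monoH.FC")
    fy <- stats::splinefun(t[s:e], gaze$y[s:e], method = "monoH.FC")
    out$x[sel] <- fx(tg[sel])
    out$y[sel] <- fy(tg[sel])
    out$valid[sel] <- TRUE
  }
  nn <- .nearest_index(t, tg)
  out$confidence <- gaze$confidence[nn]
  out$on_screen <- gaze$on_screen[nn]
  out
}

.nearest_index <- function(t, tq) {
  lo <- findInterval(tq, t)
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(t))
  ifelse(tq - t[lo] <= t[hi] - tq, lo, hi)
}

#' Gap statistics across preprocessing stages
#'
#' Summarizes, as percentages of all samples, how much of the stream was
#' lost at each cleaning stage: low confidence, off-screen, missing after
#' gating, after short-gap interpolation, and after gap padding.
#'
#' @param raw Gaze stream before gating (for the confidence / off-screen
#'   breakdown).
#' @param classified,interpolated,padded The stream after
#'   [classify_gaps()], [interpolate_short_gaps()] and [extend_gaps()];
#'   all four must share the same length and timebase.
#' @param threshold Confidence threshold used for the breakdown.
#' @return An object of class `gap_stats` with fields `pct_low_confidence`,
#'   `pct_off_screen`, `pct_nan_before_interp`, `pct_nan_after_interp`,
#'   `pct_nan_after_pad`.
#' @export
gap_stats <- function(raw, classified, interpolated, padded, threshold = 0.8) {
  n <- nrow(raw)
  if (nrow(classified) != n || nrow(interpolated) != n || nrow(padded) != n) {
    stop("all four streams must have the same length")
  }
  structure(list(
    pct_low_confidence = 100 * mean(raw$confidence < threshold),
    pct_off_screen = 100 * mean(!raw$on_screen),
    pct_nan_before_interp = 100 * mean(!classified$valid),
    pct_nan_after_interp = 100 * mean(!interpolated$valid),
    pct_nan_after_pad = 100 * mean(!padded$valid)
  ), class = "gap_stats")
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "gap statistics (%% of samples):\n",
    "  low confidence            %6.2f\n",
    "  off-screen                %6.2f\n",
    "  missing after gating      %6.2f\n",
    "  missing after interp      %6.2f\n",
    "  missing after +/- pad     %6.2f\n"),
    x$pct_low_confidence, x$pct_off_screen, x$pct_nan_before_interp,
    x$pct_nan_after_interp, x$pct_nan_after_pad))
  invisible(x)
}

#' Run the full gaze preprocessing pipeline
#'
#' Applies, in order: [median_filter()], [classify_gaps()],
#' [interpolate_short_gaps()], [extend_gaps()], [resample_uniform()], and
#' computes [gap_stats()] over the pre-resampling stages. The composition is
#' deterministic.
#'
#' @param gaze A pooled gaze data.frame (see [pool_surfaces()]).
#' @param params A [preprocess_params()].
#' @return A list with elements `gaze` (the cleaned, uniformly resampled
#'   stream) and `stats` (a `gap_stats` object).
#' @export
preprocess_gaze <- function(gaze, params = preprocess_params()) {
  filtered <- median_filter(gaze, params$median_window)
  classified <- classify_gaps(filtered, params$confidence_threshold)
  interpolated <- interpolate_short_gaps(classified, params$max_interp_gap_ms)
  padded <- extend_gaps(interpolated, params$gap_pad_ms)
  resampled <- resample_uniform(padded, params$target_rate_hz)
  list(gaze = resampled,
       stats = gap_stats(filtered, classified, interpolated, padded,
                         params$confidence_threshold))
}
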