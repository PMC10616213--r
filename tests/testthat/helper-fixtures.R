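# Shared fixtures and independent oracles used across the test files.

default_geom <- screen_geometry()

make_gaze <- function(t, x = 0, y = 0, confidence = 0.99, on_screen = TRUE,
                      valid = TRUE) {
  data.frame(t = t, x = x, y = y, confidence = confidence,
             on_screen = on_screen, valid = valid)
}

# brute-force running median (sort-and-pick at every interior index)
oracle_runmed <- function(v, k) {
  h <- (k - 1) / 2
  out <- v
  n <- length(v)
  if (n < k) return(v)
  for (i in (h + 1):(n - h)) {
    out[i] <- sort(v[(i - h):(i + h)])[h + 1]
  }
  out
}

# independent run-length scanner for visit extraction
oracle_visits <- function(t, eff) {
  visits <- list()
  open <- NA
  for (i in seq_along(eff)) {
    if (eff[i] && is.na(open)) open <- i
    if (!eff[i] && !is.na(open)) {
      visits[[length(visits) + 1]] <- c(open, i - 1)
      open <- NA
    }
  }
  if (!is.na(open)) visits[[length(visits) + 1]] <- c(open, length(eff))
  if (length(visits) == 0) {
    return(data.frame(t_entry = numeric(0), t_exit = numeric(0),
                      duration_s = numeric(0)))
  }
  m <- do.call(rbind, visits)
  data.frame(t_entry = t[m[, 1]], t_exit = t[m[, 2]],
             duration_s = t[m[, 2]] - t[m[, 1]])
}

# independent merge/filter: repeatedly merge the first adjacent pair whose
# gap is below threshold until stable, then drop short dwells. Ties (a gap
# or dwell of exactly the threshold, up to grid-quantization rounding) sit
# on the no-merge / keep side, as in the implementation's contract.
oracle_merge_filter <- function(visits, gap_ms = 100, min_ms = 100) {
  repeat {
    n <- nrow(visits)
    if (n < 2) break
    gaps <- (visits$t_entry[-1] - visits$t_exit[-n]) * 1000
    i <- which(gaps < gap_ms - 1e-9)[1]
    if (is.na(i)) break
    visits$t_exit[i] <- visits$t_exit[i + 1]
    visits <- visits[-(i + 1), , drop = FALSE]
  }
  visits$duration_s <- visits$t_exit - visits$t_entry
  out <- visits[visits$duration_s * 1000 >= min_ms - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_hit_stream <- function(n, rate = 240) {
  t <- (seq_len(n) - 1) / rate
  # blocky hit pattern so that realistic visit/gap lengths occur
  hit <- logical(n)
  i <- 1
  state <- runif(1) < 0.5
  while (i <= n) {
    len <- sample.int(60, 1)
    hit[i:min(n, i + len - 1)] <- state
    state <- !state
    i <- i + len
  }
  valid <- runif(n) > 0.05
  list(t = t, hit = hit, valid = valid)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a$x_right, b$x_right) - max(a$x_left, b$x_left))
  iy <- max(0, min(a$y_bottom, b$y_bottom) - max(a$y_top, b$y_top))
  inter <- ix * iy
  area <- function(z) (z$x_right - z$x_left) * (z$y_bottom - z$y_top)
  inter / (area(a) + area(b) - inter)
}

# nine empty surface streams to be filled selectively
empty_surfaces <- function(layout = surface_layout(default_geom)) {
  out <- lapply(seq_len(9), function(i) {
    data.frame(gaze_timestamp = numeric(0), world_index = integer(0),
               x_norm = numeric(0), y_norm = numeric(0),
               on_surf = logical(0), confidence = numeric(0))
  })
  names(out) <- layout$name
  out
}

surface_record <- function(t, x_norm, y_norm, on_surf = TRUE,
                           confidence = 0.99) {
  data.frame(gaze_timestamp = t, world_index = as.integer(floor(t * 30)),
             x_norm = x_norm, y_norm = y_norm, on_surf = on_surf,
             confidence = confidence)
}
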