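test_that("keyframe interpolation is the exact affine blend, keyframes exact", {
  kf <- rbind(aoi_box(0, 10, 20, 110, 120, "car1"),
              aoi_box(10, 10, 20, 110, 120, "car1"))
  traj <- interpolate_boxes(kf)
  expect_equal(nrow(traj$boxes), 11)
  expect_true(all(traj$boxes$x_left == 10))
  expect_true(all(traj$boxes$y_bottom == 120))

  kf2 <- rbind(aoi_box(0, 0, 0, 40, 40, "car1"),
               aoi_box(10, 100, 0, 140, 40, "car1"))
  traj2 <- interpolate_boxes(kf2)
  expect_equal(traj2$boxes$x_left[traj2$boxes$frame == 5], 50)

  set.seed(13)
  for (i in 1:10) {
    f1 <- sample(0:50, 1); f2 <- f1 + sample(5:40, 1)
    b1 <- sort(sample(-500:500, 2)); b2 <- sort(sample(-500:500, 2))
    kf3 <- rbind(aoi_box(f1, b1[1], -40, b1[2], 40, "x"),
                 aoi_box(f2, b2[1], -40, b2[2], 40, "x"))
    tr <- interpolate_boxes(kf3)
    w <- (tr$boxes$frame - f1) / (f2 - f1)
    expect_equal(tr$boxes$x_left, round(b1[1] + w * (b2[1] - b1[1])))
    expect_equal(tr$boxes$x_right, round(b1[2] + w * (b2[2] - b1[2])))
    expect_equal(tr$boxes$x_left[c(1, nrow(tr$boxes))], c(b1[1], b2[1]))
  }

  expect_error(interpolate_boxes(aoi_box(0, 0, 0, 10, 10)), "2 keyframes")
  expect_error(interpolate_boxes(rbind(aoi_box(3, 0, 0, 10, 10),
                                       aoi_box(3, 0, 0, 20, 20))),
               "duplicate")
})

test_that("AOI tables round-trip field-by-field and reject degenerate rows", {
  set.seed(4)
  trajs <- lapply(1:13, function(i) {
    f0 <- sample(0:100, 1)
    interpolate_boxes(rbind(
      aoi_box(f0, -600 + 10 * i, -100, -400 + 10 * i, 50, sprintf("obj%02d", i)),
      aoi_box(f0 + sample(10:60, 1), 100, -80, 400, 90, sprintf("obj%02d", i))))
  })
  names(trajs) <- vapply(trajs, function(tr) tr$object_id, "")
  path <- withr::local_tempfile(fileext = ".csv")
  write_aoi_table(trajs, path)
  back <- read_aoi_table(path)
  expect_equal(names(back), sort(names(trajs)))
  for (nm in names(trajs)) {
    expect_equal(back[[nm]]$boxes$frame, trajs[[nm]]$boxes$frame)
    expect_equal(back[[nm]]$boxes$x_left, trajs[[nm]]$boxes$x_left)
    expect_equal(back[[nm]]$boxes$y_bottom, trajs[[nm]]$boxes$y_bottom)
  }

  df <- read.csv(path)
  df$x_left[3] <- df$x_right[3] + 5
  write.csv(df, path, row.names = FALSE)
  expect_error(read_aoi_table(path), "4")  # row number incl. header
})

test_that("visibility duration follows the closed frame interval", {
  boxes <- interpolate_boxes(rbind(aoi_box(0, -900, 100, -100, 500, "van1"),
                                   aoi_box(42, 200, 100, 900, 500, "van1")))
  expect_equal(aoi_duration_s(boxes), 43 / 25)  # 1.72 s
  expect_equal(round(aoi_duration_s(boxes), 1), 1.7)
})

test_that("trajectory summaries sign velocity by horizontal direction", {
  right_to_left <- interpolate_boxes(rbind(aoi_box(0, 800, -50, 1000, 50, "a"),
                                           aoi_box(24, -1000, -50, -800, 50, "a")))
  s <- trajectory_summary(right_to_left, default_geom)
  expect_lt(s$velocity_deg_s, 0)
  left_to_right <- interpolate_boxes(rbind(aoi_box(0, -1000, -50, -800, 50, "b"),
                                           aoi_box(24, 800, -50, 1000, 50, "b")))
  expect_gt(trajectory_summary(left_to_right, default_geom)$velocity_deg_s, 0)
  expect_equal(s$width_median, 200)
  expect_equal(s$duration_s, 1)
})

# --- tracker ----------------------------------------------------------------

textured_rect_frames <- function(n, w = 160, h = 110, cx0 = 60, cy0 = 50,
                                 dx = 0, dy = 0, rw0 = 24, rh0 = 18,
                                 grow = 0, vanish_at = Inf) {
  set.seed(99)
  tex <- matrix(runif(40 * 40, 0, 0.45), 40, 40)
  lapply(seq_len(n) - 1L, function(f) {
    img <- matrix(0.85, h, w)
    if (f >= vanish_at) return(img)
    cx <- cx0 + dx * f; cy <- cy0 + dy * f
    rw <- rw0 * (1 + grow)^f; rh <- rh0 * (1 + grow)^f
    xs <- max(1, round(cx - rw / 2)):min(w, round(cx + rw / 2))
    ys <- max(1, round(cy - rh / 2)):min(h, round(cy + rh / 2))
    # texture sampled at ~1 texel/px in object coordinates: it stretches
    # with the object, as a real approaching vehicle would
    for (yy in ys) {
      u <- round((yy - (cy - rh / 2)) / rh * (rh0 - 1)) + 1
      v <- round((xs - (cx - rw / 2)) / rw * (rw0 - 1)) + 1
      img[yy, xs] <- tex[cbind(pmin(pmax(u, 1), 40), pmin(pmax(v, 1), 40))]
    }
    img
  })
}

truth_box <- function(f, cx0 = 60, cy0 = 50, dx = 0, dy = 0, rw0 = 24,
                      rh0 = 18, grow = 0) {
  cx <- cx0 + dx * f; cy <- cy0 + dy * f
  rw <- rw0 * (1 + grow)^f; rh <- rh0 * (1 + grow)^f
  data.frame(x_left = cx - rw / 2, y_top = cy - rh / 2,
             x_right = cx + rw / 2, y_bottom = cy + rh / 2)
}

test_that("tracking a static textured rectangle is exact", {
  frames <- textured_rect_frames(12)
  init <- aoi_box(0, 60 - 12, 50 - 9, 60 + 12, 50 + 9, "static")
  traj <- track_object(frames, init)
  expect_equal(attr(traj, "status"), "tracked")
  expect_equal(nrow(traj$boxes), 12)
  for (j in seq_len(nrow(traj$boxes))) {
    expect_gte(box_iou(traj$boxes[j, ], truth_box(0)), 0.999)
  }
})

test_that("tracking follows translation and growth with IoU >= 0.8", {
  frames <- textured_rect_frames(16, dx = 4, grow = 0.01)
  init <- aoi_box(0, 60 - 12, 50 - 9, 60 + 12, 50 + 9, "mover")
  traj <- track_object(frames, init)
  expect_equal(attr(traj, "status"), "tracked")
  expect_equal(nrow(traj$boxes), 16)
  ious <- vapply(seq_len(nrow(traj$boxes)), function(j) {
    box_iou(traj$boxes[j, ], truth_box(traj$boxes$frame[j], dx = 4, grow = 0.01))
  }, 0)
  expect_true(all(ious >= 0.8))
})

test_that("a vanishing target is reported lost within two frames", {
  frames <- textured_rect_frames(14, vanish_at = 8)
  init <- aoi_box(0, 60 - 12, 50 - 9, 60 + 12, 50 + 9, "ghost")
  traj <- track_object(frames, init)
  expect_equal(attr(traj, "status"), "lost")
  expect_lte(attr(traj, "lost_frame"), 10)
})

test_that("a keyframe correction re-seeds the track and bridges the lost span", {
  frames <- textured_rect_frames(14, vanish_at = 20)
  # perturb frames 8-9 to an uninformative flat field: the track gets lost
  for (f in 9:10) frames[[f]] <- matrix(0.85, nrow(frames[[f]]), ncol(frames[[f]]))
  init <- aoi_box(0, 60 - 12, 50 - 9, 60 + 12, 50 + 9, "fixed")
  fix <- aoi_box(10, 60 - 12, 50 - 9, 60 + 12, 50 + 9, "fixed")
  traj <- track_object(frames, init, corrections = list(fix))
  expect_equal(attr(traj, "status"), "tracked")
  expect_equal(traj$boxes$frame, 0:13)  # lost frames 8-9 bridged
  expect_equal(attr(traj, "lost_frame"), 8)
})

test_that("coordinate conversion between video and centered frames inverts", {
  b <- aoi_box(0, 100, 200, 300, 400, "x")
  cc <- video_to_centered(b, default_geom)
  expect_equal(cc$x_left, 100 - 2880)
  expect_equal(cc$y_top, 200 - 600)
  expect_equal(centered_to_video(cc, default_geom)[, 2:5], b[, 2:5])
})
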