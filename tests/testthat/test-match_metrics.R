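test_that("frame numbers follow half-open 1/fps intervals", {
  expect_equal(frame_of(0, 25, 0), 0L)
  expect_equal(frame_of(0.0399, 25), 0L)
  expect_equal(frame_of(0.0400, 25), 1L)
  expect_error(frame_of(-0.1, 25, 0), ">= t0")
  # a uniform 240 Hz second maps 9 or 10 samples into each 25 fps frame
  f <- frame_of((0:239) / 240, 25)
  counts <- table(f)
  expect_true(all(counts %in% c(9, 10)))
  expect_equal(sum(counts), 240)
  expect_equal(length(counts), 25)
})

test_that("hit testing uses closed boundaries on the margin-expanded box", {
  box <- data.frame(x_left = -100, x_right = 100, y_top = -50, y_bottom = 50)
  m <- data.frame(left_px = 10, right_px = 20, top_px = 5, bottom_px = 5)
  corner <- make_gaze(0, x = 120, y = 55)
  expect_true(hit_test(corner, box, m))
  outside <- make_gaze(0, x = 121, y = 55)
  expect_false(hit_test(outside, box, m))
  expect_error(hit_test(make_gaze(0, x = 0, y = 0, valid = FALSE), box, m),
               "valid")

  set.seed(21)
  n <- 10000
  s <- make_gaze(t = seq_len(n) / 240, x = runif(n, -200, 200),
                 y = runif(n, -100, 100))
  verdict <- hit_test(s, box, m)
  brute <- vapply(seq_len(n), function(i) {
    s$x[i] >= -110 && s$x[i] <= 120 && s$y[i] >= -55 && s$y[i] <= 55
  }, TRUE)
  expect_identical(verdict, brute)
})

test_that("visit extraction matches an independent run-length scanner", {
  t <- (0:99) / 240
  all_hit <- extract_visits(t, rep(TRUE, 100))
  expect_equal(nrow(all_hit), 1)
  expect_equal(all_hit$t_entry, 0)
  expect_equal(all_hit$t_exit, 99 / 240)
  expect_equal(nrow(extract_visits(t, rep(FALSE, 100))), 0)
  # gap samples close visits like non-hits
  v <- rep(TRUE, 100); v[40:45] <- FALSE
  expect_equal(nrow(extract_visits(t, rep(TRUE, 100), v)), 2)

  set.seed(8)
  for (i in 1:25) {
    s <- random_hit_stream(sample(50:400, 1))
    got <- extract_visits(s$t, s$hit, s$valid)
    expect_equal(got, oracle_visits(s$t, s$hit & s$valid))
  }
})

test_that("visits merge across short gaps and sub-100 ms dwells are dropped", {
  v <- data.frame(t_entry = c(0, 0.55), t_exit = c(0.50, 1.00),
                  duration_s = c(0.50, 0.45))
  out <- merge_and_filter(v)
  expect_equal(nrow(out), 1)
  expect_equal(out$t_entry, 0)
  expect_equal(out$t_exit, 1.00)
  expect_equal(out$duration_s, 1.00)  # the bridged gap counts toward dwell

  lone <- data.frame(t_entry = 2, t_exit = 2.08, duration_s = 0.08)
  expect_equal(nrow(merge_and_filter(lone)), 0)
  # boundary cases: a gap of exactly 100 ms does not merge,
  # a dwell of exactly 100 ms is retained
  v2 <- data.frame(t_entry = c(0, 0.6), t_exit = c(0.5, 0.7),
                   duration_s = c(0.5, 0.1))
  out2 <- merge_and_filter(v2)
  expect_equal(nrow(out2), 2)
  overlap <- data.frame(t_entry = c(0, 0.4), t_exit = c(0.5, 0.9),
                        duration_s = c(0.5, 0.5))
  expect_error(merge_and_filter(overlap), "non-overlapping")
})

test_that("merge/filter equals brute-force merge-chain enumeration", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    gaps <- runif(n, 0.001, 0.3)
    durs <- runif(n, 0.01, 0.4)
    ends <- cumsum(gaps + durs)
    starts <- ends - durs
    v <- data.frame(t_entry = starts, t_exit = ends,
                    duration_s = ends - starts)
    got <- merge_and_filter(v)
    want <- oracle_merge_filter(v)
    expect_equal(got$t_entry, want$t_entry)
    expect_equal(got$t_exit, want$t_exit)
  }
})

test_that("dwell and entry metrics summarize visits against appearance time", {
  traj <- interpolate_boxes(rbind(aoi_box(0, -100, -50, 100, 50, "obj"),
                                  aoi_box(249, -100, -50, 100, 50, "obj")))
  ideal <- data.frame(t_entry = 0, t_exit = 10, duration_s = 10)
  m <- summarize_aoi(ideal, traj)
  expect_equal(m$dwell_pct, 100)
  expect_equal(m$time_to_first_entry_s, 0)
  expect_equal(m$appearance_s, 10)

  nine <- data.frame(t_entry = 0.5, t_exit = 9.5, duration_s = 9)
  expect_equal(summarize_aoi(nine, traj)$dwell_pct, 90)

  none <- merge_and_filter(data.frame(t_entry = numeric(0),
                                      t_exit = numeric(0),
                                      duration_s = numeric(0)))
  m0 <- summarize_aoi(none, traj)
  expect_equal(m0$n_visits, 0)
  expect_equal(m0$total_dwell_s, 0)
  expect_true(is.na(m0$time_to_first_entry_s))
})

test_that("retained dwell never exceeds appearance time by more than quantization", {
  sc <- scenario_script(duration_s = 6, noise_sigma_deg = 0.3, seed = 17,
                        blinks = data.frame(onset_s = 2.5, duration_s = 0.15))
  res <- analyze_scenario(generate_scenario(sc), margin_deg = 1.5)
  expect_lte(res$metrics$total_dwell_s,
             res$metrics$appearance_s + 2 / 240)
})

test_that("batch output is one row per participant x object x margin", {
  set.seed(6)
  trajs <- lapply(1:13, function(i) {
    interpolate_boxes(rbind(
      aoi_box(0, -200 + 17 * i, -60, 200 + 17 * i, 60, sprintf("obj%02d", i)),
      aoi_box(49, -150 + 17 * i, -60, 250 + 17 * i, 60, sprintf("obj%02d", i))))
  })
  names(trajs) <- vapply(trajs, function(tr) tr$object_id, "")
  gaze <- make_gaze(t = (0:479) / 240, x = rnorm(480, 0, 150),
                    y = rnorm(480, 0, 60))
  tab <- run_batch(list(P01 = gaze), trajs, margins_deg = c(0, 0.5, 1, 1.5, 2))
  expect_equal(nrow(tab), 65)
  expect_equal(unique(tab$participant), "P01")
  expect_equal(sort(unique(tab$margin_deg)), c(0, 0.5, 1, 1.5, 2))
  # absent trajectory yields a missing-metrics row
  expect_message(
    tab2 <- run_batch(list(P01 = gaze), trajs, margins_deg = 0,
                      object_ids = c("obj01", "ghost")),
    "ghost")
  expect_true(is.na(tab2$dwell_pct[tab2$object_id == "ghost"]))
})

test_that("enlarging the margin never decreases any dwell percentage", {
  sc <- scenario_script(
    duration_s = 8, noise_sigma_deg = 0.6, seed = 23,
    objects = list(
      scenario_object("tracked", 0, 8, x_start = -1800, x_end = 1800,
                      w_start = 150, w_end = 300, h_start = 120, h_end = 240),
      scenario_object("bystander", 1, 7, x_start = 900, x_end = -900,
                      y_start = -200, y_end = 200)),
    gaze_target = "tracked",
    blinks = data.frame(onset_s = c(2, 5.5), duration_s = c(0.18, 0.22)))
  scn <- generate_scenario(sc)
  pooled <- pool_surfaces(scn$surfaces, scn$layout, scn$geom)
  prep <- preprocess_gaze(pooled)
  pcts <- sapply(c(0, 0.5, 1, 1.5, 2), function(m) {
    match_gaze_aois(prep$gaze, scn$trajectories, m, scn$geom)$dwell_pct
  })
  expect_true(all(diff(t(pcts)) >= -1e-9))  # per object, along margins
})
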