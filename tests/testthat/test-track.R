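test_that("a rightward-stepping particle forms one track; leftward links are gated out", {
  frames <- lapply(0:9, function(f) data.frame(x = 10 + 2 * f, y = 5))
  tp <- tracking_params(max_link_distance = 3)
  ts <- link(frames, tp, pixel_size = 1, frame_interval = 1)
  expect_equal(nrow(ts$summary), 1)
  expect_equal(nrow(ts$tracks), 10)

  back <- lapply(0:9, function(f) data.frame(x = 40 - 2 * f, y = 5))
  tsb <- link(back, tp, pixel_size = 1, frame_interval = 1)
  expect_equal(nrow(tsb$tracks), 0)       # singleton tracks fall below min length
  expect_equal(nrow(tsb$velocities), 0)
})

test_that("the angular gate is inclusive at the printed +-70 degree limit", {
  tp <- tracking_params(max_link_distance = 5)
  for (ang in c(69.9, -69.9, 70.0)) {
    d <- list(data.frame(x = 0, y = 0),
              data.frame(x = 2 * cos(ang * pi / 180), y = 2 * sin(ang * pi / 180)))
    expect_equal(nrow(link(d, tp, 1, 1)$velocities), 1,
                 info = sprintf("angle %g should link", ang))
  }
  for (ang in c(70.1, -70.1, 180)) {
    d <- list(data.frame(x = 0, y = 0),
              data.frame(x = 2 * cos(ang * pi / 180), y = 2 * sin(ang * pi / 180)))
    expect_equal(nrow(link(d, tp, 1, 1)$velocities), 0,
                 info = sprintf("angle %g should be rejected", ang))
  }
  # a stationary detection carries no direction and still links
  still <- list(data.frame(x = 3, y = 3), data.frame(x = 3, y = 3))
  ts <- link(still, tp, 1, 1)
  expect_equal(ts$velocities$v, 0)
})

test_that("assignment equals the brute-force optimum on random frame pairs", {
  withr::local_seed(61)
  tp <- tracking_params(max_link_distance = 6, min_track_length = 1)
  for (case in 1:30) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    from <- data.frame(x = runif(n1, 0, 10), y = runif(n1, 0, 10))
    to <- data.frame(x = runif(n2, 0, 10), y = runif(n2, 0, 10))
    ts <- link(list(from, to), tp, pixel_size = 1, frame_interval = 1)
    got <- linkset_cost(ts, from, to, 1)
    gc <- gate_costs(from, to, 6, 0, 70, 1)
    want <- oracle_best_matching(gc$cost, gc$admissible)
    expect_equal(got$n_links, want$n_links, info = sprintf("case %d", case))
    expect_equal(got$total_cost, want$total_cost, tolerance = 1e-9,
                 info = sprintf("case %d", case))
  }
})

test_that("no accepted link ever violates the angular or distance gate", {
  withr::local_seed(62)
  tp <- tracking_params(max_link_distance = 4, min_track_length = 2)
  for (rep in 1:5) {
    frames <- lapply(1:8, function(f)
      data.frame(x = runif(6, 0, 20), y = runif(6, 0, 20)))
    ts <- link(frames, tp, pixel_size = 1, frame_interval = 1)
    for (id in unique(ts$tracks$track_id)) {
      pts <- ts$tracks[ts$tracks$track_id == id, ]
      if (nrow(pts) < 2) next
      dx <- diff(pts$x); dy <- diff(pts$y)
      dist <- sqrt(dx^2 + dy^2)
      expect_true(all(dist <= 4 + 1e-9))
      dev <- abs(((atan2(dy, dx) * 180 / pi + 180) %% 360) - 180)
      expect_true(all(dist == 0 | dev <= 70 + 1e-6))
    }
  }
})

test_that("instantaneous velocity applies the physical calibration", {
  tr <- data.frame(frame = 1:5, x = c(0, 2, 4, 6, 8), y = 0)
  v <- instantaneous_velocity(tr, pixel_size = 0.5, frame_interval = 0.1)
  expect_equal(v, rep(10, 4))
  expect_equal(instantaneous_velocity(data.frame(frame = 1:3, x = 1, y = 1), 1, 1),
               c(0, 0))
  expect_error(link(list(data.frame(x = 1, y = 1), data.frame(x = 2, y = 1)),
                    tracking_params(max_link_distance = 2)),
               class = "pcquant_calibration_error")
})

test_that("velocities recover the planted flow exactly and under pulsatility", {
  m <- gen_flow_movie(speed_mean = 10, speed_pulsatility = 0, n_frames = 100,
                      pixel_size = 0.5, frame_interval = 0.1, snr = Inf, seed = 8)
  dets <- lapply(split(m$truth$positions, m$truth$positions$frame),
                 function(d) data.frame(x = d$x / 0.5, y = d$y / 0.5))
  ts <- link(dets, tracking_params(max_link_distance = 3), 0.5, 0.1)
  expect_true(all(abs(ts$velocities$v - 10) < 1e-9))

  mp <- gen_flow_movie(speed_mean = 10, speed_pulsatility = 0.2, n_frames = 100,
                       pixel_size = 0.5, frame_interval = 0.1, snr = Inf, seed = 9)
  dp <- lapply(split(mp$truth$positions, mp$truth$positions$frame),
               function(d) data.frame(x = d$x / 0.5, y = d$y / 0.5))
  tsp <- link(dp, tracking_params(max_link_distance = 3), 0.5, 0.1)
  expect_lt(abs(mean(tsp$velocities$v) - 10) / 10, 0.02)
  expect_gt(min(tsp$velocities$v), 7.9)
  expect_lt(max(tsp$velocities$v), 12.1)
})

test_that("gap closing bridges a missed detection when enabled", {
  frames <- list(data.frame(x = 0, y = 0),
                 data.frame(x = numeric(0), y = numeric(0)),
                 data.frame(x = 4, y = 0))
  no_gap <- link(frames, tracking_params(max_link_distance = 5), 1, 1)
  expect_equal(nrow(no_gap$velocities), 0)
  gap <- link(frames, tracking_params(max_link_distance = 5,
                                      allow_gap_frames = 1), 1, 1)
  expect_equal(nrow(gap$velocities), 1)
  expect_equal(gap$velocities$v, 2)       # 4 px over 2 frames
})
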