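test_that("displacement bound converts particle size to pixels", {
  expect_equal(max_displacement_px(2.4, 120), 20L)
  expect_equal(max_displacement_px(1.2, 120), 10L)
  expect_equal(max_displacement_px(2.4, 100), 24L)
})

test_that("a stationary particle yields one zero-length track", {
  det <- tibble::tibble(frame = 1:5, x = 1, y = 2)
  tr <- link_particles(det, max_disp = 1)
  expect_equal(length(unique(tr$track)), 1)
  m <- trajectory_metrics(tr, frame_interval_s = 1)
  expect_equal(m$total_path_length_um, 0)
  expect_equal(m$mean_speed_um_per_s, 0)
  expect_false(m$fast)
  expect_false(m$motile)
})

test_that("a jump beyond max_disp splits the trajectory", {
  det <- tibble::tibble(frame = 1:4, x = c(0, 0.1, 5, 5.1), y = 0)
  tr <- link_particles(det, max_disp = 1)
  expect_equal(length(unique(tr$track)), 2)
  expect_equal(unname(table(tr$track)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("every detection belongs to exactly one track", {
  set.seed(99)
  det <- tibble::tibble(frame = rep(1:6, each = 3),
                        x = runif(18, 0, 10), y = runif(18, 0, 10))
  tr <- link_particles(det, max_disp = 3)
  expect_equal(nrow(tr), nrow(det))
  expect_false(any(is.na(tr$track)))
  # within a track, one detection per frame
  expect_false(any(duplicated(tr[c("track", "frame")])))
})

test_that("crossing particles are linked at the exhaustive minimum cost", {
  # 3 particles x 4 frames crossing paths
  det <- tibble::tibble(
    frame = rep(1:4, each = 3),
    x = c(0, 5, 10,  2, 5, 8,  4, 5, 6,  6, 5, 4),
    y = rep(c(0, 1, 2), 4))
  md <- 3.5
  tr <- link_particles(det, max_disp = md)
  frames <- 1:4
  oracle <- 0
  for (fi in 2:4) {
    h <- det[det$frame == fi - 1, ]; d <- det[det$frame == fi, ]
    oracle <- oracle + oracle_assignment_cost(h$x, h$y, d$x, d$y, md)
  }
  expect_equal(realised_linking_cost(tr, det, md), oracle, tolerance = 1e-9)
})

test_that("linking matches the exhaustive oracle over random small instances", {
  for (s in 1:60) {
    set.seed(s)
    n_p <- sample(1:4, 1); n_f <- sample(2:5, 1)
    det <- tibble::tibble(
      frame = rep(seq_len(n_f), each = n_p),
      x = runif(n_p * n_f, 0, 4), y = runif(n_p * n_f, 0, 4))
    md <- runif(1, 0.8, 3)
    tr <- link_particles(det, max_disp = md)
    # every link respects the bound
    steps <- tr |>
      dplyr::arrange(track, frame) |>
      dplyr::group_by(track) |>
      dplyr::summarise(ok = all(sqrt(diff(x)^2 + diff(y)^2) <= md + 1e-12),
                       .groups = "drop")
    expect_true(all(steps$ok))
    oracle <- 0
    fr <- sort(unique(det$frame))
    for (fi in seq_along(fr)[-1]) {
      h <- det[det$frame == fr[fi - 1], ]; d <- det[det$frame == fr[fi], ]
      oracle <- oracle + oracle_assignment_cost(h$x, h$y, d$x, d$y, md)
    }
    expect_equal(realised_linking_cost(tr, det, md), oracle, tolerance = 1e-9)
  }
})

test_that("gap closing bridges a one-frame disappearance only with memory", {
  det <- tibble::tibble(frame = c(1, 2, 4, 5), x = c(0, 0.1, 0.3, 0.4), y = 0)
  expect_equal(length(unique(link_particles(det, 1, memory = 0)$track)), 2)
  expect_equal(length(unique(link_particles(det, 1, memory = 1)$track)), 1)
})

test_that("an overdense subnetwork errors with advice", {
  det <- tibble::tibble(frame = rep(1:2, each = 10),
                        x = rep(seq(0, 0.9, 0.1), 2), y = 0)
  expect_error(link_particles(det, max_disp = 5, cap = 6), "down-sample")
})

test_that("trajectory metrics flag fast and motile tracks", {
  det <- tibble::tibble(frame = 1:5, x = seq(0, 2, 0.5), y = 0)
  m <- trajectory_metrics(link_particles(det, 1), frame_interval_s = 1)
  expect_equal(m$mean_speed_um_per_s, 0.5)
  expect_true(m$fast)    # > 0.3 um/s
  expect_true(m$motile)  # 2 um path > 1.2 um
  expect_error(trajectory_metrics(link_particles(det, 1), 0), "positive")
})

test_that("programmed speeds are recovered within tolerance", {
  recover_speed <- function(speed, noise_sd, seed) {
    mm <- motion_model("directed", speed_um_per_s = speed, direction_deg = 35)
    sc <- generate_scene(scene_config(
      image_size_px = c(160, 160), n_round = 1, n_tubular = 0, n_frames = 10,
      noise_sd = noise_sd, motion_models = list(mm), contact_fraction = 0,
      seed = seed))
    det <- detect_stack(sc$lyso, 120) |>
      dplyr::transmute(frame, x = x_um, y = y_um)
    tr <- link_particles(det, max_disp = 2.4)
    trajectory_metrics(tr, 1)$mean_speed_um_per_s[1]
  }
  for (v in c(0.1, 0.4, 0.7, 1.0)) {
    expect_equal(recover_speed(v, 0, seed = 50 + round(10 * v)), v,
                 tolerance = 0.05)
  }
  # SNR 5 (amplitude 0.6, noise 0.12): within 15%; spurious noise
  # detections make single-point tracks, dropped with a warning
  expect_equal(suppressWarnings(recover_speed(0.6, 0.12, seed = 77)), 0.6,
               tolerance = 0.15)
})

test_that("transition events report before/after speeds from construction", {
  # 0.1 um/s while round (6 steps) then 0.6 um/s while tubular (6 steps)
  x <- c(seq(0, 0.5, 0.1), seq(1.1, 4.1, 0.6))
  tr <- tibble::tibble(track = 1L, frame = seq_along(x), x = x, y = 0,
                       shape_class = rep(c("round", "tubular"), each = 6))
  ev <- transition_speeds(tr, frame_interval_s = 1, window_frames = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "round->tubular")
  expect_equal(ev$speed_before_um_per_s, 0.1, tolerance = 1e-9)
  expect_equal(ev$speed_after_um_per_s, 0.6, tolerance = 1e-9)
  expect_lt(ev$speed_before_um_per_s, ev$speed_after_um_per_s)

  # no class change -> no events
  tr2 <- dplyr::mutate(tr, shape_class = "round")
  expect_equal(nrow(transition_speeds(tr2, 1)), 0)

  # two alternating changes -> two events in frame order
  cls <- rep(c("round", "tubular", "round"), each = 5)
  tr3 <- tibble::tibble(track = 1L, frame = 1:15,
                        x = cumsum(rep(0.2, 15)), y = 0, shape_class = cls)
  ev3 <- transition_speeds(tr3, 1, window_frames = 2)
  expect_equal(nrow(ev3), 2)
  expect_true(all(diff(ev3$frame) > 0))
  expect_equal(ev3$direction, c("round->tubular", "tubular->round"))
})
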