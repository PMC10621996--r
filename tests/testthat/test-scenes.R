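test_that("empty scene gives background-only stack and empty truth", {
  sc <- generate_scene(scene_config(n_round = 0, n_tubular = 0,
                                    noise_sd = 0, seed = 1))
  expect_equal(nrow(sc$truth), 0)
  expect_equal(max(sc$lyso), sc$config$background, tolerance = 1e-12)
  expect_equal(min(sc$lyso), sc$config$background, tolerance = 1e-12)
})

test_that("same config and seed reproduce bit-identical scenes", {
  cfg <- scene_config(n_round = 5, n_tubular = 3, n_frames = 3,
                      noise_sd = 0.05, seed = 7)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$lyso, b$lyso)
  expect_identical(a$er, b$er)
  expect_identical(a$er_mask, b$er_mask)
  expect_identical(a$truth, b$truth)
})

test_that("contact_fraction = 1 seeds every lysosome on an ER edge", {
  sc <- generate_scene(scene_config(n_round = 8, n_tubular = 0,
                                    contact_fraction = 1, noise_sd = 0,
                                    seed = 3))
  half_ridge_um <- sc$config$er_tubule_width_nm / 1000 / 2
  pts <- sc$er_graph$points
  eg <- sc$er_graph$edges
  t1 <- dplyr::filter(sc$truth, frame == 1)
  seg_dist <- function(p) {
    min(vapply(seq_len(nrow(eg)), function(e) {
      a <- pts[eg[e, 1], ]; b <- pts[eg[e, 2], ]
      ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      sqrt(sum((p - (a + t * ab))^2))
    }, numeric(1)))
  }
  d <- vapply(seq_len(nrow(t1)),
              function(i) seg_dist(c(t1$x_um[i], t1$y_um[i])), numeric(1))
  expect_true(all(d <= half_ridge_um + 1e-9))
  expect_true(all(t1$on_er))
})

test_that("zero-noise well-separated scene is fully recoverable by segmentation", {
  sc <- clean_scene(n_round = 7, n_tubular = 5, seed = 21)
  mask <- binarize_spots(sc$lyso[, , 1], scale_px = 2)
  expect_equal(max(label_mask(mask)), 12)
})

test_that("directed motion advances truth positions by speed x interval", {
  mm <- motion_model("directed", speed_um_per_s = 0.8, direction_deg = 30)
  sc <- generate_scene(scene_config(n_round = 2, n_tubular = 0, n_frames = 6,
                                    noise_sd = 0, motion_models = list(mm),
                                    seed = 9))
  steps <- sc$truth |>
    dplyr::arrange(object_id, frame) |>
    dplyr::group_by(object_id) |>
    dplyr::reframe(d = sqrt(diff(x_um)^2 + diff(y_um)^2))
  expect_equal(steps$d, rep(0.8 * 1, nrow(steps)), tolerance = 1e-9)
})

test_that("shape transitions appear in the truth at the programmed frame", {
  sc <- generate_scene(scene_config(n_round = 4, n_tubular = 0, n_frames = 8,
                                    n_transition = 2, noise_sd = 0, seed = 5))
  tf <- unique(sc$truth$transition_frame[!is.na(sc$truth$transition_frame)])
  expect_equal(tf, 4L)
  sw <- dplyr::filter(sc$truth, !is.na(transition_frame))
  expect_true(all(sw$shape_class[sw$frame < 4] == "round"))
  expect_true(all(sw$shape_class[sw$frame >= 4] == "tubular"))
})

test_that("infeasible object counts raise an explicit error", {
  expect_error(
    generate_scene(scene_config(image_size_px = c(32, 32), n_round = 50,
                                n_tubular = 10, seed = 1)),
    "infeasible|do not fit")
})

test_that("axon scene honours programmed direction classes", {
  cfg <- axon_scene_config(n_lysosomes = 10, fractions = c(1, 0, 0),
                           noise_sd = 0, seed = 4)
  ax <- generate_axon_scene(cfg)
  net <- ax$truth |>
    dplyr::arrange(object_id, frame) |>
    dplyr::group_by(object_id) |>
    dplyr::summarise(net = s_um[dplyr::n()] - s_um[1], .groups = "drop")
  expect_true(all(net$net > 0))

  cfg2 <- axon_scene_config(n_lysosomes = 6, fractions = c(0, 0, 1),
                            jitter_um_sd = 0, noise_sd = 0, seed = 4)
  ax2 <- generate_axon_scene(cfg2)
  spread <- ax2$truth |>
    dplyr::group_by(object_id) |>
    dplyr::summarise(rng = diff(range(s_um)), .groups = "drop")
  expect_true(all(spread$rng == 0))
})

test_that("axon class counts follow the fractions exactly", {
  ax <- generate_axon_scene(axon_scene_config(
    n_lysosomes = 40, fractions = c(0.5, 0.5, 0), seed = 11))
  counts <- ax$truth |>
    dplyr::distinct(object_id, class) |>
    dplyr::count(class)
  expect_equal(counts$n[counts$class == "anterograde"], 20)
  expect_equal(counts$n[counts$class == "retrograde"], 20)
})

test_that("config validation rejects bad inputs", {
  expect_error(scene_config(contact_fraction = 1.5), "contact_fraction")
  expect_error(scene_config(n_transition = 5, n_round = 2), "n_transition")
  expect_error(axon_scene_config(fractions = c(0.5, 0.2, 0.2)), "summing to 1")
  expect_error(motion_model("directed", speed_um_per_s = -1), "speed")
})
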