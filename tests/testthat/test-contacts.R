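square_mask <- function(n, rows, cols) {
  m <- matrix(0, n, n); m[rows, cols] <- 1; m
}

test_that("overlap fractions cover the full/none/half constructions", {
  ly <- square_mask(20, 5:14, 5:14)
  expect_equal(overlap_fraction(ly, matrix(1, 20, 20))$overlap_fraction, 1)
  expect_equal(overlap_fraction(ly, square_mask(20, 16:20, 16:20))$overlap_fraction, 0)
  # ER strip covering 5 of the 10 columns -> 0.5
  er <- square_mask(20, 1:20, 5:9)
  r <- overlap_fraction(ly, er)
  expect_equal(r$overlap_fraction, 0.5)
  expect_true(r$in_contact)  # 0.5 > 0.30
  expect_equal(nrow(overlap_fraction(matrix(0, 20, 20), er)), 0)
})

test_that("overlap is invariant under a shared rigid shift of both masks", {
  ly <- square_mask(30, 8:13, 6:15)
  er <- square_mask(30, 1:30, 9:11)
  shift <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  a <- overlap_fraction(ly, er)$overlap_fraction
  b <- overlap_fraction(shift(ly, 4, 7), shift(er, 4, 7))$overlap_fraction
  expect_equal(a, b)
})

test_that("apparent overlap reproduces the printed imaging geometry", {
  r <- apparent_overlap(500, 10, 50, 120)
  expect_equal(r$overlap_nm, 230)
  expect_equal(r$apparent_lysosome_diameter_nm, 740)
  expect_equal(round(r$percent_of_diameter, -1), 30)  # "about 30%"
  # gap equal to the two-pixel spread -> zero overlap
  expect_equal(apparent_overlap(500, 240, 50, 120)$overlap_nm, 0)
})

test_that("apparent overlap is monotone in gap and pixel size", {
  gaps <- c(0, 10, 50, 100, 240, 400)
  ov_gap <- vapply(gaps, function(g) apparent_overlap(500, g, 50, 120)$overlap_nm,
                   numeric(1))
  expect_true(all(diff(ov_gap) <= 0))
  px <- c(60, 90, 120, 160, 200)
  ov_px <- vapply(px, function(p) apparent_overlap(500, 10, 50, p)$overlap_nm,
                  numeric(1))
  expect_true(all(diff(ov_px) >= 0))
})

test_that("the 90-degree flip control destroys structured overlap", {
  # full-coverage ER: flip changes nothing
  ly <- square_mask(20, 5:8, 5:8)
  expect_equal(flip_control(ly, matrix(1, 20, 20))$overlap_fraction, 1)
  # lysosome on a vertical ER stripe moves off it under rotation
  n <- 41
  er <- square_mask(n, 1:n, 19:23)
  ly2 <- square_mask(n, 5:8, 20:22)   # on the stripe, far from centre
  expect_equal(overlap_fraction(ly2, er)$overlap_fraction, 1)
  expect_equal(flip_control(ly2, er)$overlap_fraction, 0)
  # synthetic scene: flipped mean overlap below structured mean overlap
  sc <- generate_scene(scene_config(n_round = 10, n_tubular = 0,
                                    contact_fraction = 1, noise_sd = 0,
                                    seed = 11))
  lym <- binarize_spots(sc$lyso[, , 1], 2)
  expect_lt(mean(flip_control(lym, sc$er_mask)$overlap_fraction),
            mean(overlap_fraction(lym, sc$er_mask)$overlap_fraction))
})

test_that("contact calls increase with the programmed contact fraction", {
  frac_in_contact <- vapply(c(0, 0.5, 1), function(cf) {
    sc <- generate_scene(scene_config(n_round = 10, n_tubular = 0,
                                      contact_fraction = cf, noise_sd = 0,
                                      seed = 19))
    lym <- binarize_spots(sc$lyso[, , 1], 2)
    mean(overlap_fraction(lym, sc$er_mask)$in_contact)
  }, numeric(1))
  expect_true(all(diff(frac_in_contact) >= 0))
  expect_lt(frac_in_contact[1], frac_in_contact[3])
})

test_that("membrane proximity scores boundary distances against the cutoff", {
  # EM-like pixels: 5 nm. Touching masks are within any cutoff.
  ly <- square_mask(40, 15:24, 15:24)
  er <- square_mask(40, 15:24, 25:34)
  r <- membrane_proximity(ly, er, pixel_size_nm = 5, cutoff_nm = 30)
  expect_true(r$is_near)
  expect_gt(r$fraction_of_boundary_near, 0)
  # separation beyond the cutoff everywhere
  er_far <- square_mask(40, 1:3, 1:3)
  expect_false(membrane_proximity(ly, er_far, 5, 30)$is_near)
  # slab at exact distance d: near edge length is countable
  n <- 60
  ly3 <- square_mask(n, 21:30, 21:30)        # 10x10 square
  er3 <- square_mask(n, 1:n, 35:40)          # vertical slab, 4 px gap
  # gap between column 30 and column 35 boundary pixels = 5 px = 25 nm
  r3 <- membrane_proximity(ly3, er3, pixel_size_nm = 5, cutoff_nm = 25)
  expect_true(r3$is_near)
  # only the right edge of the square (10 of 36 boundary px) is at 25 nm
  expect_equal(r3$fraction_of_boundary_near, 10 / 36, tolerance = 1e-12)
  expect_equal(r3$min_distance_nm, 25)
  # sub-pixel cutoff warns
  expect_warning(membrane_proximity(ly3, er3, pixel_size_nm = 120,
                                    cutoff_nm = 30), "below one pixel")
})

test_that("spot colocalization classes and proportions follow construction", {
  n <- 30
  a <- square_mask(n, 1:15, 1:n)    # top half
  b <- square_mask(n, 1:n, 1:15)    # left half
  # construct 4 both / 3 a-only / 2 b-only / 1 neither (0-based coords)
  spots <- tibble::tibble(
    x_px = c(2, 4, 6, 8,   20, 22, 24,  2, 4,   25),
    y_px = c(2, 4, 6, 8,    2,  4,  6, 20, 22,  25))
  cl <- spot_colocalization(spots, a, b)
  pr <- coloc_proportions(cl)
  expect_equal(pr$proportion[pr$class == "both"], 0.4)
  expect_equal(pr$proportion[pr$class == "mask_a_only"], 0.3)
  expect_equal(pr$proportion[pr$class == "mask_b_only"], 0.2)
  expect_equal(pr$proportion[pr$class == "neither"], 0.1)
  expect_warning(spot_colocalization(spots[0, ], a, b), "No spots")
  expect_error(spot_colocalization(tibble::tibble(x_px = 99, y_px = 0), a, b),
               "bounds")
})
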