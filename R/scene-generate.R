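#' Generate a synthetic two-channel lysosome/ER time-lapse
#'
#' Renders a time-lapse of round (disc) and tubular (capsule) lysosomes
#' moving over a static reticular ER network, with exact per-frame
#' ground truth, so that detection, classification, contact scoring and
#' tracking can all be validated against known answers. Rendering is
#' anti-aliased coverage rasterization followed by a Gaussian
#' point-spread blur and additive Gaussian noise; output is
#' deterministic for a given config (same seed, bit-identical stacks).
#'
#' Objects are placed with a minimum mutual separation; a fraction
#' `contact_fraction` of them is seeded with its centroid exactly on an
#' ER ridge midline. Motion models (stationary jitter, diffusive,
#' directed runs) are sampled per object; positions reflect at the image
#' margins so objects stay in bounds.
#'
#' @param config A [scene_config()].
#' @return A `lyso_scene` list: `lyso` and `er` intensity arrays
#'   (`ny x nx x n_frames`), `er_mask` (binary matrix, ground-truth ER
#'   footprint), `truth` (tibble: `frame`, `object_id`, `x_um`, `y_um`,
#'   `shape_class`, `motion_kind`, `on_er`, `orientation_deg`,
#'   `transition_frame`), and `config`.
#' @examples
#' sc <- generate_scene(scene_config(n_round = 3, n_tubular = 1,
#'                                   n_frames = 2, seed = 7))
#' dim(sc$lyso)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  ny <- cfg$image_size_px[1]; nx <- cfg$image_size_px[2]
  px_um <- cfg$pixel_size_nm / 1000
  size_um <- c(x = nx * px_um, y = ny * px_um)
  n_obj <- cfg$n_round + cfg$n_tubular

  er <- make_er_network(cfg)

  # --- placement ------------------------------------------------------
  margin <- max(cfg$tubule_length_um / 2, cfg$round_radius_um) + 2 * px_um
  if (2 * margin >= min(size_um) && n_obj > 0)
    abort("Objects do not fit: image smaller than one object plus margins.")
  usable_area <- max(0, (size_um["x"] - 2 * margin) * (size_um["y"] - 2 * margin))
  if (n_obj > 0 && usable_area < n_obj * (cfg$min_separation_um / 2)^2 * pi)
    abort("Object count infeasible for this image size and separation.")

  shape <- rep(c("round", "tubular"), c(cfg$n_round, cfg$n_tubular))
  on_er <- rep(FALSE, n_obj)
  if (n_obj > 0) on_er <- runif(n_obj) < cfg$contact_fraction

  # --- motion (sampled before placement: a directed run constrains the
  # start point so the whole run stays inside the margins and the
  # programmed speed is preserved exactly) -----------------------------
  wts <- cfg$motion_weights / sum(cfg$motion_weights)
  mm_idx <- if (n_obj > 0)
    sample.int(length(cfg$motion_models), n_obj, replace = TRUE, prob = wts)
  else integer(0)
  dt <- cfg$frame_interval_s
  t_total <- (cfg$n_frames - 1) * dt
  ang <- rep(NA_real_, n_obj)
  run_vec <- matrix(0, max(n_obj, 1), 2)
  for (i in seq_len(n_obj)) {
    mm <- cfg$motion_models[[mm_idx[i]]]
    if (mm$kind == "directed") {
      ang[i] <- if (is.na(mm$direction_deg)) runif(1, 0, 360)
                else mm$direction_deg
      run_vec[i, ] <- mm$speed_um_per_s * t_total *
        c(cospi(ang[i] / 180), sinpi(ang[i] / 180))
    }
  }

  # --- placement ------------------------------------------------------
  pos <- matrix(NA_real_, n_obj, 2)
  for (i in seq_len(n_obj)) {
    lo <- c(margin + max(0, -run_vec[i, 1]), margin + max(0, -run_vec[i, 2]))
    hi <- c(size_um["x"] - margin - max(0, run_vec[i, 1]),
            size_um["y"] - margin - max(0, run_vec[i, 2]))
    if (any(lo >= hi)) {  # run longer than the field: reflection handles it
      lo <- c(margin, margin)
      hi <- c(size_um["x"] - margin, size_um["y"] - margin)
    }
    placed <- FALSE
    for (try in seq_len(2000L)) {
      p <- if (on_er[i] && nrow(er$edges) > 0) {
        random_edge_point(er)
      } else {
        c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      }
      inside <- p[1] >= lo[1] && p[1] <= hi[1] &&
        p[2] >= lo[2] && p[2] <= hi[2]
      if (!inside) next
      if (i == 1L ||
          all(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2)) >=
              cfg$min_separation_um)) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      abort("Could not place all objects: count infeasible for this scene.")
  }
  orient <- runif(max(n_obj, 0), 0, 180)

  # --- trajectories ---------------------------------------------------
  traj <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    mm <- cfg$motion_models[[mm_idx[i]]]
    xy <- matrix(NA_real_, cfg$n_frames, 2)
    xy[1, ] <- pos[i, ]
    if (cfg$n_frames > 1) {
      step <- switch(mm$kind,
        stationary = matrix(rnorm(2 * (cfg$n_frames - 1), 0, mm$jitter_um_sd),
                            ncol = 2),
        diffusive = matrix(rnorm(2 * (cfg$n_frames - 1), 0,
                                 sqrt(2 * mm$diffusion_coeff_um2_per_s * dt)),
                           ncol = 2),
        directed = matrix(rep(mm$speed_um_per_s * dt *
                                c(cospi(ang[i] / 180), sinpi(ang[i] / 180)),
                              each = cfg$n_frames - 1), ncol = 2))
      if (mm$kind == "stationary") {
        # jitter around the anchor point, not a random walk
        xy[-1, ] <- rep(pos[i, ], each = cfg$n_frames - 1) + step
      } else {
        xy[-1, 1] <- pos[i, 1] + cumsum(step[, 1])
        xy[-1, 2] <- pos[i, 2] + cumsum(step[, 2])
      }
      xy[, 1] <- reflect_into(xy[, 1], margin, size_um["x"] - margin)
      xy[, 2] <- reflect_into(xy[, 2], margin, size_um["y"] - margin)
    }
    traj[[i]] <- xy
  }

  trans_frame <- rep(NA_integer_, n_obj)
  if (cfg$n_transition > 0) {
    rounds <- which(shape == "round")
    trans_frame[rounds[seq_len(cfg$n_transition)]] <-
      as.integer(max(2, floor(cfg$n_frames / 2)))
  }

  # --- truth table ----------------------------------------------------
  truth <- map(seq_len(n_obj), function(i) {
    cls <- rep(shape[i], cfg$n_frames)
    if (!is.na(trans_frame[i]))
      cls[seq_len(cfg$n_frames) >= trans_frame[i]] <- "tubular"
    tibble(
      frame = seq_len(cfg$n_frames), object_id = i,
      x_um = traj[[i]][, 1], y_um = traj[[i]][, 2],
      shape_class = cls,
      motion_kind = cfg$motion_models[[mm_idx[i]]]$kind,
      on_er = on_er[i], orientation_deg = orient[i],
      transition_frame = trans_frame[i]
    )
  }) |> list_rbind()
  if (n_obj == 0L)
    truth <- tibble(frame = integer(), object_id = integer(), x_um = double(),
                    y_um = double(), shape_class = character(),
                    motion_kind = character(), on_er = logical(),
                    orientation_deg = double(), transition_frame = integer())

  # --- rendering ------------------------------------------------------
  er_frame <- render_er(er, cfg)
  er$mask <- attr(er_frame, "mask")
  attr(er_frame, "mask") <- NULL
  lyso <- array(0, c(ny, nx, cfg$n_frames))
  er_stack <- array(0, c(ny, nx, cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    cov <- matrix(0, ny, nx)
    for (i in seq_len(n_obj)) {
      cls <- if (!is.na(trans_frame[i]) && f >= trans_frame[i]) "tubular"
             else shape[i]
      cov <- if (cls == "round") {
        add_disc(cov, traj[[i]][f, ], cfg$round_radius_um, px_um)
      } else {
        add_capsule(cov, traj[[i]][f, ], cfg$tubule_length_um,
                    cfg$tubule_width_um, orient[i], px_um)
      }
    }
    img <- cfg$background + cfg$amplitude *
      as.matrix(EBImage::gblur(cov, sigma = cfg$psf_sigma_px,
                               boundary = "replicate"))
    if (cfg$noise_sd > 0) img <- img + rnorm(ny * nx, 0, cfg$noise_sd)
    lyso[, , f] <- img
    ef <- cfg$background + cfg$amplitude *
      as.matrix(EBImage::gblur(er_frame, sigma = cfg$psf_sigma_px,
                               boundary = "replicate"))
    if (cfg$noise_sd > 0) ef <- ef + rnorm(ny * nx, 0, cfg$noise_sd)
    er_stack[, , f] <- ef
  }

  structure(list(lyso = lyso, er = er_stack, er_mask = er$mask,
                 er_graph = er[c("points", "edges")], truth = truth,
                 config = cfg),
            class = "lyso_scene")
}

# --- ER network -------------------------------------------------------

# Poisson point sample + Gabriel graph (every Gabriel edge is a Delaunay
# edge: its diametral circle is empty of other points), rendered later
# as fixed-width ridges. Gives a connected-looking reticular network
# with density controlled by the point intensity.
make_er_network <- function(cfg) {
  ny <- cfg$image_size_px[1]; nx <- cfg$image_size_px[2]
  px_um <- cfg$pixel_size_nm / 1000
  area <- nx * px_um * ny * px_um
  n <- max(4L, rpois(1, cfg$er_density * area))
  pts <- cbind(runif(n, 0, nx * px_um), runif(n, 0, ny * px_um))
  edges <- gabriel_edges(pts)
  mask <- matrix(FALSE, ny, nx)
  list(points = pts, edges = edges, mask = mask, px_um = px_um)
}

# Gabriel graph by the empty diametral circle test, O(n^3) but n is tens
# of points at realistic ER seed densities.
gabriel_edges <- function(pts) {
  n <- nrow(pts)
  out <- matrix(integer(0), 0, 2)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      r2 <- sum((pts[i, ] - mid)^2)
      d2 <- (pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2
      d2[c(i, j)] <- Inf
      if (all(d2 > r2)) out <- rbind(out, c(i, j))
    }
  }
  out
}

random_edge_point <- function(er) {
  len <- sqrt(rowSums((er$points[er$edges[, 1], , drop = FALSE] -
                         er$points[er$edges[, 2], , drop = FALSE])^2))
  e <- sample.int(nrow(er$edges), 1, prob = len)
  t <- runif(1)
  (1 - t) * er$points[er$edges[e, 1], ] + t * er$points[er$edges[e, 2], ]
}

# Rasterize the ER graph as anti-aliased ridges; also fills er$mask via
# the calling scene (mask = pixels whose centre is within half a pixel
# of the ridge footprint).
render_er <- function(er, cfg) {
  ny <- cfg$image_size_px[1]; nx <- cfg$image_size_px[2]
  px_um <- cfg$pixel_size_nm / 1000
  halfw_px <- (cfg$er_tubule_width_nm / 1000 / 2) / px_um
  img <- matrix(0, ny, nx)
  mask <- matrix(FALSE, ny, nx)
  for (e in seq_len(nrow(er$edges))) {
    a <- er$points[er$edges[e, 1], ] / px_um  # px coords (0-based centres)
    b <- er$points[er$edges[e, 2], ] / px_um
    box <- seg_box(a, b, halfw_px + 2, ny, nx)
    if (is.null(box)) next
    d <- dist_to_segment(box$X, box$Y, a, b)
    cov <- pmin(1, pmax(0, halfw_px - d + 0.5))
    img[box$rows, box$cols] <- pmax(img[box$rows, box$cols], cov)
    mask[box$rows, box$cols] <- mask[box$rows, box$cols] | (d <= halfw_px + 0.5)
  }
  attr(img, "mask") <- mask
  img
}

seg_box <- function(a, b, pad, ny, nx) {
  r0 <- max(1, floor(min(a[2], b[2]) - pad) + 1)
  r1 <- min(ny, ceiling(max(a[2], b[2]) + pad) + 1)
  c0 <- max(1, floor(min(a[1], b[1]) - pad) + 1)
  c1 <- min(nx, ceiling(max(a[1], b[1]) + pad) + 1)
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix(rep(cols - 1, each = length(rows)), length(rows))
  Y <- matrix(rep(rows - 1, length(cols)), length(rows))
  list(rows = rows, cols = cols, X = X, Y = Y)
}

dist_to_segment <- function(X, Y, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((X - a[1])^2 + (Y - a[2])^2))
  t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2)
}

# --- object rasterizers ----------------------------------------------

add_disc <- function(cov, centre_um, radius_um, px_um) {
  c_px <- centre_um / px_um
  r_px <- radius_um / px_um
  box <- seg_box(c_px, c_px, r_px + 2, nrow(cov), ncol(cov))
  if (is.null(box)) return(cov)
  d <- sqrt((box$X - c_px[1])^2 + (box$Y - c_px[2])^2)
  cov[box$rows, box$cols] <-
    pmax(cov[box$rows, box$cols], pmin(1, pmax(0, r_px - d + 0.5)))
  cov
}

add_capsule <- function(cov, centre_um, length_um, width_um, angle_deg, px_um) {
  halfseg_px <- max(0, (length_um - width_um) / 2) / px_um
  halfw_px <- (width_um / 2) / px_um
  u <- c(cospi(angle_deg / 180), sinpi(angle_deg / 180))
  a <- centre_um / px_um - halfseg_px * u
  b <- centre_um / px_um + halfseg_px * u
  box <- seg_box(a, b, halfw_px + 2, nrow(cov), ncol(cov))
  if (is.null(box)) return(cov)
  d <- dist_to_segment(box$X, box$Y, a, b)
  cov[box$rows, box$cols] <-
    pmax(cov[box$rows, box$cols], pmin(1, pmax(0, halfw_px - d + 0.5)))
  cov
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(pmin(pmax(x, lo), hi))
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
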