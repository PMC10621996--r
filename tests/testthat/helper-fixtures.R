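# Shared fixtures, all built in code.

# Rasterize a disc mask of radius r px centred in an n x n image.
disc_mask <- function(r = 10, n = 2 * r + 21) {
  ctr <- (n - 1) / 2
  yy <- outer(0:(n - 1), rep(1, n))
  xx <- t(yy)
  (yy - ctr)^2 + (xx - ctr)^2 <= r^2
}

# Axis-aligned h x w rectangle of pixels in an n x n image.
rect_mask <- function(h = 4, w = 20, n = 30) {
  m <- matrix(FALSE, n, n)
  r0 <- floor((n - h) / 2); c0 <- floor((n - w) / 2)
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- TRUE
  m
}

# Independent pixel-moment oracle: ellipse axes/eccentricity straight
# from the pixel coordinate list (regionprops convention, +1/12).
moment_oracle <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  x <- ij[, 2] - 1; y <- ij[, 1] - 1
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  com <- (mu20 + mu02) / 2
  del <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- com + del; l2 <- max(com - del, 0)
  list(major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
       ecc = sqrt(max(1 - l2 / l1, 0)), area_px = length(x))
}

# Exhaustive minimum-cost frame-pair assignment oracle: enumerate every
# injective head -> detection map (within max_disp), unmatched nodes
# cost max_disp^2 each. No pruning, no subnetworks.
oracle_assignment_cost <- function(hx, hy, dx, dy, max_disp) {
  m <- length(hx); n <- length(dx)
  pen <- max_disp^2
  cost <- outer(hx, dx, "-")^2 + outer(hy, dy, "-")^2
  best <- Inf
  rec <- function(i, used, acc) {
    if (i > m) {
      best <<- min(best, acc + pen * sum(!used))
      return()
    }
    rec(i + 1, used, acc + pen)
    for (j in seq_len(n)) {
      if (!used[j] && cost[i, j] <= pen) {
        used[j] <- TRUE
        rec(i + 1, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, n), 0)
  best
}

# Frame-by-frame cost actually realised by a linking result.
realised_linking_cost <- function(tracks, det, max_disp) {
  pen <- max_disp^2
  frames <- sort(unique(det$frame))
  total <- 0
  for (fi in seq_along(frames)[-1]) {
    f0 <- frames[fi - 1]; f1 <- frames[fi]
    heads <- tracks[tracks$frame == f0, ]
    cur <- tracks[tracks$frame == f1, ]
    linked <- intersect(heads$track, cur$track)
    for (tr in linked) {
      a <- heads[heads$track == tr, ]; b <- cur[cur$track == tr, ]
      total <- total + (a$x - b$x)^2 + (a$y - b$y)^2
    }
    total <- total + pen * (nrow(heads) - length(linked)) +
      pen * (nrow(cur) - length(linked))
  }
  total
}

# Small zero-noise scene used by several recovery tests.
clean_scene <- function(n_round = 6, n_tubular = 4, n_frames = 1, seed = 42,
                        ...) {
  generate_scene(scene_config(
    n_round = n_round, n_tubular = n_tubular, n_frames = n_frames,
    noise_sd = 0, min_separation_um = 4, contact_fraction = 0,
    seed = seed, ...))
}
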