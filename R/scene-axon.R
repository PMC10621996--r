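#' Generate a synthetic axonal lysosome time-lapse
#'
#' Simulates lysosomes on a straight axon with programmed anterograde,
#' retrograde and stationary fractions, and renders a thin 2D time-lapse
#' (axon along x, soma at x = 0) ready for kymograph construction.
#' Anterograde particles move monotonically away from the soma,
#' retrograde particles towards it; stationary particles show bounded
#' Gaussian jitter. Initial axial positions are drawn so that directed
#' runs never leave the axon during the acquisition. Class counts
#' follow the programmed fractions exactly (largest-remainder
#' apportionment), so ground-truth proportions are recoverable without
#' sampling error.
#'
#' @param config An [axon_scene_config()].
#' @return An `axon_scene` list: `stack` (`ny x nx x n_frames` array),
#'   `path` (tibble of the axon polyline in 0-based pixel coordinates,
#'   soma end first), `truth` (tibble: `frame`, `object_id`, `s_um`
#'   axial position, `class`), and `config`.
#' @examples
#' ax <- generate_axon_scene(axon_scene_config(n_lysosomes = 4, seed = 2))
#' @export
generate_axon_scene <- function(config) {
  stopifnot(inherits(config, "axon_scene_config"))
  with_seed(config$seed, generate_axon_impl(config))
}

generate_axon_impl <- function(cfg) {
  px_um <- cfg$pixel_size_nm / 1000
  counts <- apportion(cfg$n_lysosomes, cfg$fractions)
  cls <- rep(names(cfg$fractions), counts)
  t_total <- (cfg$n_frames - 1) * cfg$frame_interval_s
  L <- cfg$axon_length_um
  s0 <- map_dbl(cls, function(cl) {
    switch(cl,
      anterograde = runif(1, 0, max(0, L - cfg$speed_anterograde_um_s * t_total)),
      retrograde = runif(1, min(L, cfg$speed_retrograde_um_s * t_total), L),
      stationary = runif(1, 0, L))
  })
  tt <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_s
  truth <- map(seq_along(cls), function(i) {
    s <- switch(cls[i],
      anterograde = s0[i] + cfg$speed_anterograde_um_s * tt,
      retrograde = s0[i] - cfg$speed_retrograde_um_s * tt,
      stationary = s0[i] + if (cfg$jitter_um_sd > 0)
        c(0, rnorm(cfg$n_frames - 1, 0, cfg$jitter_um_sd)) else 0)
    tibble(frame = seq_len(cfg$n_frames), object_id = i,
           s_um = pmin(pmax(s, 0), L), class = cls[i])
  }) |> list_rbind()

  ny <- 9L
  nx <- as.integer(ceiling(L / px_um)) + 3L
  y_mid <- (ny - 1) / 2  # 0-based row coordinate of the axon
  sigma <- cfg$psf_sigma_px
  stack <- array(0, c(ny, nx, cfg$n_frames))
  xs <- matrix(rep(0:(nx - 1), each = ny), ny)
  ysq <- (0:(ny - 1) - y_mid)^2
  for (f in seq_len(cfg$n_frames)) {
    img <- matrix(cfg$background, ny, nx)
    sf <- truth$s_um[truth$frame == f] / px_um
    for (x0 in sf) {
      g <- cfg$amplitude *
        exp(-(outer(ysq, (0:(nx - 1) - x0)^2, "+")) / (2 * sigma^2))
      img <- pmax(img, cfg$background + g)
    }
    if (cfg$noise_sd > 0) img <- img + rnorm(ny * nx, 0, cfg$noise_sd)
    stack[, , f] <- img
  }
  path <- tibble(x = c(0, nx - 1), y = c(y_mid, y_mid))
  structure(list(stack = stack, path = path, truth = truth, config = cfg),
            class = "axon_scene")
}

# Deterministic integer apportionment of n by fractions (largest
# remainder; ties towards the earlier class).
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
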