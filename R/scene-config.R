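#' Motion model for a simulated lysosome
#'
#' @param kind One of `"stationary"` (position jitter only),
#'   `"diffusive"` (Brownian steps), `"directed"` (constant-velocity
#'   run, emulating microtubule-dependent transport).
#' @param speed_um_per_s Run speed for directed motion (um/s).
#' @param diffusion_coeff_um2_per_s Diffusion coefficient for diffusive
#'   motion (um^2/s).
#' @param direction_deg Run direction for directed motion, degrees
#'   counter-clockwise from +x; `NA` draws a random direction per object.
#' @param jitter_um_sd Per-frame Gaussian positional jitter (um),
#'   applied to stationary objects.
#' @return A `motion_model` list.
#' @examples
#' motion_model("directed", speed_um_per_s = 0.8)
#' @export
motion_model <- function(kind = c("stationary", "diffusive", "directed"),
                         speed_um_per_s = 0.5,
                         diffusion_coeff_um2_per_s = 0.05,
                         direction_deg = NA_real_,
                         jitter_um_sd = 0.02) {
  kind <- match.arg(kind)
  if (speed_um_per_s < 0) abort("`speed_um_per_s` must be >= 0.")
  if (diffusion_coeff_um2_per_s < 0)
    abort("`diffusion_coeff_um2_per_s` must be >= 0.")
  if (jitter_um_sd < 0) abort("`jitter_um_sd` must be >= 0.")
  structure(list(kind = kind, speed_um_per_s = speed_um_per_s,
                 diffusion_coeff_um2_per_s = diffusion_coeff_um2_per_s,
                 direction_deg = direction_deg, jitter_um_sd = jitter_um_sd),
            class = "motion_model")
}

#' Configuration for a synthetic two-channel microscopy scene
#'
#' Describes a simulated field of round (disc) and tubular (capsule)
#' lysosomes moving over a reticular ER network, rendered with a
#' Gaussian point-spread blur and additive Gaussian noise. Defaults
#' emulate spinning-disk confocal imaging of fibroblasts at a 63x
#' objective: 120 nm pixels, one frame per second, ~500 nm round
#' lysosomes, 3.0 x 0.5 um tubules, and a 50 nm-wide ER tubule network.
#' (A 2.4 x 0.5 um capsule sits exactly at the circularity-0.5
#' classification boundary, so the default tubule is drawn mid-range at
#' 3 um; tubule dimensions are free parameters of the simulation.)
#'
#' @param image_size_px `c(ny, nx)` image size in pixels.
#' @param pixel_size_nm Pixel pitch (nm).
#' @param frame_interval_s Time between frames (s).
#' @param n_frames Number of frames.
#' @param n_round,n_tubular Object counts per class.
#' @param round_radius_um Radius of round lysosomes (um).
#' @param tubule_length_um,tubule_width_um Capsule dimensions (um),
#'   tip-to-tip length and full width.
#' @param er_density ER seed points per um^2; the network is the Gabriel
#'   graph (a Delaunay-edge subset) of a Poisson point sample.
#' @param er_tubule_width_nm Rendered ER ridge width before blur (nm).
#' @param psf_sigma_px Gaussian point-spread sigma (px).
#' @param noise_sd Additive Gaussian noise SD (intensity units; object
#'   amplitude is `amplitude`, so SNR = amplitude / noise_sd).
#' @param background,amplitude Background level and object peak
#'   amplitude (intensities are kept in \[0, 1\] for float TIFF export).
#' @param contact_fraction Fraction of lysosomes seeded directly on an
#'   ER edge (their initial centroid lies on the ER ridge midline).
#' @param motion_models List of [motion_model()]s sampled per object.
#' @param motion_weights Sampling weights, same length as
#'   `motion_models`.
#' @param n_transition Number of round objects that switch to tubular at
#'   mid-acquisition (round/tubular shape interconversion).
#' @param min_separation_um Minimum initial centre-to-centre separation
#'   enforced between objects; placement failure raises an error.
#' @param seed RNG seed; the same config + seed is bit-reproducible.
#' @return A validated `scene_config` list.
#' @examples
#' cfg <- scene_config(n_round = 4, n_tubular = 2, n_frames = 3, seed = 1)
#' @export
scene_config <- function(image_size_px = c(256, 256), pixel_size_nm = 120,
                         frame_interval_s = 1, n_frames = 1,
                         n_round = 10, n_tubular = 5,
                         round_radius_um = 0.25,
                         tubule_length_um = 3.0, tubule_width_um = 0.5,
                         er_density = 0.15, er_tubule_width_nm = 50,
                         psf_sigma_px = 1, noise_sd = 0.02,
                         background = 0.1, amplitude = 0.6,
                         contact_fraction = 0.5,
                         motion_models = list(
                           motion_model("stationary"),
                           motion_model("diffusive"),
                           motion_model("directed")
                         ),
                         motion_weights = NULL,
                         n_transition = 0,
                         min_separation_um = 3,
                         seed = 1) {
  cfg <- list(
    image_size_px = as.integer(image_size_px), pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
    n_round = as.integer(n_round), n_tubular = as.integer(n_tubular),
    round_radius_um = round_radius_um, tubule_length_um = tubule_length_um,
    tubule_width_um = tubule_width_um, er_density = er_density,
    er_tubule_width_nm = er_tubule_width_nm, psf_sigma_px = psf_sigma_px,
    noise_sd = noise_sd, background = background, amplitude = amplitude,
    contact_fraction = contact_fraction, motion_models = motion_models,
    motion_weights = motion_weights %||% rep(1, length(motion_models)),
    n_transition = as.integer(n_transition),
    min_separation_um = min_separation_um, seed = seed
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    if (length(image_size_px) != 2 || any(image_size_px < 8))
      abort("`image_size_px` must be two integers >= 8.")
    pos <- c(pixel_size_nm, frame_interval_s, round_radius_um,
             tubule_length_um, tubule_width_um, er_tubule_width_nm,
             psf_sigma_px)
    if (any(pos <= 0)) abort("All lengths and scales must be positive.")
    if (n_frames < 1 || n_round < 0 || n_tubular < 0)
      abort("Counts must be non-negative (and n_frames >= 1).")
    if (contact_fraction < 0 || contact_fraction > 1)
      abort("`contact_fraction` must lie in [0, 1].")
    if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
    if (n_transition > n_round)
      abort("`n_transition` cannot exceed `n_round`.")
    if (length(cfg$motion_weights) != length(cfg$motion_models) ||
        any(cfg$motion_weights < 0) || sum(cfg$motion_weights) <= 0)
      abort("`motion_weights` must be non-negative and match `motion_models`.")
  })
  invisible(cfg)
}

#' Configuration for a synthetic axonal time-lapse
#'
#' Simulates lysosomes moving along an axon with programmed fractions of
#' anterograde (away from the soma), retrograde (towards the soma) and
#' stationary particles. The soma sits at axial coordinate 0 and the
#' axon runs to `axon_length_um`. Class counts follow the fractions by
#' largest-remainder apportionment, so programmed fractions are
#' recovered exactly from the ground truth. Defaults follow
#' neuronal imaging at two frames per second for 30 s.
#'
#' @param axon_length_um Axon length (um).
#' @param n_lysosomes Number of particles.
#' @param fractions Named or positional numeric vector
#'   `c(anterograde, retrograde, stationary)`, summing to 1.
#' @param speed_anterograde_um_s,speed_retrograde_um_s Run speeds.
#' @param jitter_um_sd Per-frame axial jitter SD of stationary objects.
#' @param frame_interval_s Frame interval (s), default 0.5.
#' @param n_frames Number of frames, default 60 (30 s).
#' @param pixel_size_nm Pixel pitch (nm).
#' @param psf_sigma_px,noise_sd,background,amplitude Rendering settings.
#' @param seed RNG seed.
#' @return A validated `axon_scene_config` list.
#' @export
axon_scene_config <- function(axon_length_um = 40, n_lysosomes = 12,
                              fractions = c(anterograde = 1 / 3,
                                            retrograde = 1 / 3,
                                            stationary = 1 / 3),
                              speed_anterograde_um_s = 0.8,
                              speed_retrograde_um_s = 0.8,
                              jitter_um_sd = 0.05,
                              frame_interval_s = 0.5, n_frames = 60,
                              pixel_size_nm = 120, psf_sigma_px = 1.2,
                              noise_sd = 0.02, background = 0.1,
                              amplitude = 0.6, seed = 1) {
  fr <- as.numeric(fractions)
  if (length(fr) != 3 || any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    abort("`fractions` must be three non-negative numbers summing to 1.")
  if (axon_length_um <= 0 || n_lysosomes < 1 || n_frames < 2)
    abort("Need a positive axon length, >= 1 lysosome and >= 2 frames.")
  if (speed_anterograde_um_s < 0 || speed_retrograde_um_s < 0 ||
      jitter_um_sd < 0 || frame_interval_s <= 0 || pixel_size_nm <= 0)
    abort("Speeds and jitter must be >= 0; intervals and pixel size > 0.")
  structure(list(
    axon_length_um = axon_length_um, n_lysosomes = as.integer(n_lysosomes),
    fractions = setNames(fr, c("anterograde", "retrograde", "stationary")),
    speed_anterograde_um_s = speed_anterograde_um_s,
    speed_retrograde_um_s = speed_retrograde_um_s,
    jitter_um_sd = jitter_um_sd, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), pixel_size_nm = pixel_size_nm,
    psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
    background = background, amplitude = amplitude, seed = seed
  ), class = "axon_scene_config")
}
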