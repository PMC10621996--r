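# lysotube

Quantitative image analysis of tubular lysosomes, ER–lysosome contacts,
and lysosome motility in fluorescence time-lapse microscopy.

Lysosomes are mostly round ~500 nm organelles, but a subpopulation
elongates into tubules several micrometres long. Tubular lysosomes form
at contact sites with the endoplasmic reticulum (ER), move in a
microtubule-dependent fashion, and their abundance is a sensitive
readout of lysosomal membrane dynamics — it collapses, for instance,
when spatacsin (SPG11) function is lost. `lysotube` is for cell
biologists who need to turn two-channel spinning-disk time-lapses (and
axonal single-channel time-lapses) into per-particle, per-cell and
per-condition numbers.

## What it computes

- **Morphometry** — LoG spot detection, 8-connected labelling,
  moment-based shape metrics (ellipse-of-inertia convention, Crofton
  perimeter), and the tubular-lysosome rule: circularity
  `4πA/P² < 0.5`, eccentricity `> 0.9`, major/minor axis ratio `> 4`.
  Densities are normalized to a *tubulation index*
  `clamp((d − d_KO)/(d_WT − d_KO), 0, 1)` between same-experiment
  control means.
- **Contacts** — per-lysosome area-overlap fraction with the ER mask
  (contact when > 30%), the 1D geometry calculator that justifies that
  threshold, a 90°-flip randomization control, an EM-style
  membrane-proximity metric (< 30 nm), and spot–mask colocalization.
- **Tracking** — Crocker–Grier-style linking minimizing
  `Σ‖Δx‖²` under a hard displacement bound (2.4 µm ≙ 20 px at 120 nm
  pixels), total path length, mean speed, motility flags
  (> 1.2 µm/min; > 0.3 µm/s), and instant speeds around round↔tubular
  transitions.
- **Axonal transport** — kymographs along an axon polyline and
  anterograde/retrograde/stationary classification with summary
  proportions and axial-distribution statistics.
- **Screen scoring** — dual-readout siRNA screen logic: mean
  knockout-phenotype probability from a pluggable classifier (a ridge
  logistic baseline on morphometry features ships with the package) and
  the tubulation index, gated against positive-control siRNAs.
- **Synthetic scenes** — a two-channel scene generator (discs, capsules,
  Gabriel-graph ER network, Gaussian PSF and noise, programmed motion
  mixtures and shape transitions) and an axon-scene generator, both with
  exact ground truth, so the whole pipeline is testable offline.

Everything is tidyverse-shaped: tabular results are tibbles, functions
compose with the pipe, result objects have `autoplot()`/`tidy()`/
`glance()` methods.

## Worked example

```r
library(lysotube)
library(dplyr)

# a synthetic field: 8 round + 4 tubular lysosomes, 5 frames, seeded
sc <- generate_scene(scene_config(n_round = 8, n_tubular = 4,
                                  n_frames = 5, seed = 7))

# detect, measure, classify frame 1
mask     <- binarize_spots(sc$lyso[, , 1], scale_px = 2)
verdicts <- classify_tubular(label_regions(mask, pixel_size_nm = 120))
count(verdicts, tubular)
#> # A tibble: 2 × 2
#>   tubular     n
#>   <lgl>   <int>
#> 1 FALSE       8
#> 2 TRUE        4

# track all particles across the 5 frames
det    <- detect_stack(sc$lyso, 120) |> transmute(frame, x = x_um, y = y_um)
tracks <- link_particles(det, max_disp = 2.4)
trajectory_metrics(tracks, frame_interval_s = 1) |> head(3)
#> # A tibble: 3 × 7
#>   track n_frames total_path_length_um duration_s mean_speed_um_per_s fast  motile
#>   <int>    <int>                <dbl>      <dbl>               <dbl> <lgl> <lgl>
#> 1     1        5                0.156          4              0.0389 FALSE FALSE
#> 2     2        5                2.02           4              0.505  TRUE  TRUE
#> 3     3        5                2.31           4              0.578  TRUE  TRUE

# ER contact scoring of the same frame
overlap_fraction(mask, sc$er_mask) |> summarise(contact = mean(in_contact))
#> contact: 0.417
```

The classification recovers the programmed 8/4 split; track 1 is a
stationary lysosome (0.04 µm/s) while tracks 2–3 are fast, motile ones
(> 0.3 µm/s, > 1.2 µm travelled); about 42% of lysosomes sit in ER
contact in this scene (half were seeded on the ER).

The 30% contact threshold is not arbitrary — it follows from imaging
geometry:

```r
apparent_overlap()
#> # A tibble: 1 × 4
#>   overlap_nm apparent_lysosome_diameter_nm apparent_er_width_nm percent_of_diameter
#> 1        230                           740                  290                31.1
```

A 500 nm lysosome 10 nm from a 50 nm ER tubule, imaged at 120 nm
pixels, shows a 230 nm apparent overlap on a 740 nm apparent diameter —
roughly 30% of the diameter.

See `vignette("tubular-lysosome-pipeline")` for the model conventions,
parameter meanings, and design decisions.

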