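#' Per-lysosome overlap with the ER mask
#'
#' For every 8-connected lysosome particle, computes the fraction of its
#' area that overlaps the ER mask, and calls a contact when that fraction
#' exceeds `threshold`. The default 30% threshold is the area-overlap
#' proxy for an ER-lysosome contact site at confocal resolution; its
#' geometric justification is computed by [apparent_overlap()].
#'
#' @param lyso_mask,er_mask Binary matrices of identical shape.
#' @param threshold Contact threshold on the overlap fraction.
#' @return Tibble with one row per lysosome particle: `label`,
#'   `area_px`, `overlap_fraction`, `in_contact`.
#' @examples
#' ly <- matrix(0, 12, 12); ly[3:6, 3:6] <- 1
#' er <- matrix(0, 12, 12); er[, 1:4] <- 1
#' overlap_fraction(ly, er)
#' @export
overlap_fraction <- function(lyso_mask, er_mask, threshold = 0.30) {
  check_same_shape(lyso_mask, er_mask)
  lab <- label_mask(lyso_mask)
  n <- max(lab)
  if (n == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  overlap_fraction = double(), in_contact = logical()))
  }
  fg <- lab > 0L
  area <- tabulate(lab[fg], n)
  inter <- tabulate(lab[fg & er_mask > 0], n)
  tibble(
    label = seq_len(n),
    area_px = area,
    overlap_fraction = inter / area,
    in_contact = inter / area > threshold
  )
}

#' Apparent 1D overlap of a lysosome and an ER tubule
#'
#' Derives the expected apparent overlap between a lysosome and a nearby
#' ER tubule from imaging geometry alone. Rasterization spreads each
#' object's edge outward by one pixel on each side, so the apparent
#' lysosome diameter is the true diameter plus two pixels, and the two
#' apparent edges overlap by two pixels minus the true edge-to-edge gap
#' (floored at zero). With the standard spinning-disk geometry (500 nm
#' lysosome, 10 nm gap, 50 nm ER tubule, 120 nm pixels) this gives a
#' 230 nm overlap on a 740 nm apparent diameter, about 30% of the
#' diameter - the rationale for the 30% area-overlap contact threshold.
#'
#' @param lysosome_diameter_nm True lysosome diameter (nm).
#' @param edge_gap_nm True edge-to-edge distance between the two
#'   membranes (nm).
#' @param er_tubule_width_nm True ER tubule width (nm).
#' @param pixel_size_nm Pixel pitch (nm).
#' @return One-row tibble: `overlap_nm`,
#'   `apparent_lysosome_diameter_nm`, `apparent_er_width_nm`,
#'   `percent_of_diameter`.
#' @examples
#' apparent_overlap()
#' @export
apparent_overlap <- function(lysosome_diameter_nm = 500, edge_gap_nm = 10,
                             er_tubule_width_nm = 50, pixel_size_nm = 120) {
  vals <- c(lysosome_diameter_nm, edge_gap_nm, er_tubule_width_nm, pixel_size_nm)
  if (any(!is.finite(vals)) || any(vals < 0))
    abort("All geometry inputs must be non-negative.")
  apparent_d <- lysosome_diameter_nm + 2 * pixel_size_nm
  overlap <- max(0, 2 * pixel_size_nm - edge_gap_nm)
  tibble(
    overlap_nm = overlap,
    apparent_lysosome_diameter_nm = apparent_d,
    apparent_er_width_nm = er_tubule_width_nm + 2 * pixel_size_nm,
    percent_of_diameter = 100 * overlap / apparent_d
  )
}

#' Spatial-randomization control by 90-degree rotation
#'
#' Rotates the lysosome mask by 90 degrees about the image centre (after
#' padding non-square images to a square, cropping back afterwards) and
#' re-scores the overlap with the unrotated ER mask. Because the
#' rotation preserves the lysosome mask's internal geometry but destroys
#' its spatial registration with the ER, the flipped overlap is a null
#' estimate of coincidental overlap.
#'
#' @inheritParams overlap_fraction
#' @return Tibble as in [overlap_fraction()], computed on the rotated
#'   lysosome mask.
#' @export
flip_control <- function(lyso_mask, er_mask, threshold = 0.30) {
  check_same_shape(lyso_mask, er_mask)
  overlap_fraction(rotate90_center(lyso_mask), er_mask, threshold)
}

# Rotate a matrix 90 degrees about its centre; non-square inputs are
# zero-padded to a centred square, rotated, then cropped back.
rotate90_center <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  s <- max(ny, nx)
  p <- matrix(0, s, s)
  oy <- floor((s - ny) / 2); ox <- floor((s - nx) / 2)
  p[(oy + 1):(oy + ny), (ox + 1):(ox + nx)] <- m
  r <- t(p)[, s:1, drop = FALSE]  # 90 deg counter-clockwise
  r[(oy + 1):(oy + ny), (ox + 1):(ox + nx), drop = FALSE]
}

#' Membrane proximity between lysosomes and the ER
#'
#' Scores each lysosome particle by the distance from its boundary
#' pixels to the nearest ER boundary pixel, the mask-based analogue of
#' the electron-microscopy criterion that a contact site is membrane
#' apposition closer than ~30 nm. Distances are Euclidean, computed by a
#' distance transform of the ER boundary.
#'
#' @inheritParams overlap_fraction
#' @param pixel_size_nm Pixel pitch in nm. A warning is issued when the
#'   cutoff is below one pixel (the masks cannot resolve it).
#' @param cutoff_nm Proximity cutoff in nm (default 30).
#' @return Tibble with one row per lysosome: `label`, `is_near` (any
#'   boundary point within the cutoff), `fraction_of_boundary_near`,
#'   `min_distance_nm`.
#' @export
membrane_proximity <- function(lyso_mask, er_mask, pixel_size_nm,
                               cutoff_nm = 30) {
  check_same_shape(lyso_mask, er_mask)
  stopifnot(pixel_size_nm > 0, cutoff_nm >= 0)
  if (cutoff_nm < pixel_size_nm)
    warn(sprintf(
      "Proximity cutoff (%g nm) is below one pixel (%g nm); masks cannot resolve it.",
      cutoff_nm, pixel_size_nm))
  lab <- label_mask(lyso_mask)
  n <- max(lab)
  empty <- tibble(label = integer(), is_near = logical(),
                  fraction_of_boundary_near = double(),
                  min_distance_nm = double())
  if (n == 0L) return(empty)
  erb <- mask_boundary(er_mask > 0)
  if (!any(erb)) {
    return(tibble(label = seq_len(n), is_near = FALSE,
                  fraction_of_boundary_near = 0, min_distance_nm = Inf))
  }
  # distance of every pixel to the nearest ER boundary pixel
  dist_px <- as.matrix(EBImage::distmap(1 - erb))
  lyb <- mask_boundary(lyso_mask > 0)
  purrr::map(seq_len(n), function(k) {
    d <- dist_px[lyb & lab == k] * pixel_size_nm
    tibble(label = k,
           is_near = any(d <= cutoff_nm),
           fraction_of_boundary_near = mean(d <= cutoff_nm),
           min_distance_nm = min(d))
  }) |> list_rbind()
}

# Boundary pixels: foreground with at least one 4-neighbour outside the
# mask (image borders count as outside).
mask_boundary <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  p <- matrix(FALSE, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- mask
  core <- p[2:(ny + 1), 2:(nx + 1)] &
    p[1:ny, 2:(nx + 1)] & p[3:(ny + 2), 2:(nx + 1)] &
    p[2:(ny + 1), 1:nx] & p[2:(ny + 1), 3:(nx + 2)]
  mask & !core
}

#' Classify spots by membership in two masks
#'
#' Assigns each spot (e.g. a proximity-ligation or immunostaining dot)
#' to one of four colocalization classes by whether its footprint hits
#' mask A (e.g. ER), mask B (e.g. lysosomes), both, or neither.
#'
#' @param spots Tibble with `x_px`, `y_px` spot centroids (0-based pixel
#'   coordinates).
#' @param mask_a,mask_b Binary matrices of identical shape.
#' @param dilate_radius_px Footprint radius in pixels; 0 tests only the
#'   pixel under the centroid.
#' @return The `spots` tibble with a `class` factor appended (levels
#'   `mask_a_only`, `mask_b_only`, `both`, `neither`).
#' @seealso [coloc_proportions()]
#' @export
spot_colocalization <- function(spots, mask_a, mask_b, dilate_radius_px = 0) {
  check_same_shape(mask_a, mask_b)
  spots <- as_tibble(spots)
  if (nrow(spots) == 0L) {
    warn("No spots supplied; returning an empty classification.")
    return(mutate(spots, class = factor(character(), levels = coloc_levels)))
  }
  i <- round(spots$y_px) + 1
  j <- round(spots$x_px) + 1
  if (any(i < 1 | i > nrow(mask_a) | j < 1 | j > ncol(mask_a)))
    abort("Spot centroids must lie within the image bounds.")
  hit <- function(mask) {
    map_lgl(seq_len(nrow(spots)), function(k) {
      if (dilate_radius_px <= 0) return(mask[i[k], j[k]] > 0)
      r <- ceiling(dilate_radius_px)
      ii <- max(1, i[k] - r):min(nrow(mask), i[k] + r)
      jj <- max(1, j[k] - r):min(ncol(mask), j[k] + r)
      win <- outer((ii - i[k])^2, (jj - j[k])^2, "+") <= dilate_radius_px^2
      any(mask[ii, jj][win] > 0)
    })
  }
  a <- hit(mask_a); b <- hit(mask_b)
  cls <- ifelse(a & b, "both",
                ifelse(a, "mask_a_only", ifelse(b, "mask_b_only", "neither")))
  mutate(spots, class = factor(cls, levels = coloc_levels))
}

coloc_levels <- c("mask_a_only", "mask_b_only", "both", "neither")

#' Colocalization class proportions
#'
#' @param classified Output of [spot_colocalization()].
#' @return Tibble with `class`, `n`, `proportion` over all spots.
#' @export
coloc_proportions <- function(classified) {
  n_total <- nrow(classified)
  if (n_total == 0L) warn("No spots; proportions are undefined (NaN).")
  tab <- table(factor(classified$class, levels = coloc_levels))
  tibble(class = factor(coloc_levels, levels = coloc_levels),
         n = as.integer(tab),
         proportion = as.integer(tab) / n_total)
}

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b)))
    abort("Masks must be matrices of identical shape.")
  invisible(NULL)
}
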