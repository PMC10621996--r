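#' Classify particles as tubular or round
#'
#' A particle counts as a tubular lysosome when all three shape criteria
#' hold: circularity below `circularity_max`, eccentricity above
#' `eccentricity_min`, and fitted-ellipse major/minor axis ratio above
#' `axis_ratio_min`. The defaults (0.5, 0.9, 4) are the standard cutoffs
#' for elongated lysosomes imaged at ~120 nm pixels. The elongation
#' criterion is applied to the major/minor axis ratio: for an elongated
#' object a literal width/length quotient is below 1 and could never
#' exceed 4, so the axis ratio is the only reading consistent with
#' selecting tubules.
#'
#' A degenerate particle with zero minor axis (a perfect line) gets an
#' infinite axis ratio and is still classified.
#'
#' @param records A tibble of region properties from [label_regions()]
#'   (needs `circularity`, `eccentricity`, `major_axis_um`,
#'   `minor_axis_um`).
#' @param circularity_max,eccentricity_min,axis_ratio_min Shape cutoffs.
#' @return The input tibble with `axis_ratio` and logical `tubular`
#'   columns appended.
#' @examples
#' m <- matrix(0, 40, 40); m[10:13, 5:35] <- 1
#' classify_tubular(label_regions(m, 120))$tubular
#' @export
classify_tubular <- function(records, circularity_max = 0.5,
                             eccentricity_min = 0.9, axis_ratio_min = 4) {
  need <- c("circularity", "eccentricity", "major_axis_um", "minor_axis_um")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("`records` lacks columns: ",
                                 paste(miss, collapse = ", ")))
  records |>
    as_tibble() |>
    mutate(
      axis_ratio = ifelse(.data$minor_axis_um > 0,
                          .data$major_axis_um / .data$minor_axis_um, Inf),
      tubular = .data$circularity < circularity_max &
        .data$eccentricity > eccentricity_min &
        .data$axis_ratio > axis_ratio_min
    )
}

#' Tubular lysosome density per unit cell area
#'
#' @param verdicts Tibble with a logical `tubular` column (from
#'   [classify_tubular()]).
#' @param cell_area_um2 Cell (or field) area in square micrometres.
#' @return Tubular count per square micrometre.
#' @export
tubule_density <- function(verdicts, cell_area_um2) {
  if (!is.numeric(cell_area_um2) || cell_area_um2 <= 0)
    abort("`cell_area_um2` must be a positive area.")
  sum(verdicts$tubular) / cell_area_um2
}

#' Normalized tubulation index
#'
#' Rescales a tubular-lysosome density linearly between the mean density
#' of knockout controls (index 0) and wild-type controls (index 1)
#' measured in the same experiment, clamped to \[0, 1\]. The index is
#' invariant to rescaling all densities by a common positive factor.
#'
#' @param density Tubule density (or densities) to normalize, per um^2.
#' @param wt_mean,ko_mean Mean control densities; `wt_mean` must exceed
#'   `ko_mean`.
#' @return Numeric vector of indices in \[0, 1\].
#' @examples
#' tubulation_index(c(0.02, 0.05, 0.08), wt_mean = 0.08, ko_mean = 0.02)
#' @export
tubulation_index <- function(density, wt_mean, ko_mean) {
  if (!is.finite(wt_mean) || !is.finite(ko_mean) || wt_mean == ko_mean)
    abort("Undefined normalization: `wt_mean` must differ from `ko_mean`.")
  if (wt_mean < ko_mean)
    abort("`wt_mean` must exceed `ko_mean` (index 1 = wild-type-like).")
  pmin(pmax((density - ko_mean) / (wt_mean - ko_mean), 0), 1)
}

#' Per-experiment means of per-cell values
#'
#' Summarizes per-cell measurements into one mean per independent
#' experiment, the superplot convention: downstream statistics consume
#' the per-experiment means, never the pooled per-cell values, so cells
#' from the same culture are not treated as independent replicates.
#'
#' @param data Tibble of per-cell values.
#' @param value Name of the value column (string).
#' @param experiment Name of the experiment-id column (string).
#' @return Tibble with one row per experiment: `experiment`, `n_cells`,
#'   `mean`. Experiments with no finite values are dropped with a
#'   warning.
#' @export
experiment_summary <- function(data, value = "value", experiment = "experiment") {
  stopifnot(value %in% names(data), experiment %in% names(data))
  out <- data |>
    as_tibble() |>
    group_by(experiment = .data[[experiment]]) |>
    summarise(
      n_cells = sum(is.finite(.data[[value]])),
      mean = mean(.data[[value]][is.finite(.data[[value]])]),
      .groups = "drop"
    )
  if (nrow(out) == 0L) abort("At least one experiment is required.")
  if (any(out$n_cells == 0L)) {
    warn(paste0("Dropping empty experiment(s): ",
                paste(out$experiment[out$n_cells == 0L], collapse = ", ")))
    out <- filter(out, .data$n_cells > 0L)
  }
  out
}
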