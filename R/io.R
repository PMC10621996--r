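#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Writes one 32-bit float multi-page TIFF per call plus a sidecar
#' `<stem>.json` holding the acquisition metadata (pixel size, frame
#' interval, channel name, seed). The sidecar is the authoritative
#' metadata source on re-reading; relying on TIFF resolution tags is a
#' fallback only, since tag dialects vary between writers.
#'
#' Intensities must lie in \[0, 1\] (the simulator's convention); values
#' outside are clipped by the TIFF writer.
#'
#' @param stack `ny x nx x n_frames` numeric array (or a matrix).
#' @param path Output TIFF path.
#' @param pixel_size_nm,frame_interval_s Calibration metadata.
#' @param channel Channel name stored in the sidecar.
#' @param seed Optional generator seed recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size_nm, frame_interval_s,
                        channel = "unknown", seed = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3, pixel_size_nm > 0, frame_interval_s > 0)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_nm = pixel_size_nm,
               frame_interval_s = frame_interval_s,
               channel = channel, n_frames = dim(stack)[3],
               axes = "TYX")
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack and its metadata
#'
#' Reads a (multi-page) TIFF into a `ny x nx x n_frames` array with the
#' time axis last; a single-page file yields a length-1 time axis.
#' Metadata comes from the JSON sidecar when present, then from TIFF
#' resolution tags, then from the supplied defaults; whichever source is
#' used is reported. A missing pixel size with no default is an error.
#'
#' @param path TIFF path.
#' @param default_pixel_size_nm,default_frame_interval_s Fallback
#'   calibration used (with a message) when neither sidecar nor tags
#'   provide it.
#' @return List with `data` (array) and `meta` (list: `pixel_size_nm`,
#'   `frame_interval_s`, `channel`, `n_frames`, `axes`, `source`).
#' @export
read_stack <- function(path, default_pixel_size_nm = NULL,
                       default_frame_interval_s = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # collapse grey-stored-as-RGB
    arr[, , f] <- pg
  }
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta$source <- "sidecar"
  } else {
    meta <- list(source = "tags")
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && xres > 0) {
      nm_per_unit <- switch(as.character(unit %||% "inch"),
                            inch = 2.54e7, cm = 1e7, 1e7)
      meta$pixel_size_nm <- nm_per_unit / xres
    }
  }
  if (is.null(meta$pixel_size_nm)) {
    if (is.null(default_pixel_size_nm))
      abort("Metadata field `pixel_size_nm` is missing and no default was supplied.")
    inform(sprintf("Using default pixel_size_nm = %g for %s.",
                   default_pixel_size_nm, basename(path)))
    meta$pixel_size_nm <- default_pixel_size_nm
    meta$source <- paste0(meta$source, "+defaults")
  }
  if (is.null(meta$frame_interval_s)) {
    if (is.null(default_frame_interval_s))
      abort("Metadata field `frame_interval_s` is missing and no default was supplied.")
    inform(sprintf("Using default frame_interval_s = %g for %s.",
                   default_frame_interval_s, basename(path)))
    meta$frame_interval_s <- default_frame_interval_s
    meta$source <- paste0(meta$source, "+defaults")
  }
  meta$n_frames <- dim(arr)[3]
  meta$axes <- "TYX"
  list(data = arr, meta = meta)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a records table to CSV
#'
#' Columns are written in their current order; floats keep full
#' round-trip precision. An empty tibble produces a header-only file.
#'
#' @param records A data frame / tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Read a records table written by [write_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a full synthetic scene to disk
#'
#' Persists both channels as float TIFF + sidecars, the ER ground-truth
#' mask, and the truth table as CSV, using the scene's own calibration.
#'
#' @param scene A `lyso_scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "lyso_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scene$config
  write_stack(scene$lyso, file.path(dir, "lysosomes.tif"),
              cfg$pixel_size_nm, cfg$frame_interval_s, "lysosome", cfg$seed)
  write_stack(scene$er, file.path(dir, "er.tif"),
              cfg$pixel_size_nm, cfg$frame_interval_s, "er", cfg$seed)
  write_stack(scene$er_mask * 1, file.path(dir, "er_mask.tif"),
              cfg$pixel_size_nm, cfg$frame_interval_s, "er_mask", cfg$seed)
  write_table(scene$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Load a screen condition manifest
#'
#' Reads a JSON manifest describing the image sets of an siRNA screen:
#' an array of objects with `condition_id`, `experiment`, `role`
#' (`candidate`, `positive_control` or `negative_control`) and an
#' `images` array of file paths. Every path must exist and every
#' condition must list at least one image.
#'
#' @param path Manifest JSON path.
#' @param check_paths Verify that image files exist (default TRUE).
#' @return Tibble with one row per image: `condition_id`, `experiment`,
#'   `role`, `image`.
#' @export
read_condition_manifest <- function(path, check_paths = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- map(raw, function(e) {
    if (is.null(e$condition_id) || length(e$images %||% list()) == 0)
      abort("Every manifest entry needs `condition_id` and >= 1 image.")
    tibble(condition_id = e$condition_id,
           experiment = e$experiment %||% NA_character_,
           role = match.arg(e$role %||% "candidate",
                            c("candidate", "positive_control",
                              "negative_control")),
           image = unlist(e$images))
  }) |> list_rbind()
  if (check_paths && !all(file.exists(rows$image)))
    abort(paste0("Missing image file(s): ",
                 paste(head(rows$image[!file.exists(rows$image)], 3),
                       collapse = ", ")))
  rows
}
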