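#' Maximum linking displacement in pixels
#'
#' Converts the physical size of one particle (the natural upper bound
#' on its frame-to-frame displacement) into pixels. With the standard
#' 2.4 um tubular-lysosome size at 120 nm pixels this gives 20 px.
#'
#' @param particle_size_um Particle size in micrometres.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @return Integer number of pixels (rounded).
#' @examples
#' max_displacement_px(2.4, 120)
#' @export
max_displacement_px <- function(particle_size_um, pixel_size_nm) {
  stopifnot(particle_size_um > 0, pixel_size_nm > 0)
  as.integer(round(particle_size_um * 1000 / pixel_size_nm))
}

#' Link particle detections into trajectories
#'
#' Frame-to-frame linking in the Crocker-Grier style: between
#' consecutive frames, the assignment of old track heads to new
#' detections minimizes the total squared displacement, among
#' assignments in which every link is shorter than `max_disp`; leaving a
#' particle unlinked costs `max_disp^2`. The candidate bipartite graph is
#' split into independent subnetworks, each solved exactly by a pruned
#' exhaustive search. Ties are broken towards links between
#' lowest-indexed particles, so linking is deterministic. Unmatched
#' detections start new tracks; with `memory = 0` (the default) a track
#' whose particle disappears for one frame is terminated rather than
#' gap-closed.
#'
#' @param detections Tibble with `frame`, `x`, `y` columns (any length
#'   unit, as long as `max_disp` matches); extra columns (e.g.
#'   `shape_class`) are carried through.
#' @param max_disp Maximum frame-to-frame displacement, same unit as
#'   `x`/`y`.
#' @param memory Number of frames a disappeared particle may be bridged
#'   over (0 = none).
#' @param cap Maximum number of particles in one assignment subnetwork;
#'   denser frames raise an error advising down-sampling.
#' @return A `lyso_tracks` tibble: `track`, `frame`, `x`, `y`, plus
#'   carried columns, sorted by track then frame.
#' @examples
#' det <- tibble::tibble(frame = rep(1:3, each = 1), x = c(0, 0.1, 0.2), y = 0)
#' link_particles(det, max_disp = 0.5)
#' @export
link_particles <- function(detections, max_disp, memory = 0, cap = 12) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)), max_disp > 0)
  det <- as_tibble(detections) |> arrange(.data$frame)
  frames <- sort(unique(det$frame))
  if (length(frames) < 2) abort("Linking needs at least two frames.")
  det$.row <- seq_len(nrow(det))
  det$track <- NA_integer_
  # open tracks: list of (track id, last frame, x, y)
  first <- det[det$frame == frames[1], ]
  det$track[first$.row] <- seq_len(nrow(first))
  open <- tibble(track = det$track[first$.row], frame = first$frame,
                 x = first$x, y = first$y)
  next_id <- nrow(first) + 1L
  for (f in frames[-1]) {
    cur <- det[det$frame == f, ]
    alive <- open$frame >= f - 1 - memory
    heads <- open[alive, ]
    asg <- assign_frame(heads$x, heads$y, cur$x, cur$y, max_disp, cap)
    for (k in seq_along(asg)) {
      if (!is.na(asg[k])) det$track[cur$.row[asg[k]]] <- heads$track[k]
    }
    new <- which(is.na(det$track[cur$.row]))
    if (length(new)) {
      det$track[cur$.row[new]] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    linked_tracks <- det$track[cur$.row]
    open <- open[!(open$track %in% linked_tracks), ]
    open <- bind_rows(open, tibble(track = linked_tracks, frame = f,
                                   x = cur$x, y = cur$y))
    open <- open[open$frame >= f - memory, ]
  }
  out <- det |>
    select(-".row") |>
    dplyr::relocate("track") |>
    arrange(.data$track, .data$frame)
  structure(out, class = c("lyso_tracks", class(out)),
            max_disp = max_disp, memory = memory)
}

# Optimal assignment of m track heads to n detections under max_disp.
# Returns an integer vector of length m (detection index or NA).
assign_frame <- function(hx, hy, dx, dy, max_disp, cap) {
  m <- length(hx); n <- length(dx)
  if (m == 0L || n == 0L) return(rep(NA_integer_, m))
  cost <- outer(hx, dx, "-")^2 + outer(hy, dy, "-")^2
  allowed <- cost <= max_disp^2
  res <- rep(NA_integer_, m)
  # independent subnetworks = connected components of the candidate graph
  g <- igraph::graph_from_edgelist(
    cbind(row(allowed)[allowed], m + col(allowed)[allowed]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m + n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  for (cc in unique(comp[seq_len(m)])) {
    hs <- which(comp[seq_len(m)] == cc)
    ds <- which(comp[m + seq_len(n)] == cc)
    if (length(ds) == 0L) next
    if (length(hs) + length(ds) > cap)
      abort(paste0(
        "Assignment subnetwork with ", length(hs) + length(ds),
        " particles exceeds the cap (", cap, "); the scene is too dense - ",
        "down-sample or raise `cap`."))
    sub <- solve_subnetwork(cost[hs, ds, drop = FALSE],
                            allowed[hs, ds, drop = FALSE], max_disp^2)
    res[hs] <- ds[sub]
  }
  res
}

# Exact minimum-cost assignment by depth-first search with pruning.
# Unassigned rows or columns cost `penalty` each. Rows are expanded in
# index order and candidate columns tried in index order with strict
# improvement, so the first-found optimum is the lexicographically
# smallest: ties break towards lowest combined indices.
solve_subnetwork <- function(cost, allowed, penalty) {
  m <- nrow(cost); n <- ncol(cost)
  best <- list(cost = Inf, asg = rep(NA_integer_, m))
  asg <- rep(NA_integer_, m)
  used <- rep(FALSE, n)
  recurse <- function(i, acc) {
    if (acc >= best$cost) return()
    if (i > m) {
      total <- acc + penalty * sum(!used)
      if (total < best$cost) best <<- list(cost = total, asg = asg)
      return()
    }
    for (j in seq_len(n)) {
      if (allowed[i, j] && !used[j]) {
        asg[i] <<- j; used[j] <<- TRUE
        recurse(i + 1, acc + cost[i, j])
        asg[i] <<- NA_integer_; used[j] <<- FALSE
      }
    }
    recurse(i + 1, acc + penalty)  # leave row i unassigned
  }
  recurse(1L, 0)
  best$asg
}

#' Per-trajectory motility statistics
#'
#' Computes, per track, the total travelled path length (sum of
#' inter-frame displacements - not the net displacement), the duration,
#' and the mean speed, plus two standard motility flags: `fast` for mean
#' speed above `fast_min_um_s` (microtubule-dependent transport is
#' faster than ~0.3 um/s) and `motile` for a total path length above
#' `motile_min_um` (1.2 um over a one-minute acquisition by default).
#'
#' @param tracks A `lyso_tracks` tibble (or any tibble with `track`,
#'   `frame`, `x`, `y` in micrometres).
#' @param frame_interval_s Time between frames in seconds.
#' @param fast_min_um_s Mean-speed threshold for the `fast` flag.
#' @param motile_min_um Path-length threshold for the `motile` flag.
#' @return Tibble with one row per track: `track`, `n_frames`,
#'   `total_path_length_um`, `duration_s`, `mean_speed_um_per_s`,
#'   `fast`, `motile`. Single-point tracks are dropped with a warning.
#' @export
trajectory_metrics <- function(tracks, frame_interval_s,
                               fast_min_um_s = 0.3, motile_min_um = 1.2) {
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    abort("`frame_interval_s` must be positive (zero duration is undefined).")
  lens <- table(tracks$track)
  if (any(lens < 2)) {
    warn(sprintf("Dropping %d single-point track(s).", sum(lens < 2)))
    tracks <- tracks[tracks$track %in% names(lens)[lens >= 2], ]
  }
  if (nrow(tracks) == 0L) abort("No track has two or more points.")
  tracks |>
    as_tibble() |>
    arrange(.data$track, .data$frame) |>
    group_by(.data$track) |>
    summarise(
      n_frames = n(),
      total_path_length_um = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      duration_s = (max(.data$frame) - min(.data$frame)) * frame_interval_s,
      .groups = "drop"
    ) |>
    mutate(
      mean_speed_um_per_s = .data$total_path_length_um / .data$duration_s,
      fast = .data$mean_speed_um_per_s > fast_min_um_s,
      motile = .data$total_path_length_um > motile_min_um
    )
}

#' Instant speeds around shape transitions
#'
#' Finds the frames where a tracked particle changes shape class (round
#' to tubular or back) and measures its instant speed averaged over a
#' window of frames on each side of the change, to ask whether the
#' morphological transition coincides with a change in motility.
#'
#' @param tracks Tibble with `track`, `frame`, `x`, `y`, `shape_class`
#'   (positions in micrometres).
#' @param frame_interval_s Time between frames in seconds.
#' @param window_frames Number of inter-frame steps averaged on each
#'   side of the transition (default 3).
#' @return Tibble with one row per transition: `track`, `frame` (first
#'   frame of the new class), `direction`, `speed_before_um_per_s`,
#'   `speed_after_um_per_s`. Transitions closer than the window to a
#'   track end are dropped with a warning.
#' @export
transition_speeds <- function(tracks, frame_interval_s, window_frames = 3) {
  stopifnot(all(c("track", "frame", "x", "y", "shape_class") %in% names(tracks)),
            frame_interval_s > 0, window_frames >= 1)
  dropped <- 0L
  out <- tracks |>
    as_tibble() |>
    arrange(.data$track, .data$frame) |>
    group_by(.data$track) |>
    dplyr::group_map(function(tr, key) {
      cls <- as.character(tr$shape_class)
      ch <- which(cls[-1] != cls[-length(cls)])  # step index of change
      if (!length(ch)) return(NULL)
      step_sp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / frame_interval_s
      evs <- map(ch, function(i) {
        # step i crosses the class change; average only steps fully
        # inside the old (before) or new (after) class
        if (i - window_frames < 1 || i + window_frames > length(step_sp)) {
          dropped <<- dropped + 1L
          return(NULL)
        }
        tibble(
          track = key$track,
          frame = tr$frame[i + 1],
          direction = paste0(cls[i], "->", cls[i + 1]),
          speed_before_um_per_s = mean(step_sp[(i - window_frames):(i - 1)]),
          speed_after_um_per_s = mean(step_sp[(i + 1):(i + window_frames)])
        )
      })
      list_rbind(purrr::compact(evs))
    }) |>
    purrr::compact() |>
    list_rbind()
  if (dropped > 0L)
    warn(sprintf("Dropped %d transition(s) closer than %d frames to a track end.",
                 dropped, window_frames))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(track = integer(), frame = integer(), direction = character(),
                  speed_before_um_per_s = double(),
                  speed_after_um_per_s = double()))
  }
  out
}
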