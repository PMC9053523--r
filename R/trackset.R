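#' Trajectory collections
#'
#' A `track_set` is the package's universal trajectory container: a
#' data.frame of localizations (`track_id`, `frame`, `x_um`, `y_um`) plus the
#' frame interval `tau` in seconds. Frames are 0-based integers; coordinates
#' are micrometres. Within a track, frames must be strictly increasing and
#' every track must contain at least two positions (one displacement).
#'
#' @param positions data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um`; rows are sorted by (track_id, frame) on construction
#' @param tau frame interval in seconds, > 0
#' @param metadata optional named list carried along (seeds, ground truth, ...)
#' @return an object of class `track_set`
#' @export
track_set <- function(positions, tau, metadata = list()) {
  required <- c("track_id", "frame", "x_um", "y_um")
  if (!is.data.frame(positions) || !all(required %in% names(positions)))
    stop("positions must be a data.frame with columns ",
         paste(required, collapse = ", "))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number (seconds)")
  if (!is.numeric(positions$frame) || !is.numeric(positions$x_um) ||
      !is.numeric(positions$y_um))
    stop("frame, x_um and y_um must be numeric")
  positions <- positions[order(positions$track_id, positions$frame),
                         required, drop = FALSE]
  rownames(positions) <- NULL
  dup <- duplicated(positions[c("track_id", "frame")])
  if (any(dup)) {
    bad <- unique(positions$track_id[dup])
    stop("duplicate (track_id, frame) pairs in track(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n_per <- table(positions$track_id)
  if (any(n_per < 2L)) {
    drop_ids <- names(n_per)[n_per < 2L]
    warning(length(drop_ids), " track(s) with < 2 positions dropped")
    positions <- positions[!(positions$track_id %in% drop_ids), , drop = FALSE]
  }
  if (nrow(positions) == 0L) stop("track_set has no usable tracks")
  structure(list(positions = positions, tau = tau, metadata = metadata),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$positions$track_id)
  cat("<track_set> ", length(ids), " tracks, ",
      nrow(x$positions), " localizations, tau = ", x$tau, " s\n", sep = "")
  invisible(x)
}

#' @export
length.track_set <- function(x) length(unique(x$positions$track_id))

n_steps_total <- function(tracks) {
  nrow(tracks$positions) - length(tracks)
}

#' Single-step displacements of every track
#'
#' Differences of consecutive-frame positions. A gap in the frame numbering
#' splits a track into independent runs: no displacement is computed across
#' missing frames. Runs with fewer than two positions are skipped.
#'
#' @param tracks a [track_set]
#' @return list of numeric matrices (one per contiguous run, columns dx/dy,
#'   micrometres) with attributes `track_id` per element
#' @export
displacements_from_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  pos <- tracks$positions
  out <- list()
  for (id in unique(pos$track_id)) {
    p <- pos[pos$track_id == id, , drop = FALSE]
    # split at frame gaps: consecutive frames only
    brk <- cumsum(c(0L, diff(p$frame) != 1L))
    for (g in unique(brk)) {
      q <- p[brk == g, , drop = FALSE]
      if (nrow(q) < 2L) next
      d <- cbind(dx = diff(q$x_um), dy = diff(q$y_um))
      attr(d, "track_id") <- id
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

#' Rigid rotation of trajectories
#'
#' Rotates every track about its own centroid by `angle` radians
#' (counter-clockwise). Step lengths are preserved exactly; used to align
#' cell long axes with the x axis before anisotropy analysis.
#'
#' @param tracks a [track_set]
#' @param angle rotation angle in radians; either a scalar applied to all
#'   tracks or a named vector with one angle per track id
#' @return rotated [track_set]
#' @export
rotate_tracks <- function(tracks, angle) {
  stopifnot(inherits(tracks, "track_set"), all(is.finite(angle)))
  pos <- tracks$positions
  ids <- unique(pos$track_id)
  if (length(angle) == 1L) {
    ang <- stats::setNames(rep(angle, length(ids)), ids)
  } else {
    if (is.null(names(angle)) || !all(as.character(ids) %in% names(angle)))
      stop("per-track angles must be named by track id")
    ang <- angle
  }
  for (id in ids) {
    i <- pos$track_id == id
    a <- ang[[as.character(id)]]
    cx <- mean(pos$x_um[i]); cy <- mean(pos$y_um[i])
    x <- pos$x_um[i] - cx; y <- pos$y_um[i] - cy
    pos$x_um[i] <- cx + cos(a) * x - sin(a) * y
    pos$y_um[i] <- cy + sin(a) * x + cos(a) * y
  }
  track_set(pos, tracks$tau, tracks$metadata)
}
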