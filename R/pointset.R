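#' Fiducial point sets
#'
#' A `point_set` holds the reference (undeformed) positions of tracked
#' fiducial points in image pixel coordinates, together with the
#' physical pixel scale. A `deformed_point_set` holds the positions of
#' the same points in a deformed frame. Coordinates follow the image
#' convention: origin at the top-left pixel centre, `x` rightward
#' (cranio-caudal extension axis by default), `y` downward, 0-based.
#'
#' @param ids integer point labels, unique.
#' @param xy numeric matrix (n x 2) of positions in pixels, finite and
#'   non-negative for reference positions.
#' @param scale mm-per-pixel conversion factor. The default 0.03 mm/px
#'   corresponds to a 30 mm field of view imaged at 1000 px.
#' @return An object of class `point_set` (or `deformed_point_set`):
#'   a list with elements `ids`, `xy` and (reference only) `scale`.
#' @examples
#' ref <- point_set(1:4, cbind(c(0, 100, 0, 100), c(0, 0, 100, 100)))
#' def <- deformed_point_set(1:4, ref$xy * 1.1)
#' @export
point_set <- function(ids, xy, scale = 0.03) {
  xy <- as_xy_matrix(xy)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("point ids must be unique")
  if (length(ids) != nrow(xy)) stop("ids and xy disagree in length")
  if (!all(is.finite(xy)) || any(xy < 0)) {
    stop("reference coordinates must be finite and >= 0")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale must be a single positive number (mm/px)")
  }
  structure(list(ids = ids, xy = xy, scale = scale), class = "point_set")
}

#' @rdname point_set
#' @export
deformed_point_set <- function(ids, xy) {
  xy <- as_xy_matrix(xy)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("point ids must be unique")
  if (length(ids) != nrow(xy)) stop("ids and xy disagree in length")
  if (!all(is.finite(xy))) stop("deformed coordinates must be finite")
  structure(list(ids = ids, xy = xy), class = "deformed_point_set")
}

as_xy_matrix <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("xy must have two columns (x, y)")
  storage.mode(xy) <- "double"
  dimnames(xy) <- list(NULL, c("x", "y"))
  xy
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, scale %.4g mm/px\n",
              length(x$ids), x$scale))
  invisible(x)
}

#' @export
print.deformed_point_set <- function(x, ...) {
  cat(sprintf("<deformed_point_set> %d points\n", length(x$ids)))
  invisible(x)
}

# Align a deformed set to the order of the reference set; error if the
# id sets differ.
match_points <- function(ref, def) {
  stopifnot(inherits(ref, "point_set"), inherits(def, "deformed_point_set"))
  idx <- match(ref$ids, def$ids)
  if (anyNA(idx) || length(ref$ids) != length(def$ids)) {
    stop("reference and deformed point sets must contain the same ids")
  }
  def$xy <- def$xy[idx, , drop = FALSE]
  def$ids <- def$ids[idx]
  def
}

#' Read and write trajectory tables
#'
#' Trajectories are exchanged as CSV with columns `id`, `frame`, `x`,
#' `y` and optionally `confidence`; `frame` 0 is the reference
#' configuration. [read_trajectories()] returns the table as a
#' data.frame; [trajectories_to_pointsets()] splits it into the
#' reference [point_set()] and one [deformed_point_set()] per
#' subsequent frame.
#'
#' @param path CSV file path.
#' @param traj data.frame with columns id, frame, x, y (confidence
#'   optional).
#' @param scale mm-per-pixel factor attached to the reference set.
#' @return `read_trajectories`: a data.frame. `trajectories_to_pointsets`:
#'   list with `ref` (point_set) and `frames` (list of
#'   deformed_point_set, one per frame >= 1).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  tr <- utils::read.csv(path)
  need <- c("id", "frame", "x", "y")
  if (!all(need %in% names(tr))) {
    stop("trajectory CSV must have columns id, frame, x, y")
  }
  tr
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trajectories
#' @export
trajectories_to_pointsets <- function(traj, scale = 0.03) {
  ref_rows <- traj[traj$frame == 0L, , drop = FALSE]
  if (nrow(ref_rows) == 0L) stop("no frame-0 (reference) rows in trajectories")
  ref_rows <- ref_rows[order(ref_rows$id), , drop = FALSE]
  ref <- point_set(ref_rows$id, cbind(ref_rows$x, ref_rows$y), scale = scale)
  frames <- sort(unique(traj$frame[traj$frame > 0L]))
  defs <- lapply(frames, function(f) {
    rows <- traj[traj$frame == f, , drop = FALSE]
    rows <- rows[order(rows$id), , drop = FALSE]
    deformed_point_set(rows$id, cbind(rows$x, rows$y))
  })
  names(defs) <- as.character(frames)
  list(ref = ref, frames = defs)
}
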