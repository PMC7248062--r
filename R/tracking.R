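#' Image sequences
#'
#' An `image_sequence` is an ordered list of single-channel intensity
#' matrices (rows = y from the top, cols = x; values on an arbitrary
#' finite scale, typically `[0, 1]`) with an optional per-frame time
#' stamp and the physical pixel scale.
#'
#' @param frames list of numeric matrices, all the same dimension,
#'   >= 2 frames.
#' @param timestamps optional numeric vector of per-frame times
#'   (seconds).
#' @param pixel_scale mm per pixel.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, timestamps = NULL, pixel_scale = 0.03) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same dimensions")
  }
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1)))) {
    stop("frame intensities must be finite")
  }
  if (!is.null(timestamps) && length(timestamps) != length(frames)) {
    stop("timestamps must match the number of frames")
  }
  structure(list(frames = frames, timestamps = timestamps,
                 pixel_scale = pixel_scale),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d px, %.4g mm/px\n",
              length(x$frames), d[1], d[2], x$pixel_scale))
  invisible(x)
}

#' Read an image sequence from disk
#'
#' Accepts a multi-page TIFF file or a directory of PNG/TIFF frames
#' (ordered by file name). Color input is converted to grayscale by
#' luminance weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path multi-page TIFF path or directory of image files.
#' @param pixel_scale mm per pixel.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(path, pixel_scale = 0.03) {
  if (!file.exists(path)) stop("input image path not found: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("need >= 2 image files in ", path)
    frames <- lapply(files, read_gray_image)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames <- lapply(pages, to_gray)
    } else {
      stop("single-file input must be a multi-page TIFF")
    }
  }
  image_sequence(frames, pixel_scale = pixel_scale)
}

read_gray_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    stop("unsupported image format: ", file))
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

#' Detect trackable fiducial points from natural image contrast
#'
#' Selects up to `max_points` corner-strength-ranked local contrast
#' maxima (smallest eigenvalue of the smoothed gradient structure
#' tensor, as in Shi-Tomasi feature selection) subject to a minimum
#' pairwise spacing — emulating the manual choice of well-textured
#' spots on shaved skin.
#'
#' @param frame0 reference image matrix.
#' @param min_spacing minimum pairwise distance between returned
#'   points, pixels.
#' @param max_points maximum number of points.
#' @param smooth_sigma Gaussian pre-smoothing / tensor-integration
#'   sigma in pixels.
#' @param scale mm per pixel, attached to the returned set.
#' @param exclude_border border margin (pixels) within which no points
#'   are returned; defaults to `2 * smooth_sigma + 10`.
#' @return A [point_set()] of detected corners (0-based pixel
#'   coordinates), strongest first.
#' @export
detect_fiducial_points <- function(frame0, min_spacing = 15, max_points = 400,
                                   smooth_sigma = 2, scale = 0.03,
                                   exclude_border = NULL) {
  frame0 <- to_gray(frame0)
  rng <- range(frame0)
  if (diff(rng) <= 1e-12) {
    stop("no trackable features: the image has constant intensity")
  }
  if (is.null(exclude_border)) exclude_border <- 2 * smooth_sigma + 10
  img <- EBImage::gblur(frame0, sigma = smooth_sigma)
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  Sxx <- EBImage::gblur(gx * gx, sigma = smooth_sigma)
  Syy <- EBImage::gblur(gy * gy, sigma = smooth_sigma)
  Sxy <- EBImage::gblur(gx * gy, sigma = smooth_sigma)
  # smaller eigenvalue of the 2x2 structure tensor
  tr2 <- (Sxx + Syy) / 2
  resp <- tr2 - sqrt(((Sxx - Syy) / 2)^2 + Sxy^2)
  b <- ceiling(exclude_border)
  mask <- matrix(FALSE, h, w)
  if (h > 2 * b && w > 2 * b) {
    mask[(b + 1):(h - b), (b + 1):(w - b)] <- TRUE
  } else {
    stop("image too small for the requested border exclusion")
  }
  # 3x3 non-maximum suppression
  is_max <- resp >= shift_mat(resp, 1, 0) & resp >= shift_mat(resp, -1, 0) &
    resp >= shift_mat(resp, 0, 1) & resp >= shift_mat(resp, 0, -1) &
    resp >= shift_mat(resp, 1, 1) & resp >= shift_mat(resp, 1, -1) &
    resp >= shift_mat(resp, -1, 1) & resp >= shift_mat(resp, -1, -1)
  cand <- which(is_max & mask & resp > 0)
  if (length(cand) == 0L) {
    stop("no trackable features: no contrast maxima found")
  }
  cand <- cand[order(resp[cand], decreasing = TRUE)]
  rows <- (cand - 1L) %% h
  cols <- (cand - 1L) %/% h
  sel_x <- numeric(0); sel_y <- numeric(0)
  for (i in seq_along(cand)) {
    x <- cols[i]; y <- rows[i]
    if (length(sel_x) == 0L ||
        all((sel_x - x)^2 + (sel_y - y)^2 >= min_spacing^2)) {
      sel_x <- c(sel_x, x); sel_y <- c(sel_y, y)
      if (length(sel_x) >= max_points) break
    }
  }
  point_set(seq_along(sel_x), cbind(sel_x, sel_y), scale = scale)
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Track fiducial points through an image sequence
#'
#' Frame-by-frame template matching by normalized cross-correlation
#' (NCC). Templates are anchored to the reference frame (frame 1), so
#' no drift accumulates; each subsequent frame is searched in a window
#' around the previous position and the correlation peak is refined to
#' subpixel precision with a three-point parabolic fit along each
#' axis. The peak NCC value is reported as the per-frame match
#' confidence; trajectories whose confidence falls below
#' `min_confidence` are flagged (not dropped) from that frame onward.
#'
#' @param seq an [image_sequence()].
#' @param points a [point_set()] of reference positions (frame 1).
#' @param window odd template size in pixels.
#' @param search odd search-window size in pixels (per frame-to-frame
#'   step, around the previous position).
#' @param min_confidence NCC threshold below which a match is flagged.
#' @return A data.frame with columns `id`, `frame` (0-based; 0 is the
#'   reference), `x`, `y` (pixels, subpixel-valued), `confidence` in
#'   `[0, 1]`, and `ok` (logical flag; FALSE once tracking became
#'   unreliable for that point).
#' @export
track_points <- function(seq, points, window = 21, search = 31,
                         min_confidence = 0.5) {
  stopifnot(inherits(seq, "image_sequence"), inherits(points, "point_set"))
  if (window %% 2 == 0 || search %% 2 == 0) {
    stop("window and search sizes must be odd")
  }
  frames <- seq$frames
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  half_t <- (window - 1) / 2
  half_s <- (search - 1) / 2
  n_pts <- length(points$ids)
  n_fr <- length(frames)
  ref <- frames[[1]]

  out <- vector("list", n_pts)
  for (p in seq_len(n_pts)) {
    x0 <- points$xy[p, 1]; y0 <- points$xy[p, 2]
    # template around the rounded reference position (1-based indices)
    tc <- round(x0) + 1L; tr <- round(y0) + 1L
    xs <- numeric(n_fr); ys <- numeric(n_fr)
    conf <- numeric(n_fr); ok <- logical(n_fr)
    xs[1] <- x0; ys[1] <- y0; conf[1] <- 1; ok[1] <- TRUE
    in_bounds <- tr - half_t >= 1 && tr + half_t <= h &&
      tc - half_t >= 1 && tc + half_t <= w
    alive <- in_bounds
    if (in_bounds) {
      tmpl <- ref[(tr - half_t):(tr + half_t), (tc - half_t):(tc + half_t)]
      frac <- c(x0 - (tc - 1L), y0 - (tr - 1L))  # subpixel ref offset
    } else {
      ok[1] <- FALSE; conf[1] <- 0
    }
    prev <- c(x0, y0)
    for (k in seq_len(n_fr)[-1]) {
      if (!alive) {
        xs[k] <- prev[1]; ys[k] <- prev[2]; conf[k] <- 0; ok[k] <- FALSE
        next
      }
      pc <- round(prev[1]) + 1L; pr <- round(prev[2]) + 1L
      r0 <- pr - half_t - half_s; c0 <- pc - half_t - half_s
      surf <- ncc_surface_cpp(frames[[k]], tmpl, r0, c0,
                              2L * half_s + 1L, 2L * half_s + 1L)
      finite <- which(is.finite(surf), arr.ind = TRUE)
      if (nrow(finite) == 0L) {
        alive <- FALSE
        xs[k] <- prev[1]; ys[k] <- prev[2]; conf[k] <- 0; ok[k] <- FALSE
        next
      }
      vals <- surf[finite]
      best <- which.max(vals)
      br <- finite[best, 1]; bc <- finite[best, 2]
      peak <- vals[best]
      # the peak must be interior to the search surface with a fully
      # finite 3x3 neighborhood, otherwise the true match likely lies
      # (partially) outside the frame and the best in-bounds placement
      # is unreliable
      interior <- br > 1L && br < nrow(surf) && bc > 1L && bc < ncol(surf) &&
        all(is.finite(surf[(br - 1L):(br + 1L), (bc - 1L):(bc + 1L)]))
      if (!interior) peak <- -1
      sub <- if (peak > 1 - 1e-9) c(0, 0) else  # perfect match
        paraboloid_offset(surf, br, bc)
      # placement (br, bc) puts the template centre at image pixel
      # (pr - half_s + br - 1, pc - half_s + bc - 1), 1-based
      cx <- (pc - half_s + bc - 1L) - 1L + sub[1] + frac[1]
      cy <- (pr - half_s + br - 1L) - 1L + sub[2] + frac[2]
      good <- is.finite(peak) && peak >= min_confidence
      xs[k] <- cx; ys[k] <- cy
      conf[k] <- max(0, min(1, peak))
      ok[k] <- good
      if (!good) alive <- FALSE else prev <- c(cx, cy)
    }
    # once a frame fails, keep the flag down for the rest
    if (any(!ok)) ok[seq(min(which(!ok)), n_fr)] <- FALSE
    out[[p]] <- data.frame(id = points$ids[p], frame = seq_len(n_fr) - 1L,
                           x = xs, y = ys, confidence = conf, ok = ok)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# subpixel refinement of a correlation peak: least-squares paraboloid
# through the 3x3 neighborhood (captures the diagonal coupling a
# sheared correlation peak exhibits); returns c(dx, dy) in
# [-0.5, 0.5]^2, or (0, 0) at a boundary/degenerate peak
paraboloid_offset <- function(surf, r, c) {
  if (r <= 1L || r >= nrow(surf) || c <= 1L || c >= ncol(surf)) {
    return(c(0, 0))
  }
  z <- surf[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
  if (!all(is.finite(z))) return(c(0, 0))
  # f = a + b x + c y + d x^2 + e xy + f y^2 on the 3x3 stencil; the
  # coefficients have closed forms as separable stencil sums
  xs <- c(-1, 0, 1)
  b <- sum(t(z) * xs) / 6          # df/dx
  cc <- sum(z * xs) / 6            # df/dy
  d <- sum(t(z) * (3 * xs^2 - 2)) / 6
  f <- sum(z * (3 * xs^2 - 2)) / 6
  e <- sum(outer(xs, xs) * z) / 4  # cross term; outer(y, x)
  det <- 4 * d * f - e * e
  if (!is.finite(det) || det < 1e-12 || d >= 0 || f >= 0) {
    return(c(0, 0))  # degenerate or saddle: no reliable refinement
  }
  dx <- (-2 * f * b + e * cc) / det
  dy <- (-2 * d * cc + e * b) / det
  c(max(-0.5, min(0.5, dx)), max(-0.5, min(0.5, dy)))
}

#' Convert a trajectory table to per-frame point sets
#'
#' Keeps only points whose `ok` flag (if present) is TRUE at the
#' requested frame, so low-confidence trajectories are excluded from
#' strain estimation without being dropped from the raw output.
#'
#' @param traj data.frame from [track_points()] or
#'   [read_trajectories()].
#' @param frame 0-based frame index (> 0).
#' @param scale mm per pixel for the reference set.
#' @return List with `ref` ([point_set()]) and `def`
#'   ([deformed_point_set()]) restricted to reliable points.
#' @export
trajectory_frame <- function(traj, frame, scale = 0.03) {
  stopifnot(frame >= 1)
  keep_ids <- unique(traj$id)
  if ("ok" %in% names(traj)) {
    bad <- unique(traj$id[traj$frame <= frame & !traj$ok])
    keep_ids <- setdiff(keep_ids, bad)
  }
  r <- traj[traj$frame == 0L & traj$id %in% keep_ids, , drop = FALSE]
  d <- traj[traj$frame == frame & traj$id %in% keep_ids, , drop = FALSE]
  r <- r[order(r$id), , drop = FALSE]
  d <- d[order(d$id), , drop = FALSE]
  if (nrow(r) == 0L || nrow(d) != nrow(r)) {
    stop("no reliable trajectories at frame ", frame)
  }
  list(ref = point_set(r$id, cbind(r$x, r$y), scale = scale),
       def = deformed_point_set(d$id, cbind(d$x, d$y)))
}
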