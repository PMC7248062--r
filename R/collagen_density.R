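#' Element-based collagen-density map from a binary fiber mask
#'
#' Splits a binary collagen mask into square elements (default
#' 50 x 50 px), quantifies the relative collagen amount per element
#' (positive pixels / total pixels, with partial edge elements using
#' their actual pixel count), smooths each element by uniform
#' averaging over the neighboring elements whose centroid-to-centroid
#' distance is at most the element diagonal (which on a square grid is
#' exactly the 8-neighborhood, corner neighbors included, plus the
#' element itself), and normalizes to the image-specific maximum. An
#' empty mask yields all-zero densities with the normalization step
#' skipped.
#'
#' @param mask binary matrix (logical or 0/1); values other than 0/1
#'   are rejected unless `threshold` is supplied, in which case the
#'   mask is first binarized at `mask > threshold`.
#' @param element_size element edge length in pixels (>= 1).
#' @param threshold optional binarization threshold for non-binary
#'   input.
#' @return An object of class `density_map`: list with `raw`,
#'   `smoothed`, `normalized` (matrices, rows x cols of elements, all
#'   in `[0, 1]`), `element_size`, and `dim` (mask dimension).
#' @examples
#' m <- matrix(0, 150, 150); m[51:100, 51:100] <- 1
#' dm <- compute_density_map(m, 50)
#' dm$raw[2, 2]       # 1: the central element is fully positive
#' dm$smoothed[2, 2]  # 1/9 before normalization
#' @export
compute_density_map <- function(mask, element_size = 50, threshold = NULL) {
  mask <- as.matrix(mask)
  if (is.logical(mask)) mask <- mask * 1
  if (!is.null(threshold)) {
    mask <- (mask > threshold) * 1
  } else if (!all(mask %in% c(0, 1))) {
    stop("mask must be binary (0/1); supply threshold= to binarize")
  }
  if (element_size < 1) stop("element_size must be >= 1")
  h <- nrow(mask); w <- ncol(mask)
  nr <- ceiling(h / element_size)
  nc <- ceiling(w / element_size)
  raw <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * element_size + 1):min(i * element_size, h)
    for (j in seq_len(nc)) {
      cols <- ((j - 1) * element_size + 1):min(j * element_size, w)
      raw[i, j] <- mean(mask[rows, cols])
    }
  }
  # neighborhood: nominal grid centroids, centroid distance <= sqrt(2) *
  # element_size (with a tiny tolerance so exact corner neighbors are in)
  diag_dist <- sqrt(2) * element_size + 1e-9
  smoothed <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- seq(max(1, i - 1), min(nr, i + 1))
      jj <- seq(max(1, j - 1), min(nc, j + 1))
      grid <- expand.grid(ii = ii, jj = jj)
      d <- element_size * sqrt((grid$ii - i)^2 + (grid$jj - j)^2)
      keep <- d <= diag_dist
      smoothed[i, j] <- mean(raw[cbind(grid$ii[keep], grid$jj[keep])])
    }
  }
  mx <- max(smoothed)
  normalized <- if (mx > 0) smoothed / mx else smoothed
  structure(list(raw = raw, smoothed = smoothed, normalized = normalized,
                 element_size = element_size, dim = c(h, w)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d elements of %d px; max raw %.3f, max smoothed %.3f\n",
    nrow(x$raw), ncol(x$raw), x$element_size, max(x$raw), max(x$smoothed)))
  invisible(x)
}

#' Write a density map as CSV grid and heat-map PNG
#'
#' @param dm a [compute_density_map()] result.
#' @param csv_path,png_path output paths (either may be NULL to skip).
#' @param palette color palette name passed to [grDevices::hcl.colors()].
#' @return Invisibly, the paths written.
#' @export
write_density_map <- function(dm, csv_path = NULL, png_path = NULL,
                              palette = "Inferno") {
  stopifnot(inherits(dm, "density_map"))
  if (!is.null(csv_path)) {
    utils::write.csv(dm$normalized, csv_path, row.names = FALSE)
  }
  if (!is.null(png_path)) {
    png::writePNG(value_to_rgb(dm$normalized, c(0, 1), palette), png_path)
  }
  invisible(c(csv = csv_path, png = png_path))
}

# map a matrix of values to an h x w x 3 RGB array with a fixed palette
value_to_rgb <- function(vals, limits, palette = "Inferno", n_colors = 256) {
  pal <- grDevices::hcl.colors(n_colors, palette)
  idx <- pmin(pmax((vals - limits[1]) / diff(limits), 0), 1)
  idx <- round(idx * (n_colors - 1)) + 1
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(nrow(vals), ncol(vals), 3))
  out[, , 1] <- matrix(rgb[1, ], nrow(vals))
  out[, , 2] <- matrix(rgb[2, ], nrow(vals))
  out[, , 3] <- matrix(rgb[3, ], nrow(vals))
  out
}
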