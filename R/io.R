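#' Analysis configuration
#'
#' Collects all pipeline parameters with defaults matching the imaging
#' study settings: 0.03 mm/px (30 mm field at 1000 px), cranio-caudal
#' extension along the image x axis, target global strain 0.10, weight
#' cutoff 100 px, and 50 px density elements. Configs round-trip
#' losslessly through JSON.
#'
#' @param scale mm per pixel.
#' @param axis extension-axis vector.
#' @param target_strain target global strain for frame selection.
#' @param r_max weight-cutoff radius (pixels).
#' @param window,search tracking template and per-step search sizes
#'   (odd pixels).
#' @param min_spacing,max_points fiducial-detection parameters.
#' @param strip_width width (pixels) of the displacement-profile strip
#'   for the functional-length fit.
#' @param roi wound ROI (see [wound_region_strain()]) or NULL to derive
#'   a rectangle inscribed in the fitted wound ellipse.
#' @param element_size density-map element edge (pixels).
#' @param out_dir output directory for pipeline runs.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(scale = 0.03, axis = c(1, 0),
                            target_strain = 0.10, r_max = 100,
                            window = 21, search = 31,
                            min_spacing = 15, max_points = 400,
                            strip_width = 100, roi = NULL,
                            element_size = 50, out_dir = ".") {
  cfg <- list(scale = scale, axis = as.numeric(axis),
              target_strain = target_strain, r_max = r_max,
              window = window, search = search,
              min_spacing = min_spacing, max_points = max_points,
              strip_width = strip_width, roi = roi,
              element_size = element_size, out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  num_pos <- c("scale", "target_strain", "r_max", "window", "search",
               "min_spacing", "max_points", "strip_width", "element_size")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (v <= 0 && f != "target_strain") || v < 0) {
      stop("invalid config field: ", f)
    }
  }
  if (length(cfg$axis) != 2L || !all(is.finite(cfg$axis)) ||
      all(cfg$axis == 0)) {
    stop("invalid config field: axis")
  }
  invisible(cfg)
}

#' @rdname analysis_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- analysis_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(unclass(base), raw)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param cfg an `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full wound-deformability analysis pipeline
#'
#' Executes detect -> track -> frame selection at the target global
#' strain -> strain field -> wound-ROI strain -> functional wound
#' length (-> ellipse morphometry when a wound mask is supplied) and
#' writes tidy outputs: `trajectories.csv`, `metrics.csv`,
#' `strain_field.csv`, `elastogram.png`, and the fully resolved
#' `config.json` beside them. Input is either an image sequence (path
#' or [image_sequence()]) or a precomputed trajectory CSV/table, which
#' skips tracking but produces the same downstream metrics.
#'
#' @param config an [analysis_config()].
#' @param images image-sequence path or object (exclusive with
#'   `trajectories`).
#' @param trajectories trajectory CSV path or data.frame.
#' @param wound_mask optional binary mask (matrix or image path) of the
#'   visible wound, used for ellipse morphometry and the default ROI.
#' @param write logical; write output files to `config$out_dir`.
#' @return List with `frame`, `achieved_strain`, `field`
#'   (strain_field), `wound_strain`, `funlen` (functional_length),
#'   `geometry` (wound_geometry or NULL), `metrics` (tidy data.frame)
#'   and `trajectories`.
#' @export
run_wound_analysis <- function(config, images = NULL, trajectories = NULL,
                               wound_mask = NULL, write = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(images) == is.null(trajectories)) {
    stop("supply exactly one of images= or trajectories=")
  }
  log_msg <- function(...) message(sprintf(...))

  if (!is.null(images)) {
    seq <- if (inherits(images, "image_sequence")) images else
      read_image_sequence(images, pixel_scale = config$scale)
    log_msg("detecting fiducial points (min_spacing=%g, max_points=%g)",
            config$min_spacing, config$max_points)
    pts <- detect_fiducial_points(seq$frames[[1]],
                                  min_spacing = config$min_spacing,
                                  max_points = config$max_points,
                                  scale = config$scale)
    log_msg("tracking %d points over %d frames (window=%g, search=%g)",
            length(pts$ids), length(seq$frames), config$window,
            config$search)
    traj <- track_points(seq, pts, window = config$window,
                         search = config$search)
  } else {
    traj <- if (is.character(trajectories)) read_trajectories(trajectories)
      else trajectories
    log_msg("using %d supplied trajectories", length(unique(traj$id)))
  }

  sel <- select_frame_at_global_strain(traj, axis = config$axis,
                                       target = config$target_strain,
                                       scale = config$scale)
  log_msg("target global strain %.3f reached at frame %d (achieved %.4f)",
          config$target_strain, sel$frame, sel$achieved)
  ps <- trajectory_frame(traj, sel$frame - 1L, scale = config$scale)
  field <- compute_strain_field(ps$ref, ps$def, axis = config$axis,
                                scheme = weight_scheme(config$r_max))
  log_msg("strain field: %d points estimated, %d failed",
          nrow(field$points), nrow(field$failed))

  geometry <- NULL
  roi <- config$roi
  if (!is.null(wound_mask)) {
    mask <- if (is.character(wound_mask)) {
      (read_gray_image(wound_mask) > 0.5) * 1
    } else wound_mask
    geometry <- fit_wound_ellipse(mask_to_contour(mask), axis = config$axis,
                                  scale = config$scale)
    if (is.null(roi)) {
      # default ROI: rectangle inscribed in the fitted ellipse
      half <- geometry$semi_axes / sqrt(2)
      roi <- list(type = "rect",
                  x0 = geometry$center[1] - half[1],
                  x1 = geometry$center[1] + half[1],
                  y0 = geometry$center[2] - half[2],
                  y1 = geometry$center[2] + half[2])
    }
  }
  if (is.null(roi)) {
    stop("no wound ROI: supply config$roi or a wound_mask")
  }
  wound_strain <- wound_region_strain(field, roi)

  strip_center <- if (roi$type == "rect") (roi$y0 + roi$y1) / 2 else roi$cy
  funlen <- functional_wound_length(
    ps$ref, ps$def, strip = list(center = strip_center,
                                 width = config$strip_width),
    axis = config$axis)

  metrics <- data.frame(
    metric = c("frame_at_target", "achieved_global_strain",
               "wound_region_strain", "functional_length_mm",
               if (!is.null(geometry)) c("visible_length_mm",
                                         "visible_area_mm2")),
    value = c(sel$frame, sel$achieved, wound_strain,
              funlen$functional_length_mm,
              if (!is.null(geometry)) c(geometry$visible_length_mm,
                                        geometry$area_mm2)))

  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_trajectories(traj, p("trajectories.csv"))
    utils::write.csv(field$points, p("strain_field.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(metrics, p("metrics.csv"), row.names = FALSE,
                     quote = FALSE)
    write_config(config, p("config.json"))
    write_elastogram(field, p("elastogram.png"))
    log_msg("outputs written to %s", config$out_dir)
  }
  list(frame = sel$frame, achieved_strain = sel$achieved, field = field,
       wound_strain = wound_strain, funlen = funlen, geometry = geometry,
       metrics = metrics, trajectories = traj)
}

#' Render an elastogram PNG from a strain field
#'
#' Rasterizes per-point axial strains as filled squares on a dark
#' background using a fixed perceptually uniform colormap (Viridis),
#' with the color limits spanning the observed strain range (or a
#' supplied pair), and a 1-px white scale bar of 5 mm length in the
#' bottom-left corner.
#'
#' @param field a `strain_field`.
#' @param path output PNG path.
#' @param limits length-2 color limits for the axial strain; default
#'   the field range.
#' @param dot half-size of the rasterized point marker (pixels).
#' @param dim output image size `c(rows, cols)`; default the bounding
#'   box of the points.
#' @return Invisibly, `path`.
#' @export
write_elastogram <- function(field, path, limits = NULL, dot = 4,
                             dim = NULL) {
  stopifnot(inherits(field, "strain_field"))
  pts <- field$points
  if (nrow(pts) == 0L) stop("empty strain field")
  if (is.null(dim)) {
    dim <- c(ceiling(max(pts$y)) + dot + 2, ceiling(max(pts$x)) + dot + 2)
  }
  if (is.null(limits)) limits <- range(pts$axial)
  if (diff(limits) == 0) limits <- limits + c(-1e-6, 1e-6)
  vals <- matrix(NA_real_, dim[1], dim[2])
  for (i in seq_len(nrow(pts))) {
    r <- round(pts$y[i]) + 1; c <- round(pts$x[i]) + 1
    rs <- max(1, r - dot):min(dim[1], r + dot)
    cs <- max(1, c - dot):min(dim[2], c + dot)
    vals[rs, cs] <- pts$axial[i]
  }
  img <- value_to_rgb(ifelse(is.na(vals), limits[1], vals), limits,
                      palette = "Viridis")
  dark <- is.na(vals)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[dark] <- 0.08
    img[, , ch] <- plane
  }
  # 5 mm scale bar
  bar_px <- round(5 / field$scale)
  if (bar_px + 20 < dim[2]) {
    rr <- (dim[1] - 12):(dim[1] - 10)
    cc <- 10:(10 + bar_px)
    for (ch in 1:3) img[rr, cc, ch] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Run the density-mapping pipeline on a mask file
#'
#' Reads a binary collagen mask (PNG/TIFF), computes the element-based
#' density map and writes the CSV grid and heat-map PNG, plus the
#' resolved config.
#'
#' @param config an [analysis_config()].
#' @param mask_path path to the binary mask image.
#' @param threshold optional binarization threshold for non-binary
#'   masks; without it, non-binary input is an error.
#' @param name stem for the output files.
#' @return The `density_map`, invisibly-written outputs in
#'   `config$out_dir`.
#' @export
run_density_map <- function(config, mask_path, threshold = NULL,
                            name = "density") {
  stopifnot(inherits(config, "analysis_config"))
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
  mask <- read_gray_image(mask_path)
  dm <- compute_density_map(mask, element_size = config$element_size,
                            threshold = threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_density_map(dm,
                    csv_path = file.path(config$out_dir,
                                         paste0(name, ".csv")),
                    png_path = file.path(config$out_dir,
                                         paste0(name, ".png")))
  write_config(config, file.path(config$out_dir, "config.json"))
  dm
}

#' Write an image sequence to disk
#'
#' A path ending in `.tif`/`.tiff` produces a 16-bit multi-page TIFF
#' (preserving subpixel-relevant intensity resolution); any other path
#' is treated as a directory of ordered 8-bit PNG frames.
#'
#' @param seq an [image_sequence()].
#' @param path multi-page TIFF file or output directory.
#' @return Invisibly, the written file path(s).
#' @export
write_image_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  frames <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 1))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(frames, path, bits.per.sample = 16)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    paths[k] <- file.path(path, sprintf("frame_%03d.png", k - 1L))
    png::writePNG(frames[[k]], paths[k])
  }
  invisible(paths)
}
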