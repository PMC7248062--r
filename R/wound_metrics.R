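#' Select the frame at which a target global strain is reached
#'
#' Standardizes measurements across acquisitions: computes the global
#' strain (regression slope, [global_strain()]) for every frame of a
#' trajectory table and returns the first frame at which it reaches
#' the prescribed level (first-crossing rule, no interpolation). The
#' achieved strain is reported so downstream normalization can correct
#' small overshoot.
#'
#' @param traj trajectory data.frame (columns id, frame, x, y,
#'   optionally ok/confidence).
#' @param axis extension-axis vector.
#' @param target target global strain (default 0.10; the study design
#'   also uses 0.05).
#' @param scale mm per pixel.
#' @return List with `frame` (1-based index into the sequence; frame 1
#'   is the reference), `achieved` global strain, and `strains` per
#'   frame.
#' @export
select_frame_at_global_strain <- function(traj, axis = c(1, 0),
                                          target = 0.10, scale = 0.03) {
  frames <- sort(unique(traj$frame))
  strains <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    if (f == 0L) { strains[i] <- 0; next }
    ps <- trajectory_frame(traj, f, scale = scale)
    strains[i] <- global_strain(ps$ref, ps$def, axis)
  }
  hit <- which(strains >= target)
  if (length(hit) == 0L) {
    stop(sprintf(
      "target global strain %.3f never reached (maximum achieved: %.4f)",
      target, max(strains)))
  }
  list(frame = frames[hit[1]] + 1L, achieved = strains[hit[1]],
       strains = data.frame(frame = frames, global_strain = strains))
}

#' Compute the Green-Lagrange strain field at every tracking point
#'
#' Evaluates the local deformation gradient
#' ([estimate_deformation_gradient()]) and Green-Lagrange tensor
#' ([green_lagrange()]) at each tracking-point location, using all
#' neighbors within the weight cutoff. The axial component (along the
#' extension axis) is the elastogram quantity. Per-point failures
#' (insufficient or degenerate support) are collected, not fatal.
#'
#' @inheritParams estimate_deformation_gradient
#' @param axis extension-axis vector.
#' @return An object of class `strain_field`: data.frame `points` with
#'   columns id, x, y (reference pixels), F11, F12, F21, F22, E11,
#'   E12, E22, axial, n_support; `failed` data.frame (id, x, y,
#'   reason); plus `axis` and `scale` attributes.
#' @export
compute_strain_field <- function(ref, def, axis = c(1, 0),
                                 scheme = weight_scheme()) {
  def <- match_points(ref, def)
  e <- normalize_axis(axis)
  n <- length(ref$ids)
  rows <- vector("list", n)
  failed <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(
      estimate_deformation_gradient(ref, def, ref$xy[i, ], scheme),
      error = function(err) err)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- data.frame(
        id = ref$ids[i], x = ref$xy[i, 1], y = ref$xy[i, 2],
        reason = conditionMessage(res))
      next
    }
    st <- green_lagrange(res$F, e)
    rows[[i]] <- data.frame(
      id = ref$ids[i], x = ref$xy[i, 1], y = ref$xy[i, 2],
      F11 = res$F[1, 1], F12 = res$F[1, 2],
      F21 = res$F[2, 1], F22 = res$F[2, 2],
      E11 = st$E[1, 1], E12 = st$E[1, 2], E22 = st$E[2, 2],
      axial = st$axial, n_support = res$n_support)
  }
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pts)) pts <- data.frame()
  failed <- if (length(failed)) do.call(rbind, failed) else
    data.frame(id = integer(), x = numeric(), y = numeric(),
               reason = character())
  structure(list(points = pts, failed = failed, axis = e,
                 scale = ref$scale),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d points (%d failed), axis (%.2f, %.2f)\n",
              nrow(x$points), nrow(x$failed), x$axis[1], x$axis[2]))
  if (nrow(x$points)) {
    cat(sprintf("axial strain: mean %.4f, range [%.4f, %.4f]\n",
                mean(x$points$axial), min(x$points$axial),
                max(x$points$axial)))
  }
  invisible(x)
}

#' Average strain within a wound region of interest
#'
#' The wound deformability readout: the unweighted mean of the axial
#' Green-Lagrange strains of all field points falling inside a region
#' selected within the visible wound area.
#'
#' @param field a [compute_strain_field()] result.
#' @param roi region in reference pixels: either
#'   `list(type = "rect", x0, y0, x1, y1)` or
#'   `list(type = "ellipse", cx, cy, a, b, theta = 0)`.
#' @return Scalar mean axial strain.
#' @export
wound_region_strain <- function(field, roi) {
  stopifnot(inherits(field, "strain_field"))
  pts <- field$points
  if (nrow(pts) == 0L) stop("strain field contains no points")
  inside <- roi_contains(roi, pts$x, pts$y)
  if (!any(inside)) stop("no strain-field points inside the region of interest")
  mean(pts$axial[inside])
}

roi_contains <- function(roi, x, y) {
  type <- roi$type %||% "rect"
  if (type == "rect") {
    x >= min(roi$x0, roi$x1) & x <= max(roi$x0, roi$x1) &
      y >= min(roi$y0, roi$y1) & y <= max(roi$y0, roi$y1)
  } else if (type == "ellipse") {
    th <- roi$theta %||% 0
    dx <- x - roi$cx; dy <- y - roi$cy
    xr <- cos(th) * dx + sin(th) * dy
    yr <- -sin(th) * dx + cos(th) * dy
    (xr / roi$a)^2 + (yr / roi$b)^2 <= 1
  } else {
    stop("unknown ROI type: ", type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deformability ratio between two wounds or conditions
#'
#' Ratio of two average wound strains, e.g. comparing genotypes or
#' strain levels; invariant to the applied global strain in the
#' linear regime.
#'
#' @param strain_a,strain_b scalar average strains; `strain_b` must be
#'   nonzero.
#' @return `strain_a / strain_b`.
#' @export
deformability_ratio <- function(strain_a, strain_b) {
  stopifnot(is.finite(strain_a), is.finite(strain_b))
  if (strain_b == 0) stop("denominator strain must be nonzero")
  strain_a / strain_b
}

#' Functional wound length from a piecewise displacement regression
#'
#' Focuses on a narrow tissue strip through the wound, charts the
#' axis-projected displacement against the axis-projected reference
#' position, and fits a continuous three-segment piecewise-linear
#' model: outer segments follow the compliant surrounding skin, the
#' middle segment the stiffer, less-deforming wound. Breakpoints are
#' chosen by exhaustive grid search over candidate pairs to minimize
#' the total squared residual. The distance between the breakpoints —
#' the extent of the mechanically affected region, typically larger
#' than the visible wound — is the functional wound length.
#'
#' If the middle-segment slope is not lower than both outer slopes by
#' the detectability margin, no mechanically distinct wound region is
#' detectable and a zero length is returned with `detected = FALSE`.
#'
#' @inheritParams estimate_deformation_gradient
#' @param strip `list(center, width)`: transverse centre (pixels) and
#'   width of the analysis strip; `NULL` uses the full point set.
#' @param axis extension-axis vector.
#' @param margin relative detectability margin: the middle slope must
#'   be below `(1 - margin)` times the smaller outer slope.
#' @param n_candidates maximum number of candidate breakpoints per
#'   side of the grid search.
#' @param min_points minimum points per segment.
#' @return An object of class `functional_length`: list with
#'   `breakpoints` (pixels), `functional_length_mm`, `inside_slope`,
#'   `outside_slopes` (left, right), `rss`, `detected`, `n_points`.
#' @export
functional_wound_length <- function(ref, def, strip = NULL, axis = c(1, 0),
                                    margin = 0.20, n_candidates = 50,
                                    min_points = 4) {
  def <- match_points(ref, def)
  e <- normalize_axis(axis)
  t_perp <- c(-e[2], e[1])
  X <- as.numeric(ref$xy %*% e)
  Tv <- as.numeric(ref$xy %*% t_perp)
  u <- as.numeric((def$xy - ref$xy) %*% e)
  if (!is.null(strip)) {
    keep <- abs(Tv - strip$center) <= strip$width / 2
    X <- X[keep]; u <- u[keep]
  }
  if (length(X) < 3 * min_points) {
    stop("too few points in the analysis strip for a three-segment fit")
  }
  ord <- order(X)
  X <- X[ord]; u <- u[ord]

  xs <- sort(unique(X))
  cand <- xs[-c(1, length(xs))]
  if (length(cand) > n_candidates) {
    cand <- cand[unique(round(seq(1, length(cand),
                                  length.out = n_candidates)))]
  }
  best <- NULL
  for (i in seq_along(cand)) {
    b1 <- cand[i]
    n_left <- sum(X < b1)
    if (n_left < min_points) next
    for (j in seq_along(cand)) {
      b2 <- cand[j]
      if (b2 <= b1) next
      n_mid <- sum(X >= b1 & X < b2)
      n_right <- sum(X >= b2)
      if (n_mid < min_points || n_right < min_points) next
      A <- cbind(1, X, pmax(X - b1, 0), pmax(X - b2, 0))
      fit <- stats::.lm.fit(A, u)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(rss = rss, b1 = b1, b2 = b2, beta = fit$coefficients)
      }
    }
  }
  if (is.null(best)) {
    stop("no admissible breakpoint pair: too few points per segment")
  }
  # continuous refinement of the breakpoint pair around the grid optimum
  pw_rss <- function(b) {
    if (b[1] >= b[2]) return(Inf)
    if (sum(X < b[1]) < min_points || sum(X >= b[2]) < min_points ||
        sum(X >= b[1] & X < b[2]) < min_points) return(Inf)
    A <- cbind(1, X, pmax(X - b[1], 0), pmax(X - b[2], 0))
    fit <- stats::.lm.fit(A, u)
    sum(fit$residuals^2)
  }
  opt <- stats::optim(c(best$b1, best$b2), pw_rss, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  if (is.finite(opt$value) && opt$value <= best$rss) {
    A <- cbind(1, X, pmax(X - opt$par[1], 0), pmax(X - opt$par[2], 0))
    fit <- stats::.lm.fit(A, u)
    best <- list(rss = opt$value, b1 = opt$par[1], b2 = opt$par[2],
                 beta = fit$coefficients)
  }
  s_left <- best$beta[2]
  s_mid <- best$beta[2] + best$beta[3]
  s_right <- best$beta[2] + best$beta[3] + best$beta[4]
  detected <- s_mid < (1 - margin) * min(s_left, s_right)
  structure(list(
    breakpoints = c(best$b1, best$b2),
    functional_length_mm = if (detected)
      (best$b2 - best$b1) * ref$scale else 0,
    inside_slope = unname(s_mid),
    outside_slopes = unname(c(s_left, s_right)),
    rss = best$rss, detected = detected, n_points = length(X)),
    class = "functional_length")
}

#' @export
print.functional_length <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<functional_length> %.2f mm (breakpoints %.1f - %.1f px)\n",
      x$functional_length_mm, x$breakpoints[1], x$breakpoints[2]))
    cat(sprintf("slopes: outer %.4f / %.4f, wound %.4f\n",
                x$outside_slopes[1], x$outside_slopes[2], x$inside_slope))
  } else {
    cat("<functional_length> no mechanically distinct wound region detected\n")
  }
  invisible(x)
}

#' Fit an ellipse to a visible-wound contour
#'
#' Direct least-squares conic fitting constrained to an ellipse
#' (Fitzgibbon's method in the numerically stable partitioned form),
#' replacing the manual ellipse tool of interactive image software.
#' Area and the extent along the extension axis are returned in
#' physical units.
#'
#' @param contour n x 2 matrix of contour points (pixels), n >= 5,
#'   not collinear.
#' @param axis extension-axis vector.
#' @param scale mm per pixel.
#' @return An object of class `wound_geometry`: list with `center`
#'   (pixels), `semi_axes` (pixels, major first), `semi_axes_mm`,
#'   `orientation` (radians, major axis from image x), `area_mm2`,
#'   `visible_length_mm` (extent of the ellipse projected on the
#'   axis).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' g <- fit_wound_ellipse(cbind(500 + 100 * cos(th), 500 + 100 * sin(th)))
#' g$area_mm2  # pi * (3 mm)^2
#' @export
fit_wound_ellipse <- function(contour, axis = c(1, 0), scale = 0.03) {
  contour <- as_xy_matrix(contour)
  if (nrow(contour) < 5L) stop("ellipse fitting needs >= 5 contour points")
  e <- normalize_axis(axis)
  x <- contour[, 1]; y <- contour[, 2]
  mx <- mean(x); my <- mean(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  s <- max(sx, sy)
  if (!is.finite(s) || s == 0) stop("degenerate contour: zero spatial extent")
  xn <- (x - mx) / s; yn <- (y - my) / s

  # Halir-Flusser partitioned direct ellipse fit on normalized coords
  D1 <- cbind(xn^2, xn * yn, yn^2)
  D2 <- cbind(xn, yn, 1)
  S1 <- t(D1) %*% D1
  S2 <- t(D1) %*% D2
  S3 <- t(D2) %*% D2
  if (kappa(S3, exact = TRUE) > 1e10) {
    stop("ellipse fit failed: degenerate (collinear) contour points")
  }
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  a1 <- NULL
  for (k in seq_len(ncol(ev$vectors))) {
    v <- Re(ev$vectors[, k])
    cond <- 4 * v[1] * v[3] - v[2]^2
    if (is.finite(cond) && cond > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stop("ellipse fit failed: best conic is not an ellipse")
  coefs <- c(a1, as.numeric(T_ %*% a1))  # A B C D E F on normalized coords

  # conic -> geometric parameters (still normalized frame)
  A <- coefs[1]; B <- coefs[2] / 2; C <- coefs[3]
  D <- coefs[4] / 2; E <- coefs[5] / 2; F_ <- coefs[6]
  den <- A * C - B^2
  if (den <= 0) stop("ellipse fit failed: best conic is not an ellipse")
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  mu <- A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * D * cx + 2 * E * cy + F_
  lam <- eigen(matrix(c(A, B, B, C), 2, 2), symmetric = TRUE)
  ax2 <- -mu / lam$values
  if (any(ax2 <= 0)) stop("ellipse fit failed: non-positive axis lengths")
  semi <- sqrt(ax2)            # paired with lam$vectors columns
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord]
  major_vec <- lam$vectors[, ord[1]]

  # back to pixel coordinates
  center <- c(cx, cy) * s + c(mx, my)
  semi_px <- semi * s
  orientation <- atan2(major_vec[2], major_vec[1])
  # extent of the ellipse projected on a direction d:
  # 2 * sqrt((a d.v1)^2 + (b d.v2)^2)
  v1 <- major_vec
  v2 <- lam$vectors[, ord[2]]
  ext_px <- 2 * sqrt((semi_px[1] * sum(e * v1))^2 +
                     (semi_px[2] * sum(e * v2))^2)
  structure(list(center = center, semi_axes = semi_px,
                 semi_axes_mm = semi_px * scale,
                 orientation = orientation,
                 area_mm2 = pi * semi_px[1] * semi_px[2] * scale^2,
                 visible_length_mm = ext_px * scale),
            class = "wound_geometry")
}

#' @export
print.wound_geometry <- function(x, ...) {
  cat(sprintf(
    "<wound_geometry> area %.2f mm2, visible length %.2f mm, centre (%.1f, %.1f) px\n",
    x$area_mm2, x$visible_length_mm, x$center[1], x$center[2]))
  invisible(x)
}

#' Extract the visible-wound contour from a binary mask
#'
#' Labels connected components, keeps the largest, and returns its
#' boundary pixels (positive pixels with at least one 4-neighbor
#' outside the component) as unordered 0-based coordinates, suitable
#' for [fit_wound_ellipse()].
#'
#' @param mask binary matrix (0/1 or logical).
#' @return n x 2 matrix of boundary coordinates (x, y, pixels).
#' @export
mask_to_contour <- function(mask) {
  mask <- (as.matrix(mask) > 0) * 1
  if (sum(mask) == 0) stop("mask is empty: no wound region to outline")
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  comp <- which.max(tab)
  m <- (lab == comp) * 1
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                 pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)])
  boundary <- which(core == 1 & nb_min == 0, arr.ind = TRUE)
  cbind(x = boundary[, 2] - 1, y = boundary[, 1] - 1)
}

#' Healing time series and Eq.-style finite-difference rates
#'
#' `healing_series` stores a scalar wound metric (length in mm, strain,
#' or area in mm^2) at unevenly spaced measurement days;
#' `healing_rates` computes per-day rate-of-change estimates with the
#' three-point central finite-difference formula for uneven spacing at
#' interior days, a forward difference at the first day and a backward
#' difference at the last. The central formula is exact for quadratic
#' time courses.
#'
#' @param times measurement times (days), strictly increasing.
#' @param values metric values, same length.
#' @param metric optional metric name.
#' @return `healing_series`: object of class `healing_series`.
#'   `healing_rates`: the same object with a `rates` element (units of
#'   value per day).
#' @examples
#' hs <- healing_series(c(3, 5, 7, 10, 14, 21), c(3, 5, 7, 10, 14, 21)^2)
#' healing_rates(hs)$rates  # interior entries equal 2 t
#' @export
healing_series <- function(times, values, metric = "value") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (length(times) < 2L) stop("need >= 2 time points")
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing (no duplicates)")
  }
  structure(list(times = times, values = values, metric = metric,
                 rates = NULL),
            class = "healing_series")
}

#' @rdname healing_series
#' @param series a `healing_series`.
#' @export
healing_rates <- function(series) {
  stopifnot(inherits(series, "healing_series"))
  t <- series$times; f <- series$values
  n <- length(t)
  r <- numeric(n)
  r[1] <- (f[2] - f[1]) / (t[2] - t[1])
  r[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    for (i in 2:(n - 1)) {
      dtp <- t[i + 1] - t[i]      # forward gap
      dtm <- t[i] - t[i - 1]      # backward gap
      dtc <- t[i + 1] - t[i - 1]
      r[i] <- dtm / (dtp * dtc) * f[i + 1] +
        (dtp - dtm) / (dtp * dtm) * f[i] -
        dtp / (dtm * dtc) * f[i - 1]
    }
  }
  series$rates <- r
  series
}

#' @export
print.healing_series <- function(x, ...) {
  cat(sprintf("<healing_series> %s at %d time points (days %s)\n",
              x$metric, length(x$times),
              paste(x$times, collapse = ", ")))
  if (!is.null(x$rates)) {
    cat("rates:", paste(format(x$rates, digits = 4), collapse = ", "), "\n")
  }
  invisible(x)
}
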