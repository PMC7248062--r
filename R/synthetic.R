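#' Analytic inclusion displacement field
#'
#' Ground-truth generator for a uniaxially stretched sheet containing a
#' stiff circular inclusion (a model wound): the axial engineering
#' strain is `eps_in` inside the inclusion, `eps_out` far outside, with
#' a smooth cosine ramp over a transition band, as a function of the
#' distance from the inclusion centre. The axial displacement is the
#' line integral of this strain profile along the extension axis
#' (anchored at the inclusion centre); the transverse displacement is
#' zero. Both the displacement and the exact pointwise strain are
#' available as functions, so any strain estimator can be checked
#' against analytic truth.
#'
#' The defaults emulate the imaging study conditions: a 1000 x 1000 px
#' sheet (30 x 30 mm at 0.03 mm/px) with a 100 px (3 mm) radius
#' inclusion, far-field strain 0.10 and inclusion strain 0.02 — a
#' deformability contrast of 5 — and a 40 px transition band so that
#' the strain field stays resolvable by a local estimator.
#'
#' @param size sheet size in pixels (square).
#' @param center inclusion centre (pixels); default sheet centre.
#' @param radius inclusion radius in pixels.
#' @param eps_out far-field axial engineering strain.
#' @param eps_in axial engineering strain at the inclusion centre;
#'   must satisfy `eps_in <= eps_out` (stiff inclusion).
#' @param band transition band width in pixels (cosine ramp from the
#'   inclusion edge outward).
#' @param axis extension axis (unit 2-vector; only `c(1, 0)` and
#'   `c(0, 1)` are supported by the analytic construction).
#' @return An object of class `inclusion_field`: list with the
#'   parameters plus `strain(xy)` (exact axial engineering strain),
#'   `strain_gl(xy)` (exact axial Green-Lagrange strain) and
#'   `displacement(xy)` (n x 2 displacement in pixels), each taking an
#'   n x 2 matrix of reference positions.
#' @examples
#' fld <- make_inclusion_field(size = 400, radius = 60, band = 30)
#' fld$strain(rbind(c(200, 200), c(10, 200)))  # 0.02, 0.10
#' @export
make_inclusion_field <- function(size = 1000, center = NULL, radius = 100,
                                 eps_out = 0.10, eps_in = 0.02, band = 40,
                                 axis = c(1, 0)) {
  if (is.null(center)) center <- c(size, size) / 2
  center <- as.numeric(center)
  e <- normalize_axis(axis)
  if (!isTRUE(all.equal(abs(e), c(1, 0))) &&
      !isTRUE(all.equal(abs(e), c(0, 1)))) {
    stop("axis must be aligned with the image x or y axis")
  }
  if (eps_in > eps_out) stop("eps_in must be <= eps_out (stiff inclusion)")
  if (radius + band >= size / 2) {
    stop("radius + band must be smaller than the sheet half-extent")
  }
  along_x <- abs(e[1]) > 0.5

  # cosine bump: 1 inside the inclusion, 0 beyond radius + band
  bump <- function(r) {
    out <- numeric(length(r))
    out[r <= radius] <- 1
    ramp <- r > radius & r < radius + band
    out[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - radius) / band))
    out
  }
  strain_fun <- function(xy) {
    xy <- as_xy_matrix(xy)
    r <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
    eps_out + (eps_in - eps_out) * bump(r)
  }
  # axial displacement: integrate the strain profile from the centre
  # abscissa to each point along the axis (composite Simpson, smooth
  # integrand, accurate to ~1e-12 relative)
  displacement_fun <- function(xy, n_sub = 2048L) {
    xy <- as_xy_matrix(xy)
    if (nrow(xy) > 2048L) {  # chunk to bound the quadrature matrix size
      chunks <- split(seq_len(nrow(xy)),
                      ceiling(seq_len(nrow(xy)) / 2048))
      return(do.call(rbind, lapply(chunks, function(ix)
        displacement_fun(xy[ix, , drop = FALSE], n_sub))))
    }
    if (along_x) {
      a <- xy[, 1]; t_coord <- xy[, 2]; c_a <- center[1]; c_t <- center[2]
    } else {
      a <- xy[, 2]; t_coord <- xy[, 1]; c_a <- center[2]; c_t <- center[1]
    }
    n <- length(a)
    k <- 0:n_sub
    # Simpson weights (n_sub even)
    wts <- rep(c(4, 2), length.out = n_sub - 1)
    wts <- c(1, wts, 1) / 3
    # nodes per point: from the centre abscissa to the point abscissa
    h <- (a - c_a) / n_sub
    nodes <- outer(k, h) + c_a                      # (n_sub+1) x n
    tt <- matrix(t_coord, nrow = n_sub + 1, ncol = n, byrow = TRUE)
    r <- sqrt((nodes - c_a)^2 + (tt - c_t)^2)
    eps <- eps_out + (eps_in - eps_out) * bump(as.numeric(r))
    eps <- matrix(eps, nrow = n_sub + 1)
    u_axial <- colSums(eps * wts) * h
    u <- matrix(0, n, 2)
    u[, if (along_x) 1 else 2] <- u_axial
    u
  }
  strain_gl_fun <- function(xy) {
    eps <- strain_fun(xy)
    eps + eps^2 / 2
  }
  structure(list(size = size, center = center, radius = radius,
                 eps_out = eps_out, eps_in = eps_in, band = band,
                 axis = e, strain = strain_fun, strain_gl = strain_gl_fun,
                 displacement = displacement_fun),
            class = "inclusion_field")
}

#' @export
print.inclusion_field <- function(x, ...) {
  cat(sprintf(
    "<inclusion_field> %d px sheet, inclusion r=%g px at (%g, %g), eps %g -> %g, band %g px\n",
    x$size, x$radius, x$center[1], x$center[2], x$eps_in, x$eps_out, x$band))
  invisible(x)
}

#' Render a synthetic speckle image sequence with ground truth
#'
#' Draws a random Gaussian-blob speckle pattern on the reference sheet
#' and advects it through an [make_inclusion_field()] displacement
#' field, scaled linearly from 0 (frame 1) to the full field (last
#' frame) — emulating a video of a progressively stretched, naturally
#' textured skin surface. Additive Gaussian pixel noise is applied
#' per frame. Exact per-speckle trajectories are returned for tracker
#' validation. All randomness flows through the mandatory seed:
#' identical seeds give bit-identical output.
#'
#' @param field an [make_inclusion_field()] object.
#' @param n_frames number of frames (>= 2); frame 1 is the reference.
#' @param n_speckles number of Gaussian blobs; default a speckle
#'   density of 0.012 blobs per px^2 (about 5 blobs per 21 px tracking
#'   window).
#' @param noise_sigma standard deviation of additive Gaussian noise on
#'   the `[0, 1]` intensity scale (0.02 = 2 % of the dynamic range).
#' @param seed integer RNG seed (mandatory).
#' @param blob_sigma Gaussian blob radius parameter in pixels.
#' @param scale mm-per-pixel factor carried into the sequence.
#' @return List with `seq` (an `image_sequence`), `truth` (data.frame
#'   id, frame (0-based), x, y of exact speckle positions) and `field`.
#' @export
render_speckle_sequence <- function(field, n_frames = 6, n_speckles = NULL,
                                    noise_sigma = 0.0, seed,
                                    blob_sigma = 1.5, scale = 0.03) {
  stopifnot(inherits(field, "inclusion_field"))
  if (missing(seed)) stop("a seed is mandatory for reproducible rendering")
  if (n_frames < 2) stop("n_frames must be >= 2")
  # default speckle density 0.012 blobs/px^2 (~5 blobs per 21 px
  # tracking window), comparable to a well-prepared DIC speckle pattern
  if (is.null(n_speckles)) n_speckles <- round(0.012 * field$size^2)
  set.seed(as.integer(seed))
  size <- field$size
  margin <- 4 * blob_sigma
  centers <- cbind(runif(n_speckles, margin, size - 1 - margin),
                   runif(n_speckles, margin, size - 1 - margin))
  amps <- runif(n_speckles, 0.4, 1.0)
  u_full <- if (n_speckles > 0) field$displacement(centers) else
    matrix(0, 0, 2)
  alphas <- seq(0, 1, length.out = n_frames)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    pos <- centers + alphas[k] * u_full
    img <- render_blobs(size, pos, amps, blob_sigma)
    if (noise_sigma > 0) {
      img <- img + matrix(rnorm(size * size, 0, noise_sigma), size, size)
    }
    frames[[k]] <- pmin(pmax(img, 0), 1)
    if (n_speckles > 0) {
      truth[[k]] <- data.frame(id = seq_len(n_speckles),
                               frame = k - 1L, x = pos[, 1], y = pos[, 2])
    }
  }
  truth <- if (n_speckles > 0) do.call(rbind, truth) else
    data.frame(id = integer(), frame = integer(),
               x = numeric(), y = numeric())
  list(seq = image_sequence(frames, pixel_scale = scale),
       truth = truth, field = field)
}

# additive rendering of Gaussian blobs into a size x size image;
# coordinates are 0-based pixel centres (column x, row y)
render_blobs <- function(size, pos, amps, blob_sigma) {
  img <- matrix(0, size, size)
  if (nrow(pos) == 0) return(img)
  half <- ceiling(4 * blob_sigma)
  for (i in seq_len(nrow(pos))) {
    cx <- pos[i, 1]; cy <- pos[i, 2]
    c0 <- max(0, floor(cx) - half); c1 <- min(size - 1, floor(cx) + half)
    r0 <- max(0, floor(cy) - half); r1 <- min(size - 1, floor(cy) + half)
    if (c0 > c1 || r0 > r1) next
    xs <- c0:c1; ys <- r0:r1
    gx <- exp(-(xs - cx)^2 / (2 * blob_sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * blob_sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amps[i] * outer(gy, gx)
  }
  img
}

#' Rate-dependent stiffness contrast (standard linear solid)
#'
#' Models how the effective stiffness contrast between a stiff
#' inclusion and its viscoelastic surroundings depends on loading
#' duration, with standard-linear-solid relaxation: the contrast moves
#' monotonically from `contrast_inst` for fast loading to
#' `contrast_eq` for slow loading, via the ramp-averaged relaxation
#' fraction `g(T) = (tau/T) (1 - exp(-T/tau))`. The inclusion-centre
#' strain under a far-field strain `eps_out` is then
#' `eps_out / contrast(T)`. Defaults emulate a viscoelastic-elastomer
#' phantom stretched to 15 % nominal strain at rates of 0.10 vs
#' 0.001 1/s (loading durations 1.5 vs 150 s), for which the centre
#' strain changes only from about 1.7 % to 2.2 % despite the 100-fold
#' rate variation.
#'
#' @param contrast_inst instantaneous (fast-loading) stiffness
#'   contrast, > contrast_eq.
#' @param contrast_eq equilibrium (slow-loading) stiffness contrast,
#'   > 1.
#' @param tau relaxation time in seconds.
#' @return An object of class `rate_model` with functions
#'   `contrast(duration)` and `center_strain(eps_out, duration)`.
#' @examples
#' rm <- rate_model()
#' rm$center_strain(0.15, 1.5)   # ~0.017 (fast)
#' rm$center_strain(0.15, 150)   # ~0.022 (slow)
#' @export
rate_model <- function(contrast_inst = 9.13, contrast_eq = 6.72, tau = 5) {
  stopifnot(contrast_inst > contrast_eq, contrast_eq > 1, tau > 0)
  g <- function(T) ifelse(T <= 0, 1, (tau / T) * (1 - exp(-T / tau)))
  contrast <- function(duration) {
    contrast_eq + (contrast_inst - contrast_eq) * g(duration)
  }
  structure(list(contrast_inst = contrast_inst, contrast_eq = contrast_eq,
                 tau = tau, contrast = contrast,
                 center_strain = function(eps_out, duration) {
                   eps_out / contrast(duration)
                 }),
            class = "rate_model")
}

#' Rate-dependent inclusion field
#'
#' Convenience wrapper: builds an [make_inclusion_field()] whose
#' inside strain follows the [rate_model()] effective contrast for a
#' given loading duration.
#'
#' @param model a [rate_model()].
#' @param eps_out far-field strain.
#' @param duration loading duration in seconds.
#' @param ... passed to [make_inclusion_field()].
#' @return An `inclusion_field`.
#' @export
make_rate_dependent_field <- function(model = rate_model(), eps_out = 0.15,
                                      duration = 1.5, ...) {
  stopifnot(inherits(model, "rate_model"))
  make_inclusion_field(eps_out = eps_out,
                       eps_in = model$center_strain(eps_out, duration), ...)
}

#' Simulate a wound-healing time course
#'
#' Produces, for each measurement day, the visible-wound ellipse
#' geometry (shrinking over time) and an [make_inclusion_field()]
#' whose stiffness contrast evolves according to a supplied monotone
#' stiffening schedule — a synthetic stand-in for a longitudinal mouse
#' study, enabling end-to-end tests of [healing_rates()] and of
#' longitudinal deformability readouts.
#'
#' @param days measurement days post-injury.
#' @param visible_length_mm visible wound length (mm) per day; default
#'   an exponential contraction from 6 mm.
#' @param contrast stiffness contrast (eps_out / eps_in) per day; must
#'   be non-decreasing (monotone stiffening). Scalars are recycled.
#' @param eps_out applied far-field strain.
#' @param size sheet size (pixels).
#' @param scale mm per pixel.
#' @param seed integer seed (reserved for future stochastic variants;
#'   recorded in the output).
#' @return List of class `healing_course`: `days`, `geometry`
#'   (data.frame of per-day ellipse parameters), `fields` (list of
#'   inclusion fields), `visible_length_mm`, `contrast`.
#' @export
simulate_healing_course <- function(days = c(3, 5, 7, 10, 14, 21),
                                    visible_length_mm = NULL,
                                    contrast = NULL,
                                    eps_out = 0.10, size = 1000,
                                    scale = 0.03, seed = 1L) {
  stopifnot(length(days) >= 2, all(diff(days) > 0))
  n <- length(days)
  if (is.null(visible_length_mm)) {
    visible_length_mm <- 6 * exp(-0.12 * (days - days[1])) + 1.0
  }
  visible_length_mm <- rep_len(visible_length_mm, n)
  if (is.null(contrast)) contrast <- 2 + 0.25 * (days - days[1])
  contrast <- rep_len(contrast, n)
  if (any(diff(contrast) < 0)) {
    stop("the stiffening schedule (contrast) must be non-decreasing")
  }
  radius_px <- visible_length_mm / 2 / scale
  fields <- lapply(seq_len(n), function(i) {
    make_inclusion_field(size = size, radius = radius_px[i],
                         eps_out = eps_out,
                         eps_in = eps_out / contrast[i])
  })
  geometry <- data.frame(
    day = days,
    center_x = size / 2, center_y = size / 2,
    semi_major_px = radius_px, semi_minor_px = 0.8 * radius_px,
    visible_length_mm = visible_length_mm,
    visible_area_mm2 = pi * radius_px * 0.8 * radius_px * scale^2,
    eps_in = eps_out / contrast, eps_out = eps_out)
  structure(list(days = days, geometry = geometry, fields = fields,
                 visible_length_mm = visible_length_mm,
                 contrast = contrast, seed = as.integer(seed)),
            class = "healing_course")
}
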