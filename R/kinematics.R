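#' Inverse-distance weight scheme for local deformation-gradient fitting
#'
#' Weights neighboring tracking points by inverse distance with a hard
#' cutoff: a point at distance `d` pixels from the query location
#' receives weight `(d + 1)^-1` when `d < r_max` and 0 otherwise (the
#' cutoff is a strict inequality). The default cutoff of 100 px suits
#' the typical density of trackable contrast features on shaved skin at
#' 0.03 mm/px.
#'
#' @param r_max cutoff radius in pixels, > 0.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(r_max = 100) {
  if (!is.numeric(r_max) || length(r_max) != 1L || !is.finite(r_max) ||
      r_max <= 0) {
    stop("r_max must be a single positive number (pixels)")
  }
  structure(list(r_max = as.numeric(r_max)), class = "weight_scheme")
}

#' @rdname weight_scheme
#' @param distance non-negative distance(s) in pixels.
#' @param scheme a [weight_scheme()].
#' @return `point_weight`: weights in `[0, 1]`, vectorized over
#'   `distance`; strictly decreasing on `[0, r_max)` and identically 0
#'   beyond.
#' @examples
#' point_weight(0, weight_scheme(100))    # 1
#' point_weight(99, weight_scheme(100))   # 0.01
#' point_weight(100, weight_scheme(100))  # 0, strict cutoff
#' @export
point_weight <- function(distance, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("distance must be finite and >= 0")
  }
  ifelse(distance < scheme$r_max, 1 / (distance + 1), 0)
}

#' Estimate the local 2D deformation gradient by weighted least squares
#'
#' Fits the affine map `x = F X + c` from reference positions `X` to
#' deformed positions `x` over the tracking points within the weight
#' cutoff of a query location, minimizing the weighted sum of squared
#' residuals with weights from [point_weight()]. `F` is the local
#' deformation gradient at the query; the translation `c` absorbs rigid
#' motion so that it does not corrupt `F`. The fit is exact whenever
#' the true point motion is affine.
#'
#' @param ref a [point_set()] of reference positions.
#' @param def the matching [deformed_point_set()].
#' @param query length-2 numeric, the location (reference pixels) where
#'   the gradient is evaluated.
#' @param scheme a [weight_scheme()].
#' @return An object of class `deformation_gradient`: list with `F`
#'   (2 x 2 matrix), `translation` (length-2, pixels), `n_support`
#'   (number of points with nonzero weight) and `query`.
#' @examples
#' ref <- point_set(1:5, cbind(c(10, 50, 90, 30, 70), c(10, 80, 20, 60, 50)))
#' F0 <- matrix(c(1.1, 0, 0, 0.97), 2, 2)
#' def <- deformed_point_set(1:5, t(F0 %*% t(ref$xy)) + 3)
#' estimate_deformation_gradient(ref, def, c(50, 50))$F
#' @export
estimate_deformation_gradient <- function(ref, def, query,
                                          scheme = weight_scheme()) {
  def <- match_points(ref, def)
  query <- as.numeric(query)
  stopifnot(length(query) == 2L, all(is.finite(query)))
  d <- sqrt((ref$xy[, 1] - query[1])^2 + (ref$xy[, 2] - query[2])^2)
  w <- point_weight(d, scheme)
  sel <- w > 0
  if (sum(sel) < 3L) {
    stop(sprintf(
      "deformation-gradient estimation failed at query (%.1f, %.1f): only %d supported point(s), need >= 3",
      query[1], query[2], sum(sel)))
  }
  fit <- wls_affine(ref$xy[sel, , drop = FALSE], def$xy[sel, , drop = FALSE],
                    w[sel], query)
  if (is.null(fit)) {
    stop(sprintf(
      "deformation-gradient estimation failed at query (%.1f, %.1f): degenerate (collinear) point support",
      query[1], query[2]))
  }
  structure(list(F = fit$F, translation = fit$translation,
                 n_support = sum(sel), query = query),
            class = "deformation_gradient")
}

# Weighted affine fit x ~ F X + c. Reference coordinates are centered on
# the query for conditioning; F is shift-invariant, c is mapped back.
# Returns NULL on a rank-deficient / ill-conditioned normal matrix
# (condition number > 1e8).
wls_affine <- function(X, x, w, center) {
  Xc <- sweep(X, 2, center)
  A <- cbind(Xc, 1)
  AtW <- t(A * w)
  N <- AtW %*% A
  if (!all(is.finite(N)) || kappa(N, exact = TRUE) > 1e8) return(NULL)
  beta <- solve(N, AtW %*% x)        # 3 x 2; columns are output dims
  F <- t(beta[1:2, , drop = FALSE])  # rows: output x,y; cols: input X,Y
  c0 <- as.numeric(beta[3, ])        # fitted value at the query point
  # x = F (X - q) + c0  =>  x = F X + (c0 - F q)
  list(F = unname(F), translation = c0 - as.numeric(F %*% center))
}

#' Green-Lagrange strain tensor from a deformation gradient
#'
#' Computes `E = (F'F - I)/2` and its component along the extension
#' axis, `e' E e` for the unit axis vector `e`. `E` is invariant under
#' rigid rotations of the deformed configuration: it vanishes for any
#' rotation + translation.
#'
#' @param F a 2 x 2 deformation gradient matrix or a
#'   `deformation_gradient` object.
#' @param axis length-2 extension-axis vector (normalized internally);
#'   default `c(1, 0)`, the cranio-caudal image x axis.
#' @return An object of class `strain_tensor`: list with `E` (symmetric
#'   2 x 2) and `axial` (scalar `e' E e`).
#' @examples
#' green_lagrange(diag(c(1.1, 1)))$axial  # (1.1^2 - 1)/2 = 0.105
#' @export
green_lagrange <- function(F, axis = c(1, 0)) {
  if (inherits(F, "deformation_gradient")) F <- F$F
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(2L, 2L)))
  if (!all(is.finite(F))) stop("F must be finite")
  e <- normalize_axis(axis)
  E <- (t(F) %*% F - diag(2)) / 2
  E <- (E + t(E)) / 2  # enforce exact symmetry
  structure(list(E = unname(E), axial = as.numeric(t(e) %*% E %*% e)),
            class = "strain_tensor")
}

#' Green-Lagrange strain of a uniaxial stretch
#'
#' For a tissue stretch `lambda1` along the testing direction the
#' strain is `(lambda1^2 - 1)/2` — the axial Green-Lagrange component
#' of `diag(lambda1, 1)`, making ex vivo stretch readouts directly
#' comparable with the in vivo strain fields.
#'
#' @param lambda1 positive stretch ratio(s), deformed over reference
#'   length.
#' @return Green-Lagrange strain, same length as `lambda1`.
#' @examples
#' strain_from_stretch(1.1)  # 0.105
#' @export
strain_from_stretch <- function(lambda1) {
  if (any(!is.finite(lambda1)) || any(lambda1 <= 0)) {
    stop("lambda1 must be finite and > 0")
  }
  (lambda1^2 - 1) / 2
}

#' Global strain along the extension axis
#'
#' The overall applied strain level is the ordinary-least-squares slope
#' of the regression of axis-projected point displacements on
#' axis-projected reference positions: a homogeneous elongation
#' `u = eps * X` yields exactly `eps`, and any rigid translation yields
#' 0. Used to standardize measurements by identifying the frame at
#' which a prescribed global strain is reached.
#'
#' @inheritParams estimate_deformation_gradient
#' @param axis length-2 extension-axis vector.
#' @return The scalar slope (engineering strain, dimensionless).
#' @export
global_strain <- function(ref, def, axis = c(1, 0)) {
  def <- match_points(ref, def)
  e <- normalize_axis(axis)
  X <- as.numeric(ref$xy %*% e)
  u <- as.numeric((def$xy - ref$xy) %*% e)
  if (length(unique(X)) < 2L || var(X) == 0) {
    stop("degenerate regression: all reference positions project to the same axis coordinate")
  }
  as.numeric(sum((X - mean(X)) * (u - mean(u))) / sum((X - mean(X))^2))
}

normalize_axis <- function(axis) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 2L, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be a nonzero vector")
  axis / n
}

#' @export
print.deformation_gradient <- function(x, ...) {
  cat("<deformation_gradient>\n")
  print(round(x$F, 6))
  cat(sprintf("translation: (%.3f, %.3f) px, n_support: %d\n",
              x$translation[1], x$translation[2], x$n_support))
  invisible(x)
}

#' @export
print.strain_tensor <- function(x, ...) {
  cat("<strain_tensor> axial:", format(x$axial, digits = 6), "\n")
  print(round(x$E, 6))
  invisible(x)
}
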