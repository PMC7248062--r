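test_that("inverse-distance weights follow the cutoff formula", {
  ws <- weight_scheme(100)
  expect_equal(point_weight(0, ws), 1.0)
  expect_equal(point_weight(99, ws), 0.01)
  expect_equal(point_weight(100, ws), 0.0)  # strict cutoff at r_max
  expect_equal(point_weight(150, ws), 0.0)

  # strictly decreasing on [0, r_max), identically zero beyond
  d <- seq(0, 99.9, by = 0.1)
  w <- point_weight(d, ws)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(point_weight(seq(100, 500, by = 10), ws) == 0))

  expect_error(point_weight(-1, ws), "distance")
  expect_error(weight_scheme(0), "r_max")
})

test_that("affine deformations are recovered exactly, regardless of weights", {
  ref <- scatter_points(n = 50, extent = 150, seed = 11)
  F0 <- matrix(c(1.1, 0, 0, 0.97), 2, 2)
  def <- affine_deform(ref, F0, c(2, 1))
  for (r_max in c(60, 100, 1000)) {
    g <- estimate_deformation_gradient(ref, def, c(75, 75),
                                       weight_scheme(r_max))
    expect_lt(max(abs(g$F - F0)), 1e-10)
  }

  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    F0 <- random_affine()
    c0 <- runif(2, -20, 20)
    def <- affine_deform(ref, F0, c0)
    g <- estimate_deformation_gradient(ref, def, runif(2, 20, 130))
    worst <- max(worst, max(abs(g$F - F0)))
  }
  expect_lt(worst, 1e-9)
})

test_that("rigid translation yields identity gradient and the translation", {
  ref <- scatter_points(n = 30, extent = 120, seed = 3)
  def <- affine_deform(ref, diag(2), c(5, -3))
  g <- estimate_deformation_gradient(ref, def, c(60, 60))
  expect_lt(max(abs(g$F - diag(2))), 1e-10)
  expect_equal(g$translation, c(5, -3), tolerance = 1e-10)
  expect_gte(g$n_support, 3)
})

test_that("degenerate support is rejected with the query identified", {
  # 10 points on a single line
  ref <- point_set(1:10, cbind(seq(10, 100, by = 10), seq(10, 100, by = 10)))
  def <- deformed_point_set(1:10, ref$xy * 1.05)
  expect_error(estimate_deformation_gradient(ref, def, c(55, 55)),
               "collinear")
  # fewer than 3 supported neighbors
  ref2 <- scatter_points(n = 30, extent = 400, seed = 5)
  def2 <- affine_deform(ref2, diag(2))
  expect_error(
    estimate_deformation_gradient(ref2, def2, c(-500, -500),
                                  weight_scheme(10)),
    "supported point")
})

test_that("Green-Lagrange strain has the closed form and is objective", {
  expect_equal(green_lagrange(diag(2))$E, matrix(0, 2, 2))
  st <- green_lagrange(diag(c(1.1, 1.0)), axis = c(1, 0))
  expect_equal(st$axial, (1.1^2 - 1) / 2)
  expect_equal(st$E[2, 2], 0)
  expect_true(isSymmetric(st$E))

  # axial component equals the axis projection e' E e for oblique axes
  F <- matrix(c(1.08, 0.03, -0.02, 0.95), 2, 2)
  e <- c(1, 2) / sqrt(5)
  st2 <- green_lagrange(F, e)
  expect_equal(st2$axial, as.numeric(t(e) %*% st2$E %*% e))

  # objectivity: zero tensor for 100 random rigid motions
  set.seed(31)
  for (i in 1:100) {
    expect_lt(max(abs(green_lagrange(random_rotation())$E)), 1e-12)
  }
})

test_that("stretch-based strain matches the axial Green-Lagrange component", {
  expect_equal(strain_from_stretch(1), 0)
  expect_equal(strain_from_stretch(1.1), 0.105)
  expect_equal(strain_from_stretch(1.05), 0.05125)
  expect_error(strain_from_stretch(0), "lambda1")
  expect_error(strain_from_stretch(-1), "lambda1")

  lams <- c(0.9, 1, 1.02, 1.1, 1.3)
  ax <- vapply(lams,
               function(l) green_lagrange(diag(c(l, 1)))$axial, numeric(1))
  expect_equal(strain_from_stretch(lams), ax)
})

test_that("global strain is the displacement-position regression slope", {
  ref <- scatter_points(n = 60, extent = 500, seed = 8)
  # exact linear field u = 0.1 X
  def <- deformed_point_set(ref$ids, cbind(ref$xy[, 1] * 1.1, ref$xy[, 2]))
  expect_equal(global_strain(ref, def), 0.1, tolerance = 1e-12)
  # rigid translation: zero slope
  def_t <- affine_deform(ref, diag(2), c(7, 2))
  expect_equal(global_strain(ref, def_t), 0, tolerance = 1e-12)

  # noisy linear field: OLS slope sd is sigma / sqrt(sum((X - Xbar)^2));
  # for 200 points over 1000 px and sigma 0.5 px that is ~1.2e-4, so
  # 0.01 is a > 50-sigma band
  set.seed(13)
  X <- runif(200, 0, 1000)
  refn <- point_set(1:200, cbind(X, runif(200, 0, 1000)))
  defn <- deformed_point_set(1:200,
                             cbind(X * 1.1 + rnorm(200, 0, 0.5), refn$xy[, 2]))
  expect_equal(global_strain(refn, defn), 0.1, tolerance = 0.01)

  # degenerate: all points at the same axis coordinate
  refd <- point_set(1:3, cbind(c(5, 5, 5), c(1, 2, 3)))
  defd <- deformed_point_set(1:3, refd$xy)
  expect_error(global_strain(refd, defd), "degenerate")
})

test_that("engineering and Green-Lagrange measures agree as expected on a homogeneous stretch", {
  lam <- 1.07
  ref <- scatter_points(n = 40, extent = 300, seed = 17)
  def <- affine_deform(ref, diag(c(lam, 1)))
  eng <- global_strain(ref, def)             # lambda - 1
  gl <- green_lagrange(
    estimate_deformation_gradient(ref, def, c(150, 150))$F)$axial
  expect_equal(eng, lam - 1, tolerance = 1e-10)
  expect_equal(gl, strain_from_stretch(lam), tolerance = 1e-10)
  expect_equal(gl, eng + eng^2 / 2, tolerance = 1e-10)
})

test_that("point sets validate their invariants", {
  expect_error(point_set(c(1, 1), cbind(c(0, 1), c(0, 1))), "unique")
  expect_error(point_set(1:2, cbind(c(-1, 1), c(0, 1))), "finite")
  expect_error(point_set(1:2, cbind(c(0, 1), c(0, 1)), scale = 0), "scale")
  ref <- point_set(1:3, cbind(1:3, 1:3))
  expect_error(
    estimate_deformation_gradient(
      ref, deformed_point_set(4:6, cbind(1:3, 1:3)), c(1, 1)),
    "same ids")
})
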