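# analytic trajectory table: u = rate_per_frame * k * X along x
ramp_trajectories <- function(n_frames = 16, rate = 0.01, n_pts = 30,
                              extent = 400, seed = 4) {
  set.seed(seed)
  X <- cbind(runif(n_pts, 0, extent), runif(n_pts, 0, extent))
  do.call(rbind, lapply(0:(n_frames - 1), function(k) {
    data.frame(id = seq_len(n_pts), frame = k,
               x = X[, 1] * (1 + rate * k), y = X[, 2])
  }))
}

test_that("frame selection finds the first frame at the target strain", {
  traj <- ramp_trajectories(n_frames = 16, rate = 0.01)
  sel <- select_frame_at_global_strain(traj, target = 0.10)
  expect_equal(sel$frame, 11)          # strains 0, 0.01, ..., 0.15
  expect_equal(sel$achieved, 0.10, tolerance = 1e-10)
  expect_equal(select_frame_at_global_strain(traj, target = 0)$frame, 1)
  expect_error(
    select_frame_at_global_strain(ramp_trajectories(n_frames = 9),
                                  target = 0.10),
    "never reached")
})

test_that("strain fields reproduce homogeneous and rigid deformations", {
  ref <- scatter_points(n = 60, extent = 300, seed = 19)
  def <- affine_deform(ref, diag(c(1.1, 1)))
  sf <- compute_strain_field(ref, def, scheme = weight_scheme(150))
  expect_equal(nrow(sf$points), 60)
  expect_equal(sf$points$axial, rep(0.105, 60), tolerance = 1e-10)

  set.seed(23)
  rig <- affine_deform(ref, random_rotation(), c(4, -2))
  sf_r <- compute_strain_field(ref, rig, scheme = weight_scheme(150))
  expect_lt(max(abs(sf_r$points$axial)), 1e-10)
  expect_lt(max(abs(sf_r$points$E12)), 1e-10)

  # per-point failures are collected, not fatal
  ref2 <- point_set(1:8, cbind(c(1:4 * 10, 200, 210, 205, 215),
                               c(1:4 * 10, 200, 210, 215, 205)))
  def2 <- affine_deform(ref2, diag(c(1.05, 1)))
  sf2 <- compute_strain_field(ref2, def2, scheme = weight_scheme(30))
  expect_equal(nrow(sf2$points) + nrow(sf2$failed), 8)
})

test_that("wound-region strain averages the field inside the ROI", {
  ref <- scatter_points(n = 80, extent = 300, seed = 29)
  def <- affine_deform(ref, diag(c(1.1, 1)))
  sf <- compute_strain_field(ref, def, scheme = weight_scheme(150))
  roi <- list(type = "rect", x0 = 50, x1 = 250, y0 = 50, y1 = 250)
  expect_equal(wound_region_strain(sf, roi), 0.105, tolerance = 1e-10)
  roi_e <- list(type = "ellipse", cx = 150, cy = 150, a = 100, b = 80)
  expect_equal(wound_region_strain(sf, roi_e), 0.105, tolerance = 1e-10)
  expect_error(
    wound_region_strain(sf, list(type = "rect", x0 = 1000, x1 = 1100,
                                 y0 = 0, y1 = 10)),
    "inside")
})

test_that("deformability ratio guards the denominator", {
  expect_equal(deformability_ratio(0.09, 0.05), 1.8)
  expect_equal(deformability_ratio(0.07, 0.07), 1.0)
  expect_error(deformability_ratio(0.05, 0), "nonzero")
})

test_that("functional wound length recovers constructed breakpoints", {
  # continuous piecewise profile: slopes 0.1 / 0.02 / 0.1, flat-ish
  # middle of width 300 px between 350 and 650
  set.seed(37)
  n <- 240
  X <- runif(n, 0, 1000)
  T_ <- runif(n, 200, 300)
  b1 <- 350; b2 <- 650
  u <- 0.1 * X + (0.02 - 0.1) * (pmax(X - b1, 0) - pmax(X - b2, 0))
  ref <- point_set(1:n, cbind(X, T_))
  def <- deformed_point_set(1:n, cbind(X + u, T_))
  fl <- functional_wound_length(ref, def,
                                strip = list(center = 250, width = 100),
                                n_candidates = 80)
  expect_true(fl$detected)
  expect_lt(abs(fl$functional_length_mm - 9.0), 0.3)
  expect_lt(abs(fl$inside_slope - 0.02), 0.01)
  expect_lt(max(abs(fl$outside_slopes - 0.1)), 0.01)

  # homogeneous deformation: no mechanically distinct wound
  u_h <- 0.1 * X
  def_h <- deformed_point_set(1:n, cbind(X + u_h, T_))
  fl_h <- functional_wound_length(ref, def_h,
                                  strip = list(center = 250, width = 100))
  expect_false(fl_h$detected)
  expect_equal(fl_h$functional_length_mm, 0)
})

test_that("functional length covers the inclusion on synthetic wounds", {
  # analytic displacement (generator ground truth), 20 random draws
  set.seed(41)
  for (i in 1:20) {
    radius <- runif(1, 50, 100)
    band <- runif(1, 20, 50)
    eps_out <- runif(1, 0.08, 0.12)
    eps_in <- runif(1, 0.01, 0.04)
    fld <- make_inclusion_field(size = 500, radius = radius, band = band,
                                eps_out = eps_out, eps_in = eps_in)
    n <- 300
    xy <- cbind(runif(n, 5, 495), runif(n, 5, 495))
    ref <- point_set(1:n, xy)
    def <- deformed_point_set(1:n, xy + fld$displacement(xy))
    fl <- functional_wound_length(ref, def,
                                  strip = list(center = 250, width = 100),
                                  n_candidates = 60)
    expect_true(fl$detected)
    expect_gte(fl$functional_length_mm, 2 * radius * 0.03)
  }
})

test_that("ellipse fitting matches closed-form circle and ellipse geometry", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(500 + 100 * cos(th), 480 + 100 * sin(th))
  g <- fit_wound_ellipse(circ)
  expect_equal(g$area_mm2, pi * 9, tolerance = 1e-6)
  expect_equal(g$visible_length_mm, 6.0, tolerance = 1e-6)
  expect_equal(g$center, c(500, 480), tolerance = 1e-6)

  ell <- cbind(300 + 150 * cos(th), 300 + 75 * sin(th))
  g2 <- fit_wound_ellipse(ell)
  expect_equal(g2$visible_length_mm, 9.0, tolerance = 1e-6)
  expect_equal(g2$area_mm2, pi * 150 * 75 * 0.03^2, tolerance = 1e-6)
  expect_equal(g2$semi_axes, c(150, 75), tolerance = 1e-6)

  # rotated ellipse: the axis-projected extent shrinks accordingly
  phi <- pi / 6
  rot <- cbind(300 + 150 * cos(th) * cos(phi) - 75 * sin(th) * sin(phi),
               300 + 150 * cos(th) * sin(phi) + 75 * sin(th) * cos(phi))
  g3 <- fit_wound_ellipse(rot)
  ext <- 2 * sqrt((150 * cos(phi))^2 + (75 * sin(phi))^2) * 0.03
  expect_equal(g3$visible_length_mm, ext, tolerance = 1e-6)

  expect_error(fit_wound_ellipse(cbind(1:5, 2 * (1:5))), "collinear|ellipse")
  expect_error(fit_wound_ellipse(circ[1:4, ]), ">= 5")
})

test_that("mask contours feed the ellipse fit", {
  mask <- matrix(0, 200, 200)
  for (r in 1:200) for (c in 1:200) {
    if (((c - 100) / 60)^2 + ((r - 90) / 40)^2 <= 1) mask[r, c] <- 1
  }
  mask[5:10, 5:10] <- 1  # small spurious component, must be ignored
  ct <- mask_to_contour(mask)
  g <- fit_wound_ellipse(ct)
  expect_equal(g$center, c(99.5, 89.5), tolerance = 1.5)
  expect_equal(g$semi_axes, c(60, 40), tolerance = 1.5)
  expect_error(mask_to_contour(matrix(0, 10, 10)), "empty")
})

test_that("healing rates implement the uneven-grid central difference", {
  days <- c(3, 5, 7, 10, 14, 21)
  # exact for quadratics at interior points
  set.seed(43)
  for (i in 1:25) {
    abc <- runif(3, -2, 2)
    t <- sort(runif(6, 0, 30))
    while (min(diff(t)) < 1e-3) t <- sort(runif(6, 0, 30))
    f <- abc[1] * t^2 + abc[2] * t + abc[3]
    hs <- healing_rates(healing_series(t, f))
    expect_equal(hs$rates[2:5], 2 * abc[1] * t[2:5] + abc[2],
                 tolerance = 1e-10)
  }
  hs_d <- healing_rates(healing_series(days, days^2))
  expect_equal(hs_d$rates[2:5], 2 * days[2:5], tolerance = 1e-12)

  # constant series, linear two-point case, endpoint formulas
  expect_equal(healing_rates(healing_series(days, rep(5, 6)))$rates,
               rep(0, 6))
  hs2 <- healing_rates(healing_series(c(3, 5), c(3, 5)))
  expect_equal(hs2$rates, c(1, 1))
  hs3 <- healing_rates(healing_series(days, 2 * days + 1))
  expect_equal(hs3$rates, rep(2, 6), tolerance = 1e-12)

  expect_error(healing_series(c(3, 3, 5), 1:3), "strictly increasing")
  expect_error(healing_series(3, 1), ">= 2")
})

test_that("wound strain scales with the applied deformation (5% vs 10%)", {
  # analytic fields at two global strain levels with the same material
  # contrast: the inside/outside deformability ratio is invariant
  contrast <- 5
  get_ratio <- function(eps_out) {
    fld <- make_inclusion_field(size = 500, radius = 60, band = 30,
                                eps_out = eps_out,
                                eps_in = eps_out / contrast)
    set.seed(47)
    xy <- cbind(runif(400, 10, 490), runif(400, 10, 490))
    ref <- point_set(1:400, xy)
    def <- deformed_point_set(1:400, xy + fld$displacement(xy))
    sf <- compute_strain_field(ref, def, scheme = weight_scheme(60))
    inside <- wound_region_strain(sf, list(type = "rect", x0 = 220,
                                           x1 = 280, y0 = 220, y1 = 280))
    outside <- wound_region_strain(sf, list(type = "rect", x0 = 30,
                                            x1 = 120, y0 = 30, y1 = 470))
    c(inside = inside, outside = outside)
  }
  r5 <- get_ratio(0.05)
  r10 <- get_ratio(0.10)
  # doubling the load doubles the wound strain in the linear regime
  expect_equal(r10[["inside"]] / r5[["inside"]], 2, tolerance = 0.05)
  ratio5 <- r5[["inside"]] / r5[["outside"]]
  ratio10 <- r10[["inside"]] / r10[["outside"]]
  expect_equal(ratio5, ratio10, tolerance = 0.05)
})
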