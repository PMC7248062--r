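# Shared fixtures, generated in code. The rendered speckle simulations
# are cached per session because several test files exercise the same
# render -> track chain.

.fixture_cache <- new.env(parent = emptyenv())

# scattered, non-collinear reference point cloud
scatter_points <- function(n = 40, extent = 400, seed = 1, scale = 0.03) {
  set.seed(seed)
  point_set(seq_len(n),
            cbind(runif(n, 0, extent), runif(n, 0, extent)),
            scale = scale)
}

# apply an exact affine map x = F X + shift to a point set
affine_deform <- function(ref, F, shift = c(0, 0)) {
  deformed_point_set(ref$ids, t(F %*% t(ref$xy) + shift))
}

random_rotation <- function() {
  th <- runif(1, 0, 2 * pi)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# random invertible F with positive determinant, moderate distortion
random_affine <- function() {
  repeat {
    F <- diag(2) + matrix(runif(4, -0.15, 0.15), 2, 2)
    if (det(F) > 0.5) return(F)
  }
}

# tracked simulation of the standard inclusion sheet at a given
# far-field strain; cached by (eps_out, seed)
tracked_inclusion_sim <- function(eps_out = 0.10, seed = 7,
                                  size = 500, radius = 60, band = 30,
                                  contrast = 5, noise_sigma = 0.02,
                                  n_frames = 6, max_points = 300) {
  key <- paste("sim", eps_out, seed, size, radius, band, contrast,
               noise_sigma, n_frames, max_points, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fld <- make_inclusion_field(size = size, radius = radius, band = band,
                              eps_out = eps_out,
                              eps_in = eps_out / contrast)
  sim <- render_speckle_sequence(fld, n_frames = n_frames,
                                 noise_sigma = noise_sigma, seed = seed)
  pts <- detect_fiducial_points(sim$seq$frames[[1]], min_spacing = 15,
                                max_points = max_points,
                                exclude_border = eps_out * size / 2 + 15)
  traj <- track_points(sim$seq, pts)
  out <- list(field = fld, sim = sim, points = pts, traj = traj)
  .fixture_cache[[key]] <- out
  out
}
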