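# Independent geometric oracles and shared fixtures for the test suite.

# radius at which a ray from `ctr` along `dir` meets the half-ellipsoid
# surface with short semi-axis A, long semi-axis C, base-plane centre
# (0, 0, z_base) -- outer root of the quadratic
ray_ellipsoid_r <- function(ctr, dir, A, C, z_base) {
  o <- ctr - c(0, 0, z_base)
  aa <- (dir[1]^2 + dir[2]^2) / A^2 + dir[3]^2 / C^2
  bb <- 2 * ((o[1] * dir[1] + o[2] * dir[2]) / A^2 + o[3] * dir[3] / C^2)
  cc <- (o[1]^2 + o[2]^2) / A^2 + o[3]^2 / C^2 - 1
  disc <- bb^2 - 4 * aa * cc
  if (disc < 0) return(NA_real_)
  (-bb + sqrt(disc)) / (2 * aa)
}

# spherical count shell with a Gaussian radial profile, centred in the grid
gaussian_shell_grid <- function(R = 30, sigma = 5, n = 80, voxel = 2) {
  co <- (seq_len(n) - (n + 1) / 2) * voxel
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  counts <- exp(-(sqrt(r2) - R)^2 / (2 * sigma^2))
  voxel_grid(counts, voxel)
}

# small, fast phantom used by unit tests (not the acceptance conditions)
quick_spec <- function(edv = 100, esv = 40, ...) {
  phantom_spec(edv, esv, n_frames = 4, grid_shape = 48, voxel_size = 4,
               psf_fwhm = 8, total_counts = 0, ...)
}

quick_params <- function(...) edge_params(n_theta = 24, n_phi = 48, ...)

# circular contour polygon
circle_xy <- function(r, n = 72) {
  ang <- (seq_len(n) - 1) / n * 2 * pi
  cbind(r * cos(ang), r * sin(ang))
}
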