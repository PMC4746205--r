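#' Voxel grid container
#'
#' A 3-D array of non-negative counts on a regular lattice with millimetre
#' spacing. Axes are ordered (x, y, z) with the left-ventricular long axis
#' nominally along +z and the base at high z; coordinates refer to voxel
#' centres.
#'
#' @param counts numeric 3-D array of non-negative values.
#' @param voxel_size voxel edge length in mm, scalar or length-3.
#' @param origin mm coordinates of the centre of voxel (1,1,1). Defaults to
#'   placing the grid centre at the coordinate origin.
#' @return an object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(counts, voxel_size,
                       origin = -(dim(counts) - 1) / 2 * rep(voxel_size, length.out = 3)) {
  if (length(dim(counts)) != 3L)
    stop("'counts' must be a 3-D array")
  if (any(counts < 0))
    stop("counts must be non-negative")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0))
    stop("voxel_size must be positive")
  structure(list(counts = counts, voxel_size = voxel_size,
                 origin = rep(as.numeric(origin), length.out = 3)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  total counts %.4g, max %.4g\n", sum(x$counts), max(x$counts)))
  invisible(x)
}

# mm coordinates of all voxel centres along axis k
.axis_coords <- function(grid, k) {
  grid$origin[k] + (seq_len(dim(grid$counts)[k]) - 1) * grid$voxel_size[k]
}

# Trilinear interpolation of grid counts at mm points (n x 3 matrix).
# outside = "zero": points outside the lattice hull evaluate to 0;
# outside = "clamp": coordinates are clamped to the hull first.
# Returns list(values, inside) where inside flags points within the hull.
.interp3 <- function(grid, pts, outside = c("zero", "clamp")) {
  outside <- match.arg(outside)
  d <- dim(grid$counts)
  u <- sweep(sweep(pts, 2, grid$origin), 2, grid$voxel_size, "/") + 1
  inside <- u[, 1] >= 1 & u[, 1] <= d[1] &
            u[, 2] >= 1 & u[, 2] <= d[2] &
            u[, 3] >= 1 & u[, 3] <= d[3]
  if (outside == "clamp")
    for (k in 1:3) u[, k] <- pmin(pmax(u[, k], 1), d[k])
  i0 <- floor(u)
  fr <- u - i0
  cl <- function(i, k) pmin(pmax(i, 1), d[k])
  x0 <- cl(i0[, 1], 1); x1 <- cl(i0[, 1] + 1, 1)
  y0 <- cl(i0[, 2], 2); y1 <- cl(i0[, 2] + 1, 2)
  z0 <- cl(i0[, 3], 3); z1 <- cl(i0[, 3] + 1, 3)
  v <- grid$counts
  at <- function(i, j, k) v[cbind(i, j, k)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
  c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
  c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
  c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
  out <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz
  if (outside == "zero") out[!inside] <- 0
  list(values = out, inside = inside)
}

# Dense banded Gaussian convolution matrix (zero-padded boundaries).
.gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    K[i, j[keep]] <- k[keep]
  }
  K
}

# Separable isotropic Gaussian blur of a 3-D array; sigma_vox per axis.
.blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (sigma_vox[1] > 0)
    arr <- array(.gauss_kernel_matrix(d[1], sigma_vox[1]) %*% matrix(arr, d[1]), d)
  if (sigma_vox[2] > 0) {
    a2 <- aperm(arr, c(2, 1, 3))
    a2 <- array(.gauss_kernel_matrix(d[2], sigma_vox[2]) %*% matrix(a2, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a2, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    a3 <- aperm(arr, c(3, 2, 1))
    a3 <- array(.gauss_kernel_matrix(d[3], sigma_vox[3]) %*% matrix(a3, d[3]), c(d[3], d[2], d[1]))
    arr <- aperm(a3, c(3, 2, 1))
  }
  arr
}

# Average-pool a supersampled array by integer factor ss along every axis.
.pool3 <- function(arr, ss) {
  if (ss == 1L) return(arr)
  pool1 <- function(a) {
    d <- dim(a)
    colMeans(array(a, c(ss, d[1] / ss, d[2], d[3])))
  }
  arr <- pool1(arr)
  arr <- aperm(pool1(aperm(arr, c(2, 1, 3))), c(2, 1, 3))
  aperm(pool1(aperm(arr, c(3, 2, 1))), c(3, 2, 1))
}
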