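#' Sampling-ray grid over the left ventricle
#'
#' Radial sampling geometry for surface fitting and edge detection: rays
#' emanate from a centre on the long axis, parameterised by the polar angle
#' theta measured from the apex direction (0 = apex, pi/2 = equator,
#' larger values tilt toward the base) and the azimuth phi measured from the
#' anterior reference direction. Cell centres are used for radii and exact
#' cell solid angles for quadrature, so spherical-sector volume summation is
#' second-order accurate.
#'
#' @param center mm point on the long axis from which rays emanate.
#' @param axis unit direction of the long axis, pointing toward the base.
#' @param n_theta number of apex-to-base samples (at least 8).
#' @param n_phi number of circumferential samples (at least 8).
#' @param theta_max maximal polar angle, radians; the default 5*pi/6 (150 degrees) extends
#'   well past the equator so the basal wall and rim up to the valve plane
#'   are sampled even from a mid-cavity centre.
#' @param anterior anterior reference direction in grid coordinates; its
#'   component orthogonal to \code{axis} defines phi = 0.
#' @return an object of class \code{ray_grid}.
#' @export
ray_grid <- function(center, axis = c(0, 0, 1), n_theta = 32, n_phi = 64,
                     theta_max = 5 * pi / 6, anterior = c(0, 1, 0)) {
  if (n_theta < 8 || n_phi < 8) stop("sample counts must be at least 8")
  if (theta_max <= 0 || theta_max > pi) stop("theta_max must lie in (0, pi]")
  axis <- axis / sqrt(sum(axis^2))
  apex_dir <- -axis
  e1 <- anterior - sum(anterior * axis) * axis
  if (sqrt(sum(e1^2)) < 1e-8) {
    alt <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- alt - sum(alt * axis) * axis
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(apex_dir[2] * e1[3] - apex_dir[3] * e1[2],
          apex_dir[3] * e1[1] - apex_dir[1] * e1[3],
          apex_dir[1] * e1[2] - apex_dir[2] * e1[1])
  theta_edges <- seq(0, theta_max, length.out = n_theta + 1)
  theta <- (theta_edges[-1] + theta_edges[-(n_theta + 1)]) / 2
  dphi <- 2 * pi / n_phi
  phi <- (seq_len(n_phi) - 0.5) * dphi
  domega <- (cos(theta_edges[-(n_theta + 1)]) - cos(theta_edges[-1])) * dphi
  ct <- cos(theta); st <- sin(theta)
  # directions, (n_theta x n_phi) cells flattened column-major
  dirs <- matrix(0, n_theta * n_phi, 3)
  for (j in seq_len(n_phi)) {
    lat <- cos(phi[j]) * e1 + sin(phi[j]) * e2
    idx <- (j - 1) * n_theta + seq_len(n_theta)
    dirs[idx, ] <- outer(ct, apex_dir) + st %o% lat
  }
  structure(list(center = as.numeric(center), axis = axis,
                 apex_dir = apex_dir, e1 = e1, e2 = e2,
                 n_theta = n_theta, n_phi = n_phi,
                 theta = theta, theta_edges = theta_edges, phi = phi,
                 dirs = dirs, domega = domega),
            class = "ray_grid")
}

#' @export
print.ray_grid <- function(x, ...) {
  cat(sprintf("<ray_grid> %d theta x %d phi rays, theta up to %.1f deg\n",
              x$n_theta, x$n_phi, max(x$theta_edges) * 180 / pi))
  cat(sprintf("  center (%.1f, %.1f, %.1f) mm, axis (%.2f, %.2f, %.2f)\n",
              x$center[1], x$center[2], x$center[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# mm points at radii r (vector over cells, recycled) along every ray
.ray_points <- function(grid, r) {
  grid$dirs * r + matrix(grid$center, nrow(grid$dirs), 3, byrow = TRUE)
}

# 3x3 box smoothing of a (theta x phi) radius field; phi wraps,
# theta rows are replicated at the apex/base edges
.smooth_grid <- function(m, passes) {
  if (passes <= 0) return(m)
  nt <- nrow(m)
  for (p in seq_len(passes)) {
    up <- m[c(1, seq_len(nt - 1)), , drop = FALSE]
    dn <- m[c(seq_len(nt - 1) + 1, nt), , drop = FALSE]
    vert <- (up + m + dn)
    left <- vert[, c(ncol(m), seq_len(ncol(m) - 1)), drop = FALSE]
    right <- vert[, c(seq_len(ncol(m) - 1) + 1, 1), drop = FALSE]
    m <- (left + vert + right) / 9
  }
  m
}

#' Cavity volume enclosed by a radial surface and the valve plane
#'
#' Spherical-sector summation: the volume is the integral of r^3/3 over
#' solid angle, with each ray's radius clipped at the valve plane. Beyond
#' the grid's maximal polar angle the radius field is extended to the full
#' sphere (last-ring padding) so that the basal region bounded by the valve
#' plane is integrated; there the plane itself dominates the clip. The
#' quadrature converges at second order in the angular step.
#'
#' @param endo_r radius field, mm, (n_theta x n_phi) matrix over \code{grid}.
#' @param grid a [ray_grid()].
#' @param valve_plane list with \code{point} (mm) and \code{normal} (unit,
#'   base-ward); the cavity lies on the apex side of the plane.
#' @return volume in ml.
#' @export
cavity_volume <- function(endo_r, grid, valve_plane) {
  stopifnot(inherits(grid, "ray_grid"))
  r <- as.vector(endo_r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("radii must be finite and positive")
  n <- valve_plane$normal / sqrt(sum(valve_plane$normal^2))
  h <- sum((valve_plane$point - grid$center) * n)
  clip_sum <- function(dirs, rr, dom_full) {
    dn <- as.vector(dirs %*% n)
    rc <- ifelse(dn > 1e-12, pmin(rr, pmax(h / dn, 0)),
                 if (h >= 0) rr else 0)
    rc <- ifelse(dn <= 1e-12 & h < 0, 0, rc)
    sum(rc^3 / 3 * dom_full)
  }
  dom <- rep(grid$domega, grid$n_phi)
  v <- clip_sum(grid$dirs, r, dom)
  # extension rings theta_max..pi with last-ring radii
  tmax <- max(grid$theta_edges)
  if (tmax < pi - 1e-9) {
    dth <- diff(grid$theta_edges[1:2])
    edges <- unique(c(seq(tmax, pi, by = dth), pi))
    if (length(edges) > 1) {
      th <- (edges[-1] + edges[-length(edges)]) / 2
      dom_e <- (cos(edges[-length(edges)]) - cos(edges[-1])) * 2 * pi / grid$n_phi
      ct <- cos(th); st <- sin(th)
      r_last <- endo_r[grid$n_theta, ]
      dirs_e <- matrix(0, length(th) * grid$n_phi, 3)
      for (j in seq_len(grid$n_phi)) {
        lat <- cos(grid$phi[j]) * grid$e1 + sin(grid$phi[j]) * grid$e2
        idx <- (j - 1) * length(th) + seq_along(th)
        dirs_e[idx, ] <- outer(ct, grid$apex_dir) + st %o% lat
      }
      rr_e <- rep(r_last, each = length(th))
      v <- v + clip_sum(dirs_e, rr_e, rep(dom_e, grid$n_phi))
    }
  }
  v / 1000
}
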