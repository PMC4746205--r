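#' Edge-detection parameters
#'
#' @param threshold_fraction fraction of the per-profile maximal count at
#'   which the endocardial and epicardial edges are placed (default 0.75).
#' @param mode \code{"fixed"} for threshold detection alone, or
#'   \code{"volume_corrected"} to additionally shift both detected surfaces
#'   in the epicardial direction by the volume-dependent amount given by the
#'   [shift_model()].
#' @param profile_step sampling step along each profile, mm.
#' @param smoothing_passes neighbour-smoothing passes applied to the fitted
#'   mid-surface radii.
#' @param search_halfwidth half-width of the wall-search window around the
#'   mid surface, mm; restricts the per-profile maximum so adjacent
#'   extra-cardiac activity is not captured.
#' @param n_theta,n_phi,theta_max ray-grid resolution, see [ray_grid()].
#' @return an object of class \code{edge_params}.
#' @export
edge_params <- function(threshold_fraction = 0.75,
                        mode = c("fixed", "volume_corrected"),
                        profile_step = 1, smoothing_passes = 2,
                        search_halfwidth = 25,
                        n_theta = 32, n_phi = 64, theta_max = 5 * pi / 6) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly between 0 and 1")
  if (profile_step <= 0) stop("profile_step must be positive")
  structure(list(threshold_fraction = threshold_fraction,
                 mode = match.arg(mode), profile_step = profile_step,
                 smoothing_passes = smoothing_passes,
                 search_halfwidth = search_halfwidth,
                 n_theta = n_theta, n_phi = n_phi, theta_max = theta_max),
            class = "edge_params")
}

# count-weighted centroid and principal axis of voxels above 50% of max;
# the axis is oriented base-ward: the closed apical cap crosses the axis
# line, so the direction with the lower far-field on-axis count is basal
.init_center_axis <- function(frame) {
  v <- frame$counts
  m <- max(v)
  if (!is.finite(m) || m <= 0) stop("empty field: no counts above threshold")
  idx <- which(v >= 0.5 * m, arr.ind = TRUE)
  w <- v[v >= 0.5 * m]
  xyz <- cbind(.axis_coords(frame, 1)[idx[, 1]],
               .axis_coords(frame, 2)[idx[, 2]],
               .axis_coords(frame, 3)[idx[, 3]])
  ctr <- colSums(xyz * w) / sum(w)
  d <- sweep(xyz, 2, ctr)
  cv <- crossprod(d * sqrt(w)) / sum(w)
  vecs <- eigen(cv, symmetric = TRUE)$vectors
  # the long axis is the principal direction of maximal count asymmetry:
  # the closed apical cap skews the distribution along it, while the shell
  # is symmetric transversally (variance alone cannot tell them apart for
  # hearts as wide as they are long)
  skew <- apply(vecs, 2, function(v) {
    p <- d %*% v
    abs(sum(w * p^3) / sum(w)) / (sum(w * p^2) / sum(w))^1.5
  })
  ax <- vecs[, which.max(skew)]
  ext <- max(abs(d %*% ax))
  s <- seq(0.4, 1.1, by = 0.05) * ext
  probe <- function(dir) {
    pts <- matrix(ctr, length(s), 3, byrow = TRUE) + s %o% dir
    max(.interp3(frame, pts)$values)
  }
  if (probe(ax) > probe(-ax)) ax <- -ax  # high far count = apex cap
  list(center = ctr, axis = ax)
}

#' Fit the mid-myocardial surface to one frame
#'
#' The centre and long axis are initialised from the count-weighted centroid
#' and principal axis of voxels above 50% of the global maximum; per-ray
#' mid-surface radii are set to the count maximum along each ray, smoothed
#' over neighbouring rays, and the centre is iteratively updated to the mean
#' of the surface points until it moves less than half a voxel (at most 20
#' iterations, with a warning on non-convergence). Deterministic for fixed
#' input.
#'
#' @param frame a [voxel_grid()] containing one connected high-count
#'   structure.
#' @param init optional list with \code{center} and \code{axis} to skip the
#'   automatic initialisation.
#' @param params an [edge_params()] supplying grid resolution and smoothing.
#' @return list with elements \code{grid} (a [ray_grid()]) and \code{mid_r}
#'   (n_theta x n_phi matrix of radii, mm).
#' @export
fit_mid_surface <- function(frame, init = NULL, params = edge_params()) {
  stopifnot(inherits(frame, "voxel_grid"))
  ia <- if (is.null(init)) .init_center_axis(frame) else init
  center <- ia$center; axis <- ia$axis
  step <- min(frame$voxel_size) / 2
  r_max <- max(dim(frame$counts) * frame$voxel_size) / 2
  r_samp <- seq(step, r_max, by = step)
  tol <- 0.5 * min(frame$voxel_size)
  grid <- NULL; mid_r <- NULL
  converged <- FALSE
  for (it in seq_len(20)) {
    grid <- ray_grid(center, axis, n_theta = params$n_theta,
                     n_phi = params$n_phi, theta_max = params$theta_max)
    nray <- nrow(grid$dirs)
    pts <- grid$dirs[rep(seq_len(nray), each = length(r_samp)), ] * r_samp +
           matrix(center, nray * length(r_samp), 3, byrow = TRUE)
    vals <- matrix(.interp3(frame, pts)$values, length(r_samp), nray)
    k <- apply(vals, 2, which.max)
    # parabolic sub-step refinement of the per-ray count maximum
    ki <- pmin(pmax(k, 2L), length(r_samp) - 1L)
    idx <- cbind(ki, seq_len(nray))
    vm1 <- vals[cbind(ki - 1L, seq_len(nray))]
    vp1 <- vals[cbind(ki + 1L, seq_len(nray))]
    den <- vm1 - 2 * vals[idx] + vp1
    delta <- ifelse(abs(den) > 1e-12, 0.5 * (vm1 - vp1) / den, 0)
    delta <- pmin(pmax(delta, -1), 1)
    mid_r <- matrix(r_samp[ki] + delta * step, grid$n_theta, grid$n_phi)
    mid_r <- .smooth_grid(mid_r, params$smoothing_passes)
    # re-centre to the axial midpoint of the fitted surface (so rays reach
    # both the apex and the basal rim) and to the mean lateral offset
    spts <- .ray_points(grid, as.vector(mid_r))
    rel <- spts - matrix(center, nrow(spts), 3, byrow = TRUE)
    s_ax <- as.vector(rel %*% axis)
    ring_s <- rowMeans(matrix(s_ax, grid$n_theta))
    lat <- rel - s_ax %o% axis
    new_center <- center + axis * (max(ring_s) + min(ring_s)) / 2 +
                  colMeans(lat)
    shift <- sqrt(sum((new_center - center)^2))
    center <- new_center
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("mid-surface fit did not converge in 20 iterations; returning last iterate")
  grid <- ray_grid(center, axis, n_theta = params$n_theta,
                   n_phi = params$n_phi, theta_max = params$theta_max)
  list(grid = grid, mid_r = mid_r)
}

# valve plane perpendicular to the fitted long axis, placed where the
# circumferential median of mid-surface counts drops below 50% of the
# mid-ventricular count level (median over rings in the middle third of the
# long axis), with one-ring hysteresis; the crossing position is linearly
# interpolated between rings. With symmetric blur, the half-level crossing
# is an unbiased estimate of where the myocardium ends at the base.
.valve_plane <- function(frame, fit) {
  grid <- fit$grid
  pts <- .ray_points(grid, as.vector(fit$mid_r))
  cm <- matrix(.interp3(frame, pts)$values, grid$n_theta, grid$n_phi)
  ring_med <- apply(cm, 1, stats::median)
  s_ring <- rowMeans(matrix((pts - matrix(grid$center, nrow(pts), 3, byrow = TRUE)) %*%
                              grid$axis, grid$n_theta, grid$n_phi))
  ax_lo <- min(s_ring) + diff(range(s_ring)) / 3
  ax_hi <- min(s_ring) + 2 * diff(range(s_ring)) / 3
  midring <- which(s_ring >= ax_lo & s_ring <= ax_hi)
  if (length(midring) == 0) midring <- seq_len(grid$n_theta)
  lvl <- stats::median(ring_med[midring])
  i0 <- max(midring)
  cut <- NA_integer_
  if (i0 < grid$n_theta) {
    for (i in (i0 + 1):grid$n_theta) {
      below <- ring_med[i] < 0.5 * lvl
      confirm <- i == grid$n_theta || ring_med[min(i + 1, grid$n_theta)] < 0.5 * lvl
      if (below && confirm) { cut <- i; break }
    }
  }
  s_plane <- if (is.na(cut)) {
    max(s_ring) + abs(diff(range(s_ring))) / grid$n_theta
  } else if (cut == 1) {
    s_ring[1]
  } else {
    f <- (ring_med[cut - 1] - 0.5 * lvl) /
         max(ring_med[cut - 1] - ring_med[cut], 1e-12)
    s_ring[cut - 1] + min(max(f, 0), 1) * (s_ring[cut] - s_ring[cut - 1])
  }
  list(point = grid$center + s_plane * grid$axis, normal = grid$axis,
       ring_cut = cut)
}

#' Locate threshold crossings on a single count profile
#'
#' Given samples of a count profile along one ray (radii increasing), finds
#' the profile maximum C and the innermost and outermost positions where the
#' profile crosses \code{threshold_fraction * C}, by linear interpolation
#' between adjacent samples. When the counts inside the wall never fall
#' below the threshold (the small-cavity signature), the endocardial edge
#' falls back to the position of the cavity count minimum and the profile is
#' flagged.
#'
#' @param values profile counts.
#' @param positions radii of the samples, mm, strictly increasing.
#' @param threshold_fraction edge threshold as a fraction of the maximum.
#' @return list with \code{endo}, \code{epi}, \code{peak} positions (mm) and
#'   logical \code{flagged}.
#' @export
profile_edges <- function(values, positions, threshold_fraction = 0.75) {
  n <- length(values)
  stopifnot(length(positions) == n, n >= 2)
  i0 <- which.max(values)
  thr <- threshold_fraction * values[i0]
  endo <- NA_real_; flagged <- FALSE
  if (i0 > 1) {
    for (k in (i0 - 1):1) {
      if (values[k] < thr) {
        endo <- positions[k] + (positions[k + 1] - positions[k]) *
          (thr - values[k]) / (values[k + 1] - values[k])
        break
      }
    }
    if (is.na(endo)) { # no inner crossing: cavity minimum fallback
      kmin <- which.min(values[1:(i0 - 1)])
      endo <- positions[kmin]
      flagged <- TRUE
    }
  } else {
    endo <- positions[1]
    flagged <- TRUE
  }
  epi <- NA_real_
  if (i0 < n) {
    for (k in (i0 + 1):n) {
      if (values[k] < thr) {
        epi <- positions[k - 1] + (positions[k] - positions[k - 1]) *
          (thr - values[k - 1]) / (values[k] - values[k - 1])
        break
      }
    }
  }
  if (is.na(epi)) epi <- positions[n]
  list(endo = endo, epi = epi, peak = positions[i0], flagged = flagged)
}

#' Detect endocardial and epicardial edges along every sampling profile
#'
#' Counts are sampled by trilinear interpolation at \code{profile_step}
#' intervals in a window of half-width \code{search_halfwidth} around the
#' mid surface. Each profile's edges are placed where the counts cross
#' \code{threshold_fraction} of the profile maximum, symmetrically inside
#' (endocardial) and outside (epicardial) the maximum; see
#' [profile_edges()]. Profiles whose window leaves the image grid are
#' clamped with a warning.
#'
#' @param frame a [voxel_grid()].
#' @param grid the [ray_grid()] from [fit_mid_surface()].
#' @param mid_r fitted mid-surface radii (n_theta x n_phi), mm.
#' @param params an [edge_params()].
#' @return list with matrices \code{endo_r}, \code{epi_r} (mm) and logical
#'   matrix \code{flagged} marking cavity-minimum fallbacks.
#' @export
detect_edges <- function(frame, grid, mid_r, params = edge_params()) {
  stopifnot(inherits(frame, "voxel_grid"), inherits(grid, "ray_grid"))
  w <- params$search_halfwidth
  offs <- seq(-w, w, by = params$profile_step)
  nray <- nrow(grid$dirs)
  rmat <- outer(offs, as.vector(mid_r), "+")
  rmat[rmat < 0.1] <- 0.1
  pts <- grid$dirs[rep(seq_len(nray), each = length(offs)), ] * as.vector(rmat) +
         matrix(grid$center, nray * length(offs), 3, byrow = TRUE)
  ip <- .interp3(frame, pts, outside = "clamp")
  if (any(!ip$inside))
    warning("profile window leaves the image grid; samples clamped to the boundary")
  vals <- matrix(ip$values, length(offs), nray)
  endo <- epi <- flg <- numeric(nray)
  for (j in seq_len(nray)) {
    pe <- profile_edges(vals[, j], rmat[, j], params$threshold_fraction)
    endo[j] <- pe$endo; epi[j] <- pe$epi; flg[j] <- pe$flagged
  }
  mr <- as.vector(mid_r)
  endo <- pmin(endo, mr)  # ordering invariant endo <= mid <= epi
  epi <- pmax(epi, mr)
  list(endo_r = matrix(endo, grid$n_theta, grid$n_phi),
       epi_r = matrix(epi, grid$n_theta, grid$n_phi),
       flagged = matrix(as.logical(flg), grid$n_theta, grid$n_phi))
}

#' Volume-dependent edge-correction shift model
#'
#' The outward (epicardial-direction) surface shift as a second-degree
#' polynomial of the non-gated mid-ventricular volume v: the shift is
#' \code{s0} mm at v = 0 ml, decreases to 0 mm at v = \code{v0} ml, and is
#' identically 0 above \code{v0}. The polynomial's third condition is a
#' smooth junction at \code{v0} (zero slope), giving
#' \code{s(v) = s0 * (1 - v/v0)^2}.
#'
#' @param s0 shift at zero volume, mm (default 3.5).
#' @param v0 volume at which the shift reaches zero, ml (default 85).
#' @return an object of class \code{shift_model} with fields \code{s0},
#'   \code{v0} and the polynomial \code{coefficients} (a, b, c) of
#'   \code{a*v^2 + b*v + c}.
#' @export
shift_model <- function(s0 = 3.5, v0 = 85) {
  if (s0 < 0 || v0 <= 0) stop("s0 must be >= 0 and v0 > 0")
  structure(list(s0 = s0, v0 = v0,
                 coefficients = c(a = s0 / v0^2, b = -2 * s0 / v0, c = s0)),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("<shift_model> s(v) = %.3g*(1 - v/%.3g)^2 mm for v <= %.3g ml, else 0\n",
              x$s0, x$v0, x$v0))
  invisible(x)
}

#' Evaluate the edge-correction shift for a mid-ventricular volume
#'
#' @param v_mid non-gated mid-ventricular volume(s), ml; must be >= 0.
#' @param model a [shift_model()].
#' @return shift in mm (0 for volumes above the model's \code{v0}).
#' @export
shift_size <- function(v_mid, model = shift_model()) {
  if (any(v_mid < 0)) stop("mid-ventricular volume must be non-negative")
  # factored form of the quadratic: exact at both anchors
  unname(ifelse(v_mid > model$v0, 0, model$s0 * (1 - v_mid / model$v0)^2))
}

#' Shift detected surfaces in the epicardial direction
#'
#' Adds the same non-negative radial offset to the endocardial and
#' epicardial radii (outward along each ray), preserving their ordering.
#'
#' @param endo_r,epi_r radius matrices, mm.
#' @param s shift, mm (>= 0).
#' @return list with shifted \code{endo_r} and \code{epi_r}.
#' @export
apply_shift <- function(endo_r, epi_r, s) {
  if (s < 0) stop("shift must be non-negative")
  list(endo_r = endo_r + s, epi_r = epi_r + s)
}

#' Non-gated mid-ventricular volume
#'
#' Fits the mid-myocardial surface on the summed (non-gated) image and
#' returns the volume enclosed by that surface and the valve plane. This is
#' the volume from which the edge-correction shift is computed.
#'
#' @param summed the frame-summed [voxel_grid()] of a gated study.
#' @param params an [edge_params()].
#' @return volume in ml.
#' @export
mid_ventricular_volume <- function(summed, params = edge_params()) {
  fit <- fit_mid_surface(summed, params = params)
  vp <- .valve_plane(summed, fit)
  cavity_volume(.close_at_plane(fit$mid_r, vp), fit$grid, vp)
}

# Close a radial surface at the valve plane: rings at and beyond the ring
# where the valve plane was detected carry no myocardium (the fit there
# tracks noise), so their radii are extrapolated from the last myocardial
# ring and the plane itself bounds the enclosed volume.
.close_at_plane <- function(r, vp) {
  cut <- vp$ring_cut
  if (!is.null(cut) && !is.na(cut) && cut > 1 && cut <= nrow(r))
    for (i in cut:nrow(r)) r[i, ] <- r[cut - 1, ]
  r
}
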