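#' Specification of a synthetic gated myocardial phantom
#'
#' Defines an ellipsoidal-shell left ventricle imaged as a gated emission
#' study: a half-ellipsoid myocardial shell (closed apex, open base truncated
#' by a valve plane perpendicular to the long axis) whose cavity volume
#' follows a smooth periodic curve between end-diastole and end-systole,
#' rasterised onto a voxel grid, blurred with an isotropic Gaussian
#' point-spread function and optionally Poisson-sampled.
#'
#' @param edv_true end-diastolic cavity volume, ml.
#' @param esv_true end-systolic cavity volume, ml; must satisfy
#'   \code{0 < esv_true < edv_true}.
#' @param wall_thickness_ed myocardial wall thickness at end-diastole, mm.
#' @param long_axis_ratio cavity long semi-axis divided by short semi-axis.
#' @param n_frames number of gating frames in the cardiac cycle.
#' @param grid_shape voxels per axis (length 1 or 3).
#' @param voxel_size voxel edge length, mm (scalar or length 3).
#' @param psf_fwhm full width at half maximum of the Gaussian point-spread
#'   function, mm; 0 disables blurring.
#' @param total_counts expected total counts over all frames used to scale
#'   the Poisson noise; 0 disables noise and yields a deterministic study.
#' @param seed integer seed for the Poisson sampling.
#' @return an object of class \code{phantom_spec}.
#' @seealso [generate_phantom()], [sweep_phantoms()], [generate_contour_stack()]
#' @export
phantom_spec <- function(edv_true, esv_true, wall_thickness_ed = 10,
                         long_axis_ratio = 2, n_frames = 16,
                         grid_shape = c(64, 64, 64), voxel_size = 4.42,
                         psf_fwhm = 12, total_counts = 1e6, seed = 1L) {
  if (!(edv_true > 0 && esv_true > 0 && esv_true < edv_true))
    stop("volumes must satisfy 0 < esv_true < edv_true")
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (psf_fwhm < 0) stop("psf_fwhm must be non-negative")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (wall_thickness_ed <= 0) stop("wall_thickness_ed must be positive")
  if (long_axis_ratio <= 0) stop("long_axis_ratio must be positive")
  structure(list(edv_true = edv_true, esv_true = esv_true,
                 wall_thickness_ed = wall_thickness_ed,
                 long_axis_ratio = long_axis_ratio,
                 n_frames = as.integer(n_frames),
                 grid_shape = rep(as.integer(grid_shape), length.out = 3),
                 voxel_size = voxel_size, psf_fwhm = psf_fwhm,
                 total_counts = total_counts, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> EDV %.1f ml, ESV %.1f ml (EF %.1f%%), %d frames\n",
              x$edv_true, x$esv_true,
              (x$edv_true - x$esv_true) / x$edv_true * 100, x$n_frames))
  cat(sprintf("  grid %dx%dx%d @ %.3g mm, PSF FWHM %.3g mm, counts %.3g, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$psf_fwhm, x$total_counts, x$seed))
  invisible(x)
}

# short (a) and long (c) cavity semi-axes of a half-ellipsoid of volume v ml
.cavity_axes <- function(v_ml, ratio) {
  a <- (3 * v_ml * 1000 / (2 * pi * ratio))^(1 / 3)
  c(a = a, c = ratio * a)
}

.half_ellipsoid_ml <- function(a, c_) 2 / 3 * pi * a * a * c_ / 1000

# wall thickness giving shell volume m_ml around cavity (a, c)
.wall_thickness_for <- function(a, c_, m_ml) {
  f <- function(t) .half_ellipsoid_ml(a + t, c_ + t) - .half_ellipsoid_ml(a, c_) - m_ml
  stats::uniroot(f, c(1e-9, 200), tol = 1e-10)$root
}

# smooth periodic cavity-volume curve: end-diastole at frame 1, end-systole
# at the frame nearest 40% of the cycle (ties to the earlier frame)
.frame_volumes <- function(spec) {
  u <- (seq_len(spec$n_frames) - 1) / spec$n_frames
  f_es <- which.min(abs(u - 0.4))
  u_es <- u[f_es]
  edv <- spec$edv_true; esv <- spec$esv_true
  v <- ifelse(u <= u_es,
              esv + (edv - esv) * (1 + cos(pi * u / u_es)) / 2,
              esv + (edv - esv) * (1 - cos(pi * (u - u_es) / (1 - u_es))) / 2)
  list(volumes = v, frame_es = f_es)
}

# analytic per-frame geometry: cavity axes, wall thickness, valve-plane z
.phantom_geometry <- function(spec) {
  fv <- .frame_volumes(spec)
  ax_ed <- .cavity_axes(spec$edv_true, spec$long_axis_ratio)
  t_ed <- spec$wall_thickness_ed
  shell_ml <- .half_ellipsoid_ml(ax_ed["a"] + t_ed, ax_ed["c"] + t_ed) -
              .half_ellipsoid_ml(ax_ed["a"], ax_ed["c"])
  g <- data.frame(frame = seq_along(fv$volumes), volume = fv$volumes,
                  a = NA_real_, c = NA_real_, t = NA_real_)
  for (i in seq_len(nrow(g))) {
    ax <- .cavity_axes(g$volume[i], spec$long_axis_ratio)
    g$a[i] <- ax["a"]; g$c[i] <- ax["c"]
    g$t[i] <- .wall_thickness_for(ax["a"], ax["c"], shell_ml)
  }
  # fixed valve plane: the end-diastolic epicardial shell is centred along z
  z_valve <- (ax_ed["c"] + t_ed) / 2
  list(frames = g, frame_es = fv$frame_es, z_valve = unname(z_valve),
       shell_ml = unname(shell_ml))
}

.check_phantom_fits <- function(spec, geom) {
  ext <- spec$grid_shape * spec$voxel_size
  margin <- spec$psf_fwhm + max(spec$voxel_size)
  a_max <- max(geom$frames$a + geom$frames$t)
  l_max <- max(geom$frames$c + geom$frames$t) # apex-to-base z extent
  for (k in 1:2)
    if (2 * (a_max + margin) > ext[k])
      stop(sprintf("phantom exceeds grid along %s axis", c("x", "y")[k]))
  if (l_max + 2 * margin > ext[3])
    stop("phantom exceeds grid along z axis")
  invisible(TRUE)
}

# rasterise one half-ellipsoid shell frame onto the voxel grid with
# supersampled (anti-aliased) occupancy
.rasterize_shell <- function(spec, a, c_, t, z_valve, ss = 2L) {
  d <- spec$grid_shape; v <- spec$voxel_size
  coord <- function(k) {
    org <- -(d[k] - 1) / 2 * v[k] - v[k] / 2 + v[k] / (2 * ss)
    org + (0:(d[k] * ss - 1)) * v[k] / ss
  }
  x <- coord(1); y <- coord(2); z <- coord(3)
  qe <- outer(outer((x / a)^2, (y / a)^2, "+"), ((z - z_valve) / c_)^2, "+")
  A <- a + t; C <- c_ + t
  qo <- outer(outer((x / A)^2, (y / A)^2, "+"), ((z - z_valve) / C)^2, "+")
  below <- rep(z <= z_valve, each = length(x) * length(y))
  occ <- array(as.numeric(qo <= 1 & qe > 1 & below), dim(qe))
  .pool3(occ, ss)
}

#' Generate a synthetic gated emission study
#'
#' Rasterises the phantom's myocardial shell for every gating frame,
#' convolves each frame with the Gaussian point-spread function and, when
#' \code{total_counts > 0}, draws Poisson counts. The frame-wise sum stands
#' in for the non-gated acquisition. Analytic per-frame cavity volumes are
#' carried as ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class \code{gated_study}: a list with elements
#'   \code{frames} (list of [voxel_grid()]), \code{summed} (frame-wise sum),
#'   \code{truth} (analytic cavity volume per frame, ml), \code{geometry}
#'   (per-frame semi-axes and wall thickness, valve-plane position) and
#'   \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- .phantom_geometry(spec)
  .check_phantom_fits(spec, geom)
  sigma_mm <- spec$psf_fwhm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / spec$voxel_size
  imgs <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    g <- geom$frames[i, ]
    arr <- .rasterize_shell(spec, g$a, g$c, g$t, geom$z_valve)
    if (spec$psf_fwhm > 0) arr <- .blur3(arr, sigma_vox)
    imgs[[i]] <- arr
  }
  if (spec$total_counts > 0) {
    scale <- spec$total_counts / sum(vapply(imgs, sum, 0))
    set.seed(spec$seed)
    imgs <- lapply(imgs, function(a) {
      array(as.numeric(stats::rpois(length(a), a * scale)), dim(a))
    })
  }
  frames <- lapply(imgs, function(a) voxel_grid(a, spec$voxel_size))
  summed <- voxel_grid(Reduce(`+`, imgs), spec$voxel_size)
  structure(list(frames = frames, summed = summed,
                 truth = geom$frames$volume, frame_es = geom$frame_es,
                 geometry = geom, spec = spec),
            class = "gated_study")
}

#' @export
print.gated_study <- function(x, ...) {
  tr <- phantom_truth(x)
  cat(sprintf("<gated_study> %d frames; truth EDV %.1f ml, ESV %.1f ml, EF %.1f%%\n",
              length(x$frames), tr$edv, tr$esv, tr$ef))
  invisible(x)
}

#' Ground-truth global function of a phantom study
#'
#' @param study a \code{gated_study} produced by [generate_phantom()].
#' @return list with \code{edv}, \code{esv} (ml), \code{ef} (percent) and the
#'   per-frame \code{volumes}.
#' @export
phantom_truth <- function(study) {
  stopifnot(inherits(study, "gated_study"))
  v <- study$truth
  list(edv = max(v), esv = min(v), ef = (max(v) - min(v)) / max(v) * 100,
       volumes = v)
}

#' Generate a short-axis contour stack from the analytic phantom geometry
#'
#' Returns the exact endocardial cross-sections of the phantom at a given
#' frame, sampled at slice centres of a gapless short-axis stack, as closed
#' polygons. This is the synthetic substitute for manually traced cine-MR
#' contours; apical slices are included while the cross-sectional area is
#' positive.
#'
#' @param spec a [phantom_spec()].
#' @param phase frame index whose geometry is contoured.
#' @param slice_thickness slice thickness, mm.
#' @param n_vertices vertices per contour polygon (at least 64).
#' @return an object of class \code{contour_stack}; see [contour_stack()].
#' @export
generate_contour_stack <- function(spec, phase, slice_thickness = 10,
                                   n_vertices = 72) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (phase < 1 || phase > spec$n_frames) stop("phase out of range")
  if (n_vertices < 64) stop("n_vertices must be at least 64")
  geom <- .phantom_geometry(spec)
  g <- geom$frames[phase, ]
  ang <- (seq_len(n_vertices) - 1) / n_vertices * 2 * pi
  slices <- list()
  k <- 1
  repeat {
    z <- geom$z_valve - (k - 0.5) * slice_thickness
    rel <- (z - geom$z_valve) / g$c
    if (rel <= -1) break
    r <- g$a * sqrt(1 - rel^2)
    if (r <= 0) break
    slices[[k]] <- list(z = z, xy = cbind(x = r * cos(ang), y = r * sin(ang)))
    k <- k + 1
  }
  contour_stack(slices, slice_thickness)
}

#' Short-axis contour stack
#'
#' An ordered (base to apex) list of closed planar contours with a common
#' slice thickness, the input format for disk-summation volumetry.
#'
#' @param slices list of \code{list(z = <mm>, xy = <n x 2 matrix, mm>)},
#'   ordered base to apex (decreasing z) with consecutive spacing equal to
#'   \code{slice_thickness}.
#' @param slice_thickness slice thickness, mm.
#' @return an object of class \code{contour_stack}.
#' @export
contour_stack <- function(slices, slice_thickness) {
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  if (length(slices) == 0) stop("contour stack needs at least one slice")
  z <- vapply(slices, function(s) s$z, 0)
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz >= 0))
      stop("slices must be ordered base to apex (strictly decreasing z)")
    if (any(abs(-dz - slice_thickness) > 1e-6))
      stop("consecutive slice spacing must equal slice_thickness (gapless)")
  }
  structure(list(slices = slices, slice_thickness = slice_thickness),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> %d slices, thickness %.3g mm, volume %.2f ml\n",
              length(x$slices), x$slice_thickness, simpsons_volume(x)))
  invisible(x)
}

#' Generate a deterministic family of phantoms over a size grid
#'
#' One study per (EDV, ESV) pair, all other parameters shared; per-study
#' seeds are derived from the master seed so the whole sweep is reproducible.
#'
#' @param size_grid data frame (or 2-column matrix) with columns \code{edv}
#'   and \code{esv}, ml.
#' @param common a [phantom_spec()] supplying every other parameter.
#' @param seed master integer seed; study \code{i} uses \code{seed + i}.
#' @return list of \code{gated_study} objects.
#' @export
sweep_phantoms <- function(size_grid, common, seed = 1L) {
  stopifnot(inherits(common, "phantom_spec"))
  size_grid <- as.data.frame(size_grid)
  if (nrow(size_grid) == 0) return(list())
  names(size_grid)[1:2] <- c("edv", "esv")
  if (any(size_grid$esv >= size_grid$edv))
    stop("every pair must satisfy esv < edv")
  lapply(seq_len(nrow(size_grid)), function(i) {
    sp <- common
    sp$edv_true <- size_grid$edv[i]
    sp$esv_true <- size_grid$esv[i]
    sp$seed <- as.integer(seed + i)
    generate_phantom(sp)
  })
}
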