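#' Write / read a gated study as NIfTI frames with a JSON sidecar
#'
#' Each frame is stored as \code{frame_NN.nii.gz} with mm voxel dimensions;
#' \code{study.json} carries the grid origin, the generating phantom
#' parameters and the analytic truth volumes when present, so a written
#' phantom study round-trips.
#'
#' @param study a \code{gated_study}.
#' @param dir output directory (created if needed).
#' @return \code{write_gated_study} returns \code{dir} invisibly;
#'   \code{read_gated_study} returns the \code{gated_study}.
#' @export
write_gated_study <- function(study, dir) {
  stopifnot(inherits(study, "gated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study$frames)) {
    fr <- study$frames[[i]]
    img <- RNifti::asNifti(fr$counts)
    RNifti::pixdim(img) <- fr$voxel_size
    RNifti::writeNifti(img, file.path(dir, sprintf("frame_%02d.nii.gz", i)))
  }
  side <- list(n_frames = length(study$frames),
               voxel_size = study$frames[[1]]$voxel_size,
               origin = study$frames[[1]]$origin,
               truth = study$truth,
               spec = if (!is.null(study$spec)) unclass(study$spec))
  jsonlite::write_json(side, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_gated_study
#' @export
read_gated_study <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  frames <- lapply(seq_len(side$n_frames), function(i) {
    img <- RNifti::readNifti(file.path(dir, sprintf("frame_%02d.nii.gz", i)))
    voxel_grid(array(as.numeric(img), dim(img)), side$voxel_size, side$origin)
  })
  summed <- voxel_grid(Reduce(`+`, lapply(frames, `[[`, "counts")),
                       side$voxel_size, side$origin)
  spec <- if (!is.null(side$spec))
    do.call(phantom_spec, side$spec[c("edv_true", "esv_true",
                                      "wall_thickness_ed", "long_axis_ratio",
                                      "n_frames", "grid_shape", "voxel_size",
                                      "psf_fwhm", "total_counts", "seed")])
  structure(list(frames = frames, summed = summed, truth = side$truth,
                 spec = spec), class = "gated_study")
}

#' Write / read a contour stack as CSV with a JSON header sidecar
#'
#' The CSV has columns slice_index, z_mm, vertex_index, x_mm, y_mm; the
#' sidecar (same path with extension .json) carries the slice thickness.
#'
#' @param stack a [contour_stack()].
#' @param path CSV file path.
#' @return \code{write_contour_stack} returns \code{path} invisibly;
#'   \code{read_contour_stack} returns the \code{contour_stack}.
#' @export
write_contour_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  rows <- do.call(rbind, lapply(seq_along(stack$slices), function(i) {
    s <- stack$slices[[i]]
    data.frame(slice_index = i, z_mm = s$z,
               vertex_index = seq_len(nrow(s$xy)),
               x_mm = s$xy[, 1], y_mm = s$xy[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(slice_thickness = stack$slice_thickness,
                            n_slices = length(stack$slices)),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_stack
#' @export
read_contour_stack <- function(path) {
  head <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  rows <- utils::read.csv(path)
  slices <- lapply(sort(unique(rows$slice_index)), function(i) {
    s <- rows[rows$slice_index == i, ]
    s <- s[order(s$vertex_index), ]
    list(z = s$z_mm[1], xy = cbind(x = s$x_mm, y = s$y_mm))
  })
  contour_stack(slices, head$slice_thickness)
}

#' Dump fitted surfaces as CSV
#'
#' One row per frame and ray cell with the mid, endocardial and epicardial
#' radii in mm.
#'
#' @param fit an \code{lv_fit} from [quantify_lv()].
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_surfaces <- function(fit, path) {
  stopifnot(inherits(fit, "lv_fit"))
  rows <- do.call(rbind, lapply(seq_along(fit$surfaces), function(f) {
    s <- fit$surfaces[[f]]
    nt <- s$grid$n_theta; np <- s$grid$n_phi
    data.frame(frame = f,
               theta_index = rep(seq_len(nt), np),
               phi_index = rep(seq_len(np), each = nt),
               mid_r_mm = as.vector(s$mid_r),
               endo_r_mm = as.vector(s$endo_r),
               epi_r_mm = as.vector(s$epi_r))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
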