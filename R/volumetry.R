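# shoelace area of a closed polygon given as an n x 2 matrix (mm^2)
.polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# simple-polygon check: no two non-adjacent edges intersect (vectorised
# over all edge pairs)
.polygon_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  p2 <- xy[c(2:n, 1), , drop = FALSE]
  ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  keep <- ij[, 2] - ij[, 1] >= 2 & !(ij[, 1] == 1 & ij[, 2] == n)
  ij <- ij[keep, , drop = FALSE]
  a1 <- xy[ij[, 1], , drop = FALSE]; a2 <- p2[ij[, 1], , drop = FALSE]
  b1 <- xy[ij[, 2], , drop = FALSE]; b2 <- p2[ij[, 2], , drop = FALSE]
  d1 <- a2 - a1; d2 <- b2 - b1; r1 <- b1 - a1
  den <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  tt <- (r1[, 1] * d2[, 2] - r1[, 2] * d2[, 1]) / den
  uu <- (r1[, 1] * d1[, 2] - r1[, 2] * d1[, 1]) / den
  cross <- abs(den) > 1e-12 & tt > 1e-9 & tt < 1 - 1e-9 &
           uu > 1e-9 & uu < 1 - 1e-9
  !any(cross, na.rm = TRUE)
}

#' Cavity volume from a short-axis contour stack (modified Simpson's rule)
#'
#' Disk summation over a gapless stack: the volume is the sum of slice
#' polygon areas times the slice thickness. Polygon areas use the shoelace
#' formula; papillary and trabecular structures are considered part of the
#' cavity (contours are blood-pool outer boundaries) and are not subtracted.
#'
#' @param stack a [contour_stack()].
#' @return volume in ml.
#' @export
simpsons_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  areas <- numeric(length(stack$slices))
  for (i in seq_along(stack$slices)) {
    xy <- stack$slices[[i]]$xy
    if (!.polygon_simple(xy))
      stop(sprintf("self-intersecting contour polygon in slice %d", i))
    areas[i] <- .polygon_area(xy)
  }
  sum(areas) * stack$slice_thickness / 1000
}

#' Global LV function from end-diastolic and end-systolic contour stacks
#'
#' Frame selection (which stacks are ED and ES) is the caller's
#' responsibility, mirroring visually selected cine frames.
#'
#' @param ed,es [contour_stack()] objects at end-diastole and end-systole.
#' @return list with \code{edv}, \code{esv} (ml), \code{ef} (percent) and
#'   per-stack \code{slice_areas} (mm^2).
#' @export
lv_function_from_stacks <- function(ed, es) {
  edv <- simpsons_volume(ed)
  esv <- simpsons_volume(es)
  if (esv > edv)
    warning("ESV exceeds EDV: end-diastolic and end-systolic stacks may be swapped")
  area <- function(stack) vapply(stack$slices,
                                 function(s) .polygon_area(s$xy), 0)
  list(edv = edv, esv = esv, ef = (edv - esv) / edv * 100,
       slice_areas = list(ed = area(ed), es = area(es)))
}

#' Intra-observer reproducibility of duplicate measurements
#'
#' The coefficient of variation of each pair is the standard deviation of
#' the two values (|difference| / sqrt(2), the n - 1 form) divided by their
#' mean, in percent; the overall variability is the root mean square of the
#' per-pair CVs.
#'
#' @param repeats two-column matrix or data frame; each row holds the two
#'   repeated measurements of one case.
#' @return list with \code{cv_per_case} and \code{rms_cv}, percent.
#' @export
reproducibility <- function(repeats) {
  m <- as.matrix(repeats)
  if (ncol(m) != 2 || nrow(m) < 1)
    stop("repeats must have two columns and at least one row")
  means <- rowMeans(m)
  if (any(means == 0)) stop("undefined CV: a pair has zero mean")
  cv <- abs(m[, 1] - m[, 2]) / sqrt(2) / means * 100
  list(cv_per_case = cv, rms_cv = sqrt(mean(cv^2)))
}
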