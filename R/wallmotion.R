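#' Map ray-grid cells to the standard 17-segment model
#'
#' The long-axis extent below the valve plane is split into thirds (basal,
#' mid-cavity, apical) by the axial position of each cell's mid-surface
#' point; basal and mid rings are divided into six 60-degree sectors
#' starting at the anterior direction, the apical ring into four 90-degree
#' sectors, and rays within the apical cap angle form segment 17. Segments
#' are numbered 1-6 (basal), 7-12 (mid), 13-16 (apical), 17 (apex),
#' circumferentially from anterior.
#'
#' @param grid a [ray_grid()] spanning apex to valve plane.
#' @param valve_plane valve plane (list with \code{point}, \code{normal}).
#' @param mid_r mid-surface radii over the grid, mm.
#' @param apex_cap_deg polar angle of the apical cap, degrees.
#' @return an integer (n_theta x n_phi) matrix of segment ids, class
#'   \code{segment_model_17}.
#' @export
segment_map <- function(grid, valve_plane, mid_r, apex_cap_deg = 25) {
  stopifnot(inherits(grid, "ray_grid"))
  pts <- .ray_points(grid, as.vector(mid_r))
  s <- as.vector((pts - matrix(grid$center, nrow(pts), 3, byrow = TRUE)) %*% grid$axis)
  s_valve <- sum((valve_plane$point - grid$center) * valve_plane$normal /
                   sqrt(sum(valve_plane$normal^2)))
  s_apex <- min(s)
  if (s_valve <= s_apex) stop("degenerate grid: valve plane at or below the apex")
  h <- pmin(pmax((s - s_apex) / (s_valve - s_apex), 0), 1)
  theta <- matrix(grid$theta, grid$n_theta, grid$n_phi)
  phi <- matrix(grid$phi, grid$n_theta, grid$n_phi, byrow = TRUE)
  seg <- integer(length(h))
  cap <- as.vector(theta) < apex_cap_deg * pi / 180
  sec6 <- floor(as.vector(phi) / (pi / 3)) + 1          # anterior start
  sec4 <- floor(((as.vector(phi) + pi / 4) %% (2 * pi)) / (pi / 2)) + 1
  ring <- ifelse(h >= 2 / 3, 1L, ifelse(h >= 1 / 3, 2L, 3L))
  seg[ring == 1L] <- sec6[ring == 1L]
  seg[ring == 2L] <- 6L + sec6[ring == 2L]
  seg[ring == 3L] <- 12L + sec4[ring == 3L]
  seg[cap] <- 17L
  seg <- matrix(seg, grid$n_theta, grid$n_phi)
  if (length(unique(as.vector(seg))) < 17L)
    stop("degenerate grid: not all 17 segments are represented")
  structure(seg, class = c("segment_model_17", "matrix", "array"))
}

#' Grade segmental wall motion from endocardial excursion
#'
#' Visual grading is emulated by the mean endocardial excursion (inward
#' motion from end-diastole to end-systole) per segment, classified by
#' configurable cutpoints into the five standard grades: 0 = normal,
#' 1 = mildly or moderately decreased, 2 = severely decreased,
#' 3 = akinesis, 4 = dyskinesis (outward motion).
#'
#' @param endo_ed,endo_es endocardial radius matrices (mm) at end-diastole
#'   and end-systole, on the same ray grid.
#' @param model a [segment_map()] result on that grid.
#' @param cutpoints decreasing excursion cutpoints, mm, separating grades
#'   0|1, 1|2, 2|3 and 3|4.
#' @return named integer vector of 17 scores (0-4), with the per-segment
#'   mean excursion (mm) as attribute \code{excursion}.
#' @export
score_wall_motion <- function(endo_ed, endo_es, model,
                              cutpoints = c(5, 2, 0.5, -0.5)) {
  stopifnot(all(dim(endo_ed) == dim(endo_es)), all(dim(endo_ed) == dim(model)))
  if (any(diff(cutpoints) >= 0)) stop("cutpoints must be strictly decreasing")
  exc <- tapply(as.vector(endo_ed - endo_es), as.vector(unclass(model)), mean)
  exc <- exc[as.character(1:17)]
  score <- ifelse(exc >= cutpoints[1], 0L,
           ifelse(exc >= cutpoints[2], 1L,
           ifelse(exc >= cutpoints[3], 2L,
           ifelse(exc >= cutpoints[4], 3L, 4L))))
  names(score) <- paste0("seg", 1:17)
  attr(score, "excursion") <- unname(exc)
  score
}

#' Cross-tabulate paired ordinal scores into an agreement table
#'
#' @param a,b equal-length vectors of paired scores from two methods,
#'   integers in \code{0:(k-1)}; rows of the table are method A, columns
#'   method B.
#' @param k number of score levels (5 for wall-motion grades).
#' @return an [agreement_table()].
#' @export
cross_tabulate <- function(a, b, k = 5) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("paired score vectors differ in length")
  if (length(a) && (any(a < 0 | a >= k) || any(b < 0 | b >= k)))
    stop(sprintf("scores must lie in 0..%d", k - 1))
  lv <- 0:(k - 1)
  counts <- as.matrix(table(factor(a, levels = lv), factor(b, levels = lv)))
  agreement_table(counts)
}

#' Agreement table of paired ordinal scores
#'
#' A k x k cross-tabulation of scores from two methods, with margins and
#' grand total, the input to [weighted_kappa()].
#'
#' @param counts square matrix of non-negative integer counts; rows are
#'   method A scores, columns method B.
#' @return an object of class \code{agreement_table}.
#' @export
agreement_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("agreement table must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  k <- nrow(counts)
  dimnames(counts) <- list(score_a = 0:(k - 1), score_b = 0:(k - 1))
  structure(counts, class = c("agreement_table", "matrix", "array"),
            total = sum(counts), row_margin = rowSums(counts),
            col_margin = colSums(counts))
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[c("total", "row_margin", "col_margin")] <- NULL
  tot <- sum(m)
  out <- cbind(m, total = rowSums(m))
  out <- rbind(out, total = c(colSums(m), tot))
  cat(sprintf("<agreement_table> %d x %d, n = %d\n", nrow(m), ncol(m), tot))
  print(out)
  invisible(x)
}

#' Example wall-motion agreement tables
#'
#' Two bundled 5 x 5 wall-motion score contingency tables (reference method
#' in rows, gated-SPECT quantification in columns) from a published
#' two-method comparison in 44 patients (17 segments each, n = 748):
#' one against a fixed-threshold quantification and one against a
#' volume-corrected quantification. They exercise [weighted_kappa()] at
#' realistic marginal imbalance.
#'
#' @return named list of two [agreement_table()] objects, \code{fixed} and
#'   \code{corrected}.
#' @export
example_wall_motion_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "lvquant",
                                  mustWork = TRUE)
  load1 <- function(f) {
    m <- as.matrix(utils::read.csv(path(f), row.names = 1))
    agreement_table(m)
  }
  list(fixed = load1("wallmotion_table_fixed.csv"),
       corrected = load1("wallmotion_table_corrected.csv"))
}
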