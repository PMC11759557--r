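#' Local cardiac frame field
#'
#' Per-voxel orthonormal right-handed wall coordinate system: radial R
#' (endocardium to epicardium), circumferential C (tangent to the contours)
#' and longitudinal L (slice normal, apex to base), together with the
#' transmural depth (% of wall, 0 at endocardium) and the local wall
#' thickness.
#'
#' @param R,C,L V x 3 matrices of unit vectors over masked voxels.
#' @param depth Transmural depth in percent (length V).
#' @param wall_thickness Wall thickness in mm (length V).
#' @param mask Logical matrix defining the voxel order (`which(mask)`).
#' @param grid An [image_grid()].
#' @param flagged Logical vector marking voxels with ambiguous geometry.
#' @return Object of class `local_frame_field`.
#' @export
local_frame_field <- function(R, C, L, depth, wall_thickness, mask, grid,
                              flagged = rep(FALSE, nrow(R))) {
  v <- nrow(R)
  stopifnot(nrow(C) == v, nrow(L) == v, length(depth) == v,
            length(wall_thickness) == v, sum(mask) == v)
  structure(list(R = R, C = C, L = L, depth = depth,
                 wall_thickness = wall_thickness, mask = mask, grid = grid,
                 idx = which(mask), flagged = flagged),
            class = "local_frame_field")
}

#' Build local cardiac frames from contours
#'
#' Transmural depth at a point p is defined from the distances to the two
#' contours, `d = 100 * d_endo / (d_endo + d_epi)`, so it is 0 on the
#' endocardium and 100 on the epicardium and monotone along transmural rays.
#' The radial direction is the in-plane unit gradient of this depth field
#' (evaluated by central differences of the continuous distance functions,
#' not of a sampled grid), the longitudinal direction is the slice normal,
#' and C = L x R completes the right-handed frame.
#'
#' @param contours An [lv_contours()].
#' @param grid An [image_grid()].
#' @param mask Logical matrix; defaults to [contour_mask()].
#' @return A [local_frame_field()]. Voxels where the depth gradient is
#'   degenerate are flagged (frames set to the outward direction from the
#'   contour centroid).
#' @export
build_local_frames <- function(contours, grid, mask = contour_mask(contours, grid)) {
  idx <- which(mask)
  if (length(idx) == 0) stop("build_local_frames(): empty mask")
  ctr <- grid_centers(grid)
  px <- ctr$x[idx]; py <- ctr$y[idx]
  h <- 0.05 * min(grid$spacing)
  # signed distances keep the depth field differentiable across the
  # contours, so finite-difference probes from voxels hugging a contour do
  # not see the fold of the unsigned distance function
  depth_at <- function(x, y) {
    de <- points_polygon_distance(x, y, contours$endo) *
      ifelse(points_in_polygon(x, y, contours$endo), -1, 1)
    dp <- points_polygon_distance(x, y, contours$epi) *
      ifelse(points_in_polygon(x, y, contours$epi), 1, -1)
    w <- de + dp
    list(d = 100 * de / ifelse(abs(w) < .Machine$double.eps, NA_real_, w),
         w = w)
  }
  d0 <- depth_at(px, py)
  gx <- (depth_at(px + h, py)$d - depth_at(px - h, py)$d) / (2 * h)
  gy <- (depth_at(px, py + h)$d - depth_at(px, py - h)$d) / (2 * h)
  gnorm <- sqrt(gx^2 + gy^2)
  flagged <- gnorm < 1e-6
  if (any(flagged)) {
    cen <- colMeans(contours$endo)
    fx <- px[flagged] - cen[1]; fy <- py[flagged] - cen[2]
    fn <- pmax(sqrt(fx^2 + fy^2), .Machine$double.eps)
    gx[flagged] <- fx / fn; gy[flagged] <- fy / fn
    gnorm[flagged] <- 1
  }
  Rv <- cbind(gx / gnorm, gy / gnorm, 0)
  Lv <- cbind(0 * gx, 0 * gx, 1 + 0 * gx)
  Cv <- cross_rows(Lv, Rv)
  local_frame_field(Rv, Cv, Lv, pmin(pmax(d0$d, 0), 100), d0$w, mask, grid,
                    flagged = flagged)
}

# shared projection helper: remove the `axis` component of e and orient the
# remainder so its `ref` component is non-negative
.project_orient <- function(e, axis, ref) {
  p <- e - rowSums(e * axis) * axis
  s <- sign(rowSums(p * ref))
  s[s == 0] <- 1
  p * s
}

#' Helix angle
#'
#' Angle between the projection of the primary eigenvector onto the local
#' epicardial tangent (L-C) plane and the short-axis plane: positive helix
#' angles tilt toward the base (right-handed, subendocardial-type helix).
#' The eigenvector sign ambiguity is removed by orienting the projection
#' along +C, giving angles in [-90, 90).
#'
#' @param e1 V x 3 matrix of primary eigenvectors.
#' @param frames A [local_frame_field()].
#' @return List with `angle` (degrees) and `flagged` (degenerate projection,
#'   e1 parallel to R; angle `NA`).
#' @export
helix_angle <- function(e1, frames) {
  p <- .project_orient(e1, frames$R, frames$C)
  pn <- sqrt(rowSums(p^2))
  bad <- pn < 1e-8
  a <- atan2(rowSums(p * frames$L), rowSums(p * frames$C)) * 180 / pi
  a[a >= 90] <- -90   # fold the closed endpoint: range [-90, 90)
  a[bad] <- NA_real_
  list(angle = a, flagged = bad)
}

#' Transverse angle
#'
#' Angle between the projection of the primary eigenvector onto the
#' short-axis (R-C) plane and the circumferential direction: positive angles
#' tilt from the epicardial tangent plane toward the LV cavity. Normally
#' close to 0 degrees.
#'
#' @inheritParams helix_angle
#' @return List with `angle` (degrees) and `flagged`.
#' @export
transverse_angle <- function(e1, frames) {
  p <- .project_orient(e1, frames$L, frames$C)
  pn <- sqrt(rowSums(p^2))
  bad <- pn < 1e-8
  a <- atan2(rowSums(p * frames$R), rowSums(p * frames$C)) * 180 / pi
  a[bad] <- NA_real_
  list(angle = a, flagged = bad)
}

#' Sheetlet angle (E2A)
#'
#' Angle between the projection of the secondary eigenvector into the
#' radial/cross-myocyte plane and the cross-myocyte direction, where the
#' cross-myocyte direction is perpendicular to the wall-tangent projection of
#' e1 within the epicardial tangent plane. Reported as an absolute value in
#' [0, 90] by default (consensus convention); a signed variant in (-90, 90]
#' is available for research use.
#'
#' @param e1,e2 V x 3 matrices of primary / secondary eigenvectors.
#' @param frames A [local_frame_field()].
#' @param signed Return the signed angle instead of the absolute value.
#' @return List with `angle` (degrees) and `flagged` (degenerate projection).
#' @export
sheetlet_angle <- function(e1, e2, frames, signed = FALSE) {
  e1p <- e1 - rowSums(e1 * frames$R) * frames$R
  e1pn <- sqrt(rowSums(e1p^2))
  bad <- e1pn < 1e-8
  e1p <- e1p / pmax(e1pn, .Machine$double.eps)
  xv <- normalize_rows(cross_rows(frames$R, e1p))
  e2p <- e2 - rowSums(e2 * e1p) * e1p
  e2pn <- sqrt(rowSums(e2p^2))
  bad <- bad | e2pn < 1e-8
  a <- atan2(rowSums(e2p * frames$R), rowSums(e2p * xv)) * 180 / pi
  # fold the e2 axis symmetry (+e2 and -e2 describe the same sheetlet)
  a <- ifelse(a > 90, a - 180, ifelse(a <= -90, a + 180, a))
  if (!signed) a <- abs(a)
  a[bad] <- NA_real_
  list(angle = a, flagged = bad)
}

#' Compute all angle maps from an eigensystem
#'
#' @param eig An [eigendecompose()] result.
#' @param frames A [local_frame_field()] over the same mask.
#' @param signed_e2a Report signed E2A (default absolute).
#' @return List of class `angle_maps` with vectors `ha`, `ta`, `e2a` over the
#'   masked voxels, per-angle degenerate flags, and `e2a_low_confidence`
#'   marking voxels whose lambda2 and lambda3 are within 2% (near-degenerate
#'   sheetlet plane; no eigenvector swapping is attempted).
#' @export
angle_maps <- function(eig, frames, signed_e2a = FALSE) {
  stopifnot(identical(eig$idx, frames$idx))
  ha <- helix_angle(eig$e1, frames)
  ta <- transverse_angle(eig$e1, frames)
  e2a <- sheetlet_angle(eig$e1, eig$e2, frames, signed = signed_e2a)
  lam <- eig$values
  low_conf <- abs(lam[, 2] - lam[, 3]) <= 0.02 * pmax(abs(lam[, 2]), 1e-300)
  structure(list(ha = ha$angle, ta = ta$angle, e2a = e2a$angle,
                 ha_flagged = ha$flagged, ta_flagged = ta$flagged,
                 e2a_flagged = e2a$flagged, e2a_low_confidence = low_conf,
                 idx = eig$idx, grid = frames$grid, mask = frames$mask),
            class = "angle_maps")
}

#' Expand a masked-voxel vector to a full image matrix
#'
#' @param values Vector over masked voxels.
#' @param grid An [image_grid()].
#' @param idx Linear indices of the masked voxels.
#' @return Matrix of `grid$dim`, `NA` outside the mask.
#' @export
field_to_matrix <- function(values, grid, idx) {
  m <- matrix(NA_real_, grid$dim[1], grid$dim[2])
  m[idx] <- values
  m
}
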