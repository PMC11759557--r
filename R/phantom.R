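#' Solve eigenvalues for a target MD and FA
#'
#' Finds a descending eigenvalue triple with the requested mean diffusivity
#' and fractional anisotropy, with the shape fixed by the ratio
#' `lambda2 / lambda3`. Used to prescribe phantoms at consensus normal
#' MD/FA values; the default ratio 1.5 reflects typical in-vivo myocardial
#' triples (e.g. 0.9/0.6).
#'
#' @param md Target mean diffusivity (mm^2/s).
#' @param fa Target fractional anisotropy (0 < fa < 1).
#' @param ratio23 Ratio lambda2/lambda3 (>= 1).
#' @return Numeric 3-vector `(lambda1, lambda2, lambda3)` in mm^2/s.
#' @export
eigenvalues_from_md_fa <- function(md, fa, ratio23 = 1.5) {
  stopifnot(md > 0, fa > 0, fa < 1, ratio23 >= 1)
  fa_of <- function(l) sqrt(1.5 * sum((l - mean(l))^2) / sum(l^2))
  triple <- function(l3) c(3 * md - (1 + ratio23) * l3, ratio23 * l3, l3)
  # lambda3 where lambda1 == lambda2 (flattest shape attainable at this ratio)
  l3_max <- 3 * md / (1 + 2 * ratio23)
  f <- function(l3) fa_of(triple(l3)) - fa
  if (f(l3_max * (1 - 1e-9)) > 0) {
    stop("eigenvalues_from_md_fa(): target FA ", fa,
         " unreachable with ratio23 = ", ratio23, " (increase the ratio)")
  }
  l3 <- stats::uniroot(f, c(md * 1e-6, l3_max * (1 - 1e-9)),
                       tol = md * 1e-12)$root
  lam <- triple(l3)
  if (lam[1] < lam[2]) stop("eigenvalues_from_md_fa(): solver produced a ",
                            "non-descending triple")
  lam
}

#' Phantom specification
#'
#' Parameters of the synthetic left-ventricular short-axis phantom: an
#' annular cross-section with a linear transmural helix-angle profile,
#' prescribed transverse and sheetlet angles, prescribed eigenvalues, and a
#' mono-exponential forward signal model with optional Rician noise,
#' signal-dropout frames and per-beat RR variability.
#'
#' Defaults emulate a healthy mid-ventricular systolic STEAM acquisition:
#' helix angle +50 deg (endo) to -50 deg (epi), transverse angle 0,
#' absolute sheetlet angle 62 deg, eigenvalues solved so MD = 1.03e-3 mm^2/s
#' and FA = 0.47 (consensus STEAM systolic normal means).
#'
#' @param matrix_size Image matrix (pixels).
#' @param pixel_spacing In-plane pixel size (mm).
#' @param slice_thickness Slice thickness (mm).
#' @param center LV center in mm; defaults to the grid center.
#' @param r_endo,r_epi Endocardial / epicardial radii (mm).
#' @param ha_endo,ha_epi Helix angle at 0% and 100% transmural depth (deg).
#' @param ta Transverse angle (deg).
#' @param e2a Absolute sheetlet angle (deg, 0-90).
#' @param eigenvalues Descending triple (mm^2/s).
#' @param s0 Baseline (unattenuated) signal.
#' @param snr Signal-to-noise ratio of the baseline signal; `Inf` disables
#'   noise. Rician noise with sigma = s0/snr is applied to magnitude images.
#' @param corrupted_frames `NULL`, or a 2-column matrix / list of
#'   `c(frame, factor)` pairs: the listed frames are multiplied by the factor
#'   after noise, emulating in-plane motion signal dropout.
#' @param seed Integer seed for the noise generator.
#' @param rr_profile Optional per-frame RR interval (ms) used to rescale
#'   per-frame STEAM b-values in the forward simulation.
#' @param landmark_angles Polar angles (deg) of the two RV-insertion
#'   landmarks on the epicardial contour.
#' @param trabeculation `NULL`, or `c(angle_deg, blob_radius_mm)`: a small
#'   trabeculation blob protruding from the endocardium, flagged in the
#'   ground truth for exclusion tests.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 48, pixel_spacing = 1,
                         slice_thickness = 8, center = NULL,
                         r_endo = 10, r_epi = 17,
                         ha_endo = 50, ha_epi = -50, ta = 0, e2a = 62,
                         eigenvalues = eigenvalues_from_md_fa(1.03e-3, 0.47),
                         s0 = 1000, snr = Inf, corrupted_frames = NULL,
                         seed = 42L, rr_profile = NULL,
                         landmark_angles = c(60, -60),
                         trabeculation = NULL) {
  grid <- image_grid(matrix_size, pixel_spacing, slice_thickness)
  if (is.null(center)) center <- grid$dim * grid$spacing / 2
  if (r_endo >= r_epi) stop("phantom_spec(): r_endo must be smaller than r_epi")
  if (r_epi > min(grid$dim * grid$spacing) / 2) {
    stop("phantom_spec(): epicardial radius does not fit in the matrix")
  }
  if (abs(ha_endo) > 90 || abs(ha_epi) > 90) {
    stop("phantom_spec(): helix angles must lie in [-90, 90]")
  }
  if (e2a < 0 || e2a > 90) stop("phantom_spec(): e2a must lie in [0, 90]")
  lam <- as.numeric(eigenvalues)
  if (length(lam) != 3 || any(lam <= 0) || lam[1] < lam[2] || lam[2] < lam[3]) {
    stop("phantom_spec(): eigenvalues must be a positive descending triple")
  }
  if (!is.null(corrupted_frames)) {
    corrupted_frames <- do.call(rbind, lapply(
      if (is.list(corrupted_frames)) corrupted_frames
      else split(corrupted_frames, row(corrupted_frames)), as.numeric))
    if (ncol(corrupted_frames) != 2) {
      stop("phantom_spec(): corrupted_frames must be (frame, factor) pairs")
    }
  }
  if (!is.finite(snr) && !is.infinite(snr)) stop("phantom_spec(): bad snr")
  structure(list(grid = grid, center = as.numeric(center),
                 r_endo = r_endo, r_epi = r_epi,
                 ha_endo = ha_endo, ha_epi = ha_epi, ta = ta, e2a = e2a,
                 eigenvalues = lam, s0 = s0, snr = snr,
                 corrupted_frames = corrupted_frames, seed = as.integer(seed),
                 rr_profile = rr_profile,
                 landmark_angles = landmark_angles,
                 trabeculation = trabeculation),
            class = "phantom_spec")
}

#' Annular LV geometry of a phantom
#'
#' Builds the endocardial and epicardial contours (sampled circles), the
#' RV-insertion landmarks, the myocardial mask (voxel centers between the
#' radii) and the analytic transmural depth field.
#'
#' @param spec A [phantom_spec()].
#' @param n_points Contour sampling density (>= 90).
#' @return A list with `contours` ([lv_contours()]), `mask` (logical matrix),
#'   `depth` (matrix, % transmural, NA outside mask), `trabeculation_mask`
#'   and the `grid`.
#' @export
make_annulus <- function(spec, n_points = 180) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_points < 90) stop("make_annulus(): contours need >= 90 points")
  wall <- spec$r_epi - spec$r_endo
  if (wall < 2 * max(spec$grid$spacing)) {
    stop("make_annulus(): annulus thinner than 2 voxels")
  }
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  circle <- function(r) cbind(spec$center[1] + r * cos(th),
                              spec$center[2] + r * sin(th))
  la <- spec$landmark_angles * pi / 180
  rv <- cbind(spec$center[1] + spec$r_epi * cos(la),
              spec$center[2] + spec$r_epi * sin(la))
  ctr <- grid_centers(spec$grid)
  r_vox <- sqrt((ctr$x - spec$center[1])^2 + (ctr$y - spec$center[2])^2)
  mask <- r_vox >= spec$r_endo & r_vox <= spec$r_epi
  depth <- matrix(NA_real_, spec$grid$dim[1], spec$grid$dim[2])
  depth[mask] <- 100 * (r_vox[mask] - spec$r_endo) / wall
  trab_mask <- NULL
  trab_poly <- NULL
  if (!is.null(spec$trabeculation)) {
    ta_ang <- spec$trabeculation[1] * pi / 180
    ta_r <- spec$trabeculation[2]
    bc <- spec$center + (spec$r_endo + 1.5 * ta_r) * c(cos(ta_ang), sin(ta_ang))
    trab_poly <- cbind(bc[1] + ta_r * cos(th), bc[2] + ta_r * sin(th))
    trab_mask <- matrix(points_in_polygon(ctr$x, ctr$y, trab_poly),
                        spec$grid$dim[1], spec$grid$dim[2]) & mask
  }
  contours <- lv_contours(circle(spec$r_endo), circle(spec$r_epi),
                          rv_insertion = rv, trabeculation = trab_poly)
  list(contours = contours, mask = mask, depth = depth,
       trabeculation_mask = trab_mask, grid = spec$grid)
}

# vectorized cross product of rows of two V x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Prescribe ground-truth microstructure on a phantom
#'
#' Builds per-voxel eigenvector frames and diffusion tensors from the
#' phantom's geometry. The helix angle varies linearly with transmural depth,
#' `HA(d) = ha_endo + (ha_epi - ha_endo) * d / 100`. The primary eigenvector
#' is constructed so that the projection definitions of both the helix and
#' the transverse angle recover the prescribed values exactly:
#' `e1 ~ C + tan(HA) L + tan(TA) R`. The secondary eigenvector makes the
#' prescribed sheetlet angle with the cross-myocyte direction
#' (`x = R x e1proj`) and is re-orthogonalized against e1.
#'
#' @param spec A [phantom_spec()].
#' @param geom Output of [make_annulus()]; built if omitted.
#' @return An object of class `ground_truth`: masked-voxel tensors (V x 6,
#'   order xx,yy,zz,xy,xz,yz), eigenvector frames, prescribed angles, the
#'   analytic local wall frames and depth, contours and mask.
#' @export
prescribe_microstructure <- function(spec, geom = make_annulus(spec)) {
  idx <- which(geom$mask)
  ctr <- grid_centers(spec$grid)
  px <- ctr$x[idx] - spec$center[1]
  py <- ctr$y[idx] - spec$center[2]
  rn <- sqrt(px^2 + py^2)
  Rv <- cbind(px / rn, py / rn, 0)              # radial, endo -> epi
  Lv <- cbind(0 * rn, 0 * rn, rn / rn)          # slice normal, apex -> base
  Cv <- cross_rows(Lv, Rv)                      # circumferential (right-handed)
  d <- geom$depth[idx]
  ha <- spec$ha_endo + (spec$ha_epi - spec$ha_endo) * d / 100
  ha_r <- ha * pi / 180
  ta_r <- spec$ta * pi / 180
  near90 <- abs(abs(ha) - 90) < 1e-9
  e1 <- Cv + tan(ha_r) * Lv + tan(ta_r) * Rv
  if (any(near90)) {
    if (abs(spec$ta) > 1e-12) {
      stop("prescribe_microstructure(): |HA| = 90 requires ta = 0")
    }
    e1[near90, ] <- sign(ha[near90]) * Lv[near90, , drop = FALSE]
  }
  e1 <- normalize_rows(e1)
  e1p <- normalize_rows(e1 - rowSums(e1 * Rv) * Rv)
  xv <- normalize_rows(cross_rows(Rv, e1p))     # cross-myocyte direction
  e2a_r <- spec$e2a * pi / 180
  e2 <- cos(e2a_r) * xv + sin(e2a_r) * Rv
  e2 <- normalize_rows(e2 - rowSums(e2 * e1) * e1)
  e3 <- cross_rows(e1, e2)
  lam <- spec$eigenvalues
  outer6 <- function(v) cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                              v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
  tensors <- lam[1] * outer6(e1) + lam[2] * outer6(e2) + lam[3] * outer6(e3)
  trab_flag <- if (is.null(geom$trabeculation_mask)) rep(FALSE, length(idx))
               else geom$trabeculation_mask[idx]
  structure(list(
    spec = spec, grid = spec$grid, mask = geom$mask, idx = idx,
    contours = geom$contours, depth = d, tensors = tensors,
    e1 = e1, e2 = e2, e3 = e3,
    ha = ha, ta = rep(spec$ta, length(idx)), e2a = rep(spec$e2a, length(idx)),
    frames = local_frame_field(Rv, Cv, Lv, d,
                               rep(spec$r_epi - spec$r_endo, length(idx)),
                               geom$mask, spec$grid),
    trabeculation = trab_flag),
    class = "ground_truth")
}

#' Forward-simulate a DWI stack from ground truth
#'
#' Per-frame voxel signal follows the mono-exponential model
#' `S = s0 * exp(-b * t(g) D g)` inside the mask (0 outside). With finite
#' SNR, Rician noise is applied by adding two independent Gaussian channels
#' of width `sigma = s0 / snr` and taking the magnitude. Corrupted frames are
#' scaled after noise. If the spec carries an RR profile and the table is
#' STEAM, per-frame b-values are rescaled with each beat's RR as the
#' diffusion time.
#'
#' @param truth A [prescribe_microstructure()] result.
#' @param table A [gradient_table()].
#' @param spec Phantom spec; defaults to the one inside `truth`.
#' @return A [dwi_stack()]. The returned stack's gradient table carries the
#'   RR profile when one was simulated.
#' @export
simulate_dwis <- function(truth, table = default_gradient_table(),
                          spec = truth$spec) {
  stopifnot(inherits(truth, "ground_truth"), inherits(table, "gradient_table"))
  if (!is.null(spec$rr_profile)) {
    if (length(spec$rr_profile) != length(table)) {
      stop("simulate_dwis(): rr_profile length must match the frame count")
    }
    table <- gradient_table(table$directions, table$bvalues,
                            rr_intervals = spec$rr_profile,
                            sequence_kind = table$sequence_kind,
                            delta = table$delta,
                            big_delta_nominal = table$big_delta_nominal,
                            metadata = table$metadata)
  }
  b_eff <- effective_bvalues(table)
  q <- -design_matrix(table$directions, rep(1, length(table)))  # g' D g rows
  adc <- truth$tensors %*% t(q)                                 # V x frames
  sig <- spec$s0 * exp(-sweep(adc, 2, b_eff, `*`))
  nx <- spec$grid$dim[1]; ny <- spec$grid$dim[2]; nf <- length(table)
  arr <- array(0, dim = c(nx, ny, nf))
  flat <- matrix(arr, nx * ny, nf)
  flat[truth$idx, ] <- sig
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    set.seed(spec$seed)
    n1 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
    n2 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
    flat <- sqrt((flat + n1)^2 + n2^2)
  }
  if (!is.null(spec$corrupted_frames)) {
    for (k in seq_len(nrow(spec$corrupted_frames))) {
      fr <- spec$corrupted_frames[k, 1]
      if (fr < 1 || fr > nf) stop("corrupted frame index out of range: ", fr)
      flat[, fr] <- flat[, fr] * spec$corrupted_frames[k, 2]
    }
  }
  dwi_stack(array(flat, dim = c(nx, ny, nf)), spec$grid, table)
}

#' Build a complete phantom (geometry, truth, simulated stack)
#'
#' @param spec A [phantom_spec()].
#' @param table A [gradient_table()].
#' @return A list with `spec`, `geom`, `truth`, `stack`, `contours`.
#' @export
build_phantom <- function(spec = phantom_spec(),
                          table = default_gradient_table()) {
  geom <- make_annulus(spec)
  truth <- prescribe_microstructure(spec, geom)
  stack <- simulate_dwis(truth, table, spec)
  list(spec = spec, geom = geom, truth = truth, stack = stack,
       contours = geom$contours)
}

#' Write a phantom to disk
#'
#' Writes the simulated stack (NIfTI + .bval/.bvec), the contour file,
#' ground-truth maps (prescribed HA, E2A, depth and MD as NIfTI) and a plain
#' text echo of the spec.
#'
#' @param phantom Result of [build_phantom()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly the output directory.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  write_dwi(phantom$stack, p(""))
  write_contours(phantom$contours, p("_contours.txt"))
  tr <- phantom$truth
  to_map <- function(v) {
    m <- matrix(NA_real_, tr$grid$dim[1], tr$grid$dim[2])
    m[tr$idx] <- v
    m
  }
  write_map_nifti(to_map(tr$ha), tr$grid, p("_truth_ha.nii.gz"))
  write_map_nifti(to_map(tr$e2a), tr$grid, p("_truth_e2a.nii.gz"))
  write_map_nifti(to_map(tr$depth), tr$grid, p("_truth_depth.nii.gz"))
  write_map_nifti(to_map(rowMeans(tr$tensors[, 1:3, drop = FALSE])), tr$grid,
                  p("_truth_md.nii.gz"))
  s <- phantom$spec
  echo <- c("# cdtikit phantom spec echo",
            sprintf("matrix_size: %d %d", s$grid$dim[1], s$grid$dim[2]),
            sprintf("pixel_spacing: %g %g", s$grid$spacing[1], s$grid$spacing[2]),
            sprintf("slice_thickness: %g", s$grid$thickness),
            sprintf("center: %g %g", s$center[1], s$center[2]),
            sprintf("r_endo: %g", s$r_endo), sprintf("r_epi: %g", s$r_epi),
            sprintf("ha_endo: %g", s$ha_endo), sprintf("ha_epi: %g", s$ha_epi),
            sprintf("ta: %g", s$ta), sprintf("e2a: %g", s$e2a),
            sprintf("eigenvalues: %g %g %g", s$eigenvalues[1],
                    s$eigenvalues[2], s$eigenvalues[3]),
            sprintf("s0: %g", s$s0), sprintf("snr: %g", s$snr),
            sprintf("seed: %d", s$seed))
  writeLines(echo, p("_spec.txt"))
  invisible(dir)
}
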