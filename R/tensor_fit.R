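#' Overdetermined log-linear diffusion tensor fit
#'
#' Per voxel, solves `log S = log(S_ref) + row(g, b) . vec(D)` by least
#' squares over all frames. The intercept (the log reference signal) is
#' estimated rather than fixed, because stimulated-echo acquisitions have no
#' true b = 0 image: the low-b frame is simply another observation at its
#' actual b-value. Repetitions are never averaged; they enter as extra rows,
#' which keeps the system overdetermined and allows each frame to carry its
#' own beat-corrected b-value (STEAM tables with per-frame RR intervals are
#' corrected before the design matrix is built).
#'
#' @param stack A [dwi_stack()].
#' @param mask Logical matrix of voxels to fit.
#' @param table Gradient table; defaults to the stack's.
#' @param weighted Use weighted least squares with weights proportional to
#'   the squared signal (first-order noise propagation of the log
#'   transform); ordinary least squares by default.
#' @param keep_frames Optional integer vector of frames to use (e.g. after
#'   corrupted-frame rejection); defaults to all.
#' @return Object of class `tensor_field`: `tensors` (V x 6, order
#'   xx,yy,zz,xy,xz,yz, mm^2/s), `s_ref` (fitted reference signal),
#'   `idx`, `grid`, `mask`, and `diagnostics` (per-voxel residual norm,
#'   clamped-signal count; design condition number as an attribute).
#' @export
fit_tensor <- function(stack, mask, table = stack$table, weighted = FALSE,
                       keep_frames = NULL) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (!is.null(keep_frames)) {
    table <- gradient_table(table$directions[keep_frames, , drop = FALSE],
                            table$bvalues[keep_frames],
                            rr_intervals = table$rr_intervals[keep_frames],
                            sequence_kind = table$sequence_kind,
                            delta = table$delta,
                            big_delta_nominal = table$big_delta_nominal,
                            metadata = table$metadata)
    data <- stack$data[, , keep_frames, drop = FALSE]
  } else {
    data <- stack$data
  }
  validate_tensor_table(table)
  b_eff <- effective_bvalues(table)
  x <- cbind(1, design_matrix(table$directions, b_eff))
  qx <- qr(x)
  if (qx$rank < 7) {
    stop("fit_tensor(): design matrix rank ", qx$rank, " < 7 (6 tensor ",
         "components + reference intercept); add non-collinear directions ",
         "or a second b-value")
  }
  cond <- kappa(x, exact = TRUE)
  idx <- which(mask)
  if (length(idx) == 0) stop("fit_tensor(): empty mask")
  nf <- dim(data)[3]
  sig <- matrix(data, ncol = nf)[idx, , drop = FALSE]     # V x frames
  # log of non-positive signal is undefined; clamp to a tiny positive floor
  # and record how many observations were affected (pure-noise voxels)
  floor_val <- max(sig) * 1e-9 + .Machine$double.xmin
  n_clamped <- rowSums(sig <= 0)
  sig[sig <= 0] <- floor_val
  logs <- log(sig)
  if (!weighted) {
    beta <- qr.coef(qx, t(logs))                          # 7 x V
  } else {
    beta <- matrix(0, 7, length(idx))
    for (v in seq_along(idx)) {
      w <- sig[v, ]^2
      beta[, v] <- stats::lm.wfit(x, logs[v, ], w)$coefficients
    }
  }
  resid <- t(logs) - x %*% beta
  tensors <- t(beta[2:7, , drop = FALSE])
  structure(list(tensors = tensors, s_ref = exp(beta[1, ]),
                 idx = idx, grid = stack$grid, mask = mask,
                 table = table,
                 diagnostics = data.frame(
                   residual_norm = sqrt(colSums(resid^2)),
                   n_clamped = n_clamped),
                 condition_number = cond),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d voxels, design condition number %.3g\n",
              nrow(x$tensors), x$condition_number))
  invisible(x)
}

# expand packed 6-vector (xx,yy,zz,xy,xz,yz) to a symmetric 3x3 matrix
tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}

#' Eigendecomposition of a tensor field
#'
#' Per-voxel symmetric eigendecomposition with eigenvalues sorted in
#' descending order and eigenvectors sign-normalized to a right-handed
#' triple (`det(e1 e2 e3) > 0`). Negative third eigenvalues are flagged but
#' never clamped: a negative eigenvalue is evidence of corruption and
#' clamping would hide it.
#'
#' @param tf A [fit_tensor()] result, or any object with `tensors` (V x 6),
#'   `idx`, `grid`, `mask`.
#' @return Object of class `eigen_system`: `values` (V x 3, descending),
#'   `e1`, `e2`, `e3` (V x 3), `negative_flag`, plus `idx`/`grid`/`mask`.
#' @export
eigendecompose <- function(tf) {
  t6 <- tf$tensors
  if (any(!is.finite(t6))) stop("eigendecompose(): non-finite tensor entries")
  v <- nrow(t6)
  values <- matrix(0, v, 3)
  e1 <- matrix(0, v, 3); e2 <- matrix(0, v, 3); e3 <- matrix(0, v, 3)
  for (i in seq_len(v)) {
    es <- eigen(tensor6_to_mat(t6[i, ]), symmetric = TRUE)
    values[i, ] <- es$values           # eigen() returns descending order
    e1[i, ] <- es$vectors[, 1]
    e2[i, ] <- es$vectors[, 2]
    if (det(es$vectors) < 0) es$vectors[, 3] <- -es$vectors[, 3]
    e3[i, ] <- es$vectors[, 3]
  }
  structure(list(values = values, e1 = e1, e2 = e2, e3 = e3,
                 negative_flag = values[, 3] < 0,
                 idx = tf$idx, grid = tf$grid, mask = tf$mask),
            class = "eigen_system")
}

#' Mean diffusivity
#'
#' Average of the three tensor eigenvalues, `(l1 + l2 + l3) / 3`. Values
#' above 3e-3 mm^2/s exceed free water at body temperature and indicate
#' corruption (hard-flagged downstream by [normal_range_qc()]).
#'
#' @param eig An [eigendecompose()] result (or a V x 3 eigenvalue matrix).
#' @return Numeric vector of MD in mm^2/s.
#' @export
compute_md <- function(eig) {
  lam <- if (is.matrix(eig)) eig else eig$values
  rowMeans(lam)
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`, the standard
#' rotation-invariant form: 0 for isotropic diffusion, 1 in the stick limit.
#'
#' @inheritParams compute_md
#' @return Numeric vector in [0, 1]; `NA` where all eigenvalues are zero.
#' @export
compute_fa <- function(eig) {
  lam <- if (is.matrix(eig)) eig else eig$values
  md <- rowMeans(lam)
  num <- rowSums((lam - md)^2)
  den <- rowSums(lam^2)
  fa <- sqrt(1.5 * num / den)
  fa[den == 0] <- NA_real_
  fa
}

#' Tensor mode
#'
#' `mode = 3 * sqrt(6) * det(A / ||A||)` with `A = D - MD * I`: +1 for a
#' stick (linear) tensor, -1 for a disk (planar) tensor. Isotropic tensors
#' have an undefined mode and return 0 with a flag.
#'
#' @inheritParams compute_md
#' @return List with `mode` (numeric vector in [-1, 1]) and
#'   `isotropic_flag`.
#' @export
compute_mode <- function(eig) {
  lam <- if (is.matrix(eig)) eig else eig$values
  md <- rowMeans(lam)
  dev <- lam - md
  nrm <- sqrt(rowSums(dev^2))
  iso <- nrm <= 1e-9 * pmax(abs(md), .Machine$double.xmin)
  mode <- 3 * sqrt(6) * apply(dev, 1, prod) / pmax(nrm, .Machine$double.xmin)^3
  mode[iso] <- 0
  mode <- pmin(pmax(mode, -1), 1)
  list(mode = mode, isotropic_flag = iso)
}

#' Apparent diffusion coefficient from a two-point measurement
#'
#' `ADC = log(s_low / s_high) / (b_high - b_low)` for a single encoding
#' direction. Negative ADCs (high-b signal above low-b signal) indicate
#' noise or artifact and are flagged, not suppressed.
#'
#' @param s_low,s_high Signals at the two b-values (s_low > 0, s_high > 0).
#' @param b_low,b_high b-values in s/mm^2 (b_high > b_low).
#' @return List with `adc` (mm^2/s) and `negative_flag`.
#' @export
adc_from_pair <- function(s_low, s_high, b_low, b_high) {
  if (any(b_high <= b_low)) stop("adc_from_pair(): b_high must exceed b_low")
  if (any(s_low <= 0)) stop("adc_from_pair(): s_low must be positive")
  if (any(s_high <= 0)) stop("adc_from_pair(): s_high must be positive")
  adc <- log(s_low / s_high) / (b_high - b_low)
  list(adc = adc, negative_flag = adc < 0)
}

#' Mean ADC over three orthogonal directions
#'
#' Arithmetic mean of ADCs measured along three mutually perpendicular
#' encoding directions; equals the tensor-derived MD for noiseless
#' mono-exponential data (the trace is rotation invariant).
#'
#' @param adc3 Numeric 3-vector (or V x 3 matrix) of orthogonal ADCs.
#' @return Mean ADC (mm^2/s).
#' @export
mean_adc <- function(adc3) {
  if (is.matrix(adc3)) {
    if (ncol(adc3) != 3) stop("mean_adc(): expected three orthogonal ADCs")
    rowMeans(adc3)
  } else {
    if (length(adc3) != 3) stop("mean_adc(): expected three orthogonal ADCs")
    mean(adc3)
  }
}

#' Rotation-invariant scalar maps from an eigensystem
#'
#' @param eig An [eigendecompose()] result.
#' @return List of class `scalar_maps` with vectors `md`, `fa`, `mode` over
#'   the masked voxels plus flags.
#' @export
scalar_maps <- function(eig) {
  md <- compute_md(eig)
  fa <- compute_fa(eig)
  mode <- compute_mode(eig)
  structure(list(md = md, fa = fa, mode = mode$mode,
                 isotropic_flag = mode$isotropic_flag,
                 negative_flag = eig$negative_flag,
                 idx = eig$idx, grid = eig$grid, mask = eig$mask),
            class = "scalar_maps")
}
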