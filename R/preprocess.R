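#' Septal attenuation sanity check
#'
#' Compares the mean masked signal of the high-b frames against the low-b
#' frames. The reduction should scale roughly as `exp(-b * D)`; in practice a
#' signal reduction of 30-50% balances diffusion contrast against SNR in the
#' high-b images, so reductions outside that band are flagged.
#'
#' @param stack A [dwi_stack()].
#' @param mask Logical matrix (typically the septal ROI or full myocardium).
#' @param b_low,b_high The two b-levels to compare (s/mm^2); frames within
#'   `b_tol` of each level are pooled.
#' @param band Acceptance band on the reduction `1 - ratio` (default
#'   `c(0.30, 0.50)`).
#' @param b_tol Tolerance for matching frames to the two levels.
#' @return List with `ratio` (high/low mean signal), `reduction`
#'   (`1 - ratio`), `pass`, and the frame indices used.
#' @export
attenuation_check <- function(stack, mask, b_low = 50, b_high = 450,
                              band = c(0.30, 0.50), b_tol = 25) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (!any(mask)) stop("attenuation_check(): empty mask")
  b <- stack$table$bvalues
  lo <- which(abs(b - b_low) <= b_tol)
  hi <- which(abs(b - b_high) <= b_tol)
  if (length(lo) == 0) stop("attenuation_check(): no frames at b_low = ", b_low)
  if (length(hi) == 0) stop("attenuation_check(): no frames at b_high = ", b_high)
  idx <- which(mask)
  flat <- matrix(stack$data, ncol = dim(stack$data)[3])
  m_lo <- mean(flat[idx, lo])
  m_hi <- mean(flat[idx, hi])
  ratio <- m_hi / m_lo
  reduction <- 1 - ratio
  list(ratio = ratio, reduction = reduction,
       pass = reduction >= band[1] && reduction <= band[2],
       band = band, frames_low = lo, frames_high = hi)
}

#' Detect corrupted (signal-dropout) frames
#'
#' Scores each frame by its mean masked signal relative to the robust center
#' of its b-shell: `score = (mean_i - median_shell) / (1.4826 * MAD_shell)`.
#' A frame is rejected when its score falls below `-z_threshold` or its mean
#' falls below `drop_factor` times the shell median (profound signal loss).
#' Shells with fewer than 3 frames cannot provide a robust reference and are
#' never rejected from. Rejection never proceeds past the hard floor of six
#' non-collinear diffusion-weighted directions plus one reference frame.
#'
#' @param stack A [dwi_stack()].
#' @param mask Logical myocardial mask.
#' @param z_threshold Robust z-score threshold (default 3).
#' @param drop_factor Hard relative-signal floor (default 0.7).
#' @return List with `rejected` (frame indices), `scores` (data frame:
#'   frame, b, mean_signal, score, rejected) and `kept`.
#' @export
detect_corrupted_frames <- function(stack, mask, z_threshold = 3,
                                    drop_factor = 0.7) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (!any(mask)) stop("detect_corrupted_frames(): empty mask")
  nf <- dim(stack$data)[3]
  if (nf < 3) stop("detect_corrupted_frames(): stack too small to form a ",
                   "robust reference")
  idx <- which(mask)
  flat <- matrix(stack$data, ncol = nf)
  m <- colMeans(flat[idx, , drop = FALSE])
  b <- stack$table$bvalues
  shell <- as.integer(factor(round(b, 1)))
  score <- rep(NA_real_, nf)
  rejected <- logical(nf)
  for (s in unique(shell)) {
    in_s <- which(shell == s)
    if (length(in_s) < 3) next                 # no robust reference
    med <- stats::median(m[in_s])
    mad <- stats::mad(m[in_s])
    scale <- max(mad, 1e-12 * max(med, .Machine$double.xmin))
    score[in_s] <- (m[in_s] - med) / scale
    rejected[in_s] <- score[in_s] < -z_threshold | m[in_s] < drop_factor * med
  }
  # hard floor: enough geometry must survive for tensor work
  keep <- which(!rejected)
  b_keep <- b[keep]
  low_ok <- any(is_low_b(b_keep))
  n_dirs <- count_unique_directions(
    stack$table$directions[keep[!is_low_b(b_keep)], , drop = FALSE])
  if (!low_ok || n_dirs < 6) {
    stop("detect_corrupted_frames(): rejection would leave ", n_dirs,
         " non-collinear diffusion directions",
         if (!low_ok) " and no reference frame" else "",
         "; at least 6 + 1 reference are required. Lower the threshold or ",
         "inspect the data manually.")
  }
  list(rejected = which(rejected), kept = keep,
       scores = data.frame(frame = seq_len(nf), b = b, mean_signal = m,
                           score = score, rejected = rejected))
}

# integer circular-free shift of a matrix, zero-filled
shift_matrix <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
  okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# normalized cross-correlation between two matrices over their overlap
ncc <- function(a, b) {
  av <- a - mean(a); bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

#' Rigid (translation) registration of a DWI stack
#'
#' Translates each frame to maximize its normalized cross-correlation with
#' the reference frame, searching integer shifts within `+/- max_shift`
#' pixels, with optional subpixel refinement by parabolic interpolation of
#' the correlation surface at the peak. Breath-hold single-slice short-axis
#' data mostly exhibits in-plane translation, so translation-only is the
#' default rigid model. If the optimum lies on the search-window boundary the
#' frame is flagged and left unshifted rather than silently clipped.
#'
#' @param stack A [dwi_stack()].
#' @param reference_frame Frame index to register to (default 1, typically
#'   the low-b frame).
#' @param max_shift Search half-window in pixels (default 10).
#' @param subpixel Record subpixel-refined shifts (applied shifts remain
#'   integer).
#' @return List with `stack` (registered) and `shifts` (data frame: frame,
#'   dx_px, dy_px, dx_mm, dy_mm, ncc, boundary_flag). Shifts are the applied
#'   corrections: a frame displaced by (+2, +3) gets correction (-2, -3).
#' @export
rigid_register <- function(stack, reference_frame = 1, max_shift = 10,
                           subpixel = TRUE) {
  stopifnot(inherits(stack, "dwi_stack"))
  nf <- dim(stack$data)[3]
  if (reference_frame < 1 || reference_frame > nf) {
    stop("rigid_register(): invalid reference frame")
  }
  ref <- stack$data[, , reference_frame]
  shifts <- seq(-max_shift, max_shift)
  out <- stack$data
  res <- data.frame(frame = seq_len(nf), dx_px = 0, dy_px = 0,
                    dx_mm = 0, dy_mm = 0, ncc = 1, boundary_flag = FALSE)
  for (f in seq_len(nf)) {
    if (f == reference_frame) next
    img <- stack$data[, , f]
    cc <- matrix(-Inf, length(shifts), length(shifts))
    for (ix in seq_along(shifts)) {
      for (iy in seq_along(shifts)) {
        cc[ix, iy] <- ncc(ref, shift_matrix(img, shifts[ix], shifts[iy]))
      }
    }
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dx <- shifts[peak[1]]; dy <- shifts[peak[2]]
    on_boundary <- peak[1] == 1 || peak[1] == length(shifts) ||
                   peak[2] == 1 || peak[2] == length(shifts)
    if (on_boundary) {
      res[f, c("dx_px", "dy_px")] <- c(dx, dy)
      res$ncc[f] <- max(cc)
      res$boundary_flag[f] <- TRUE
      next                                   # flagged, not applied
    }
    sub <- c(dx, dy)
    if (subpixel) {
      para <- function(l, c0, r) {
        den <- l - 2 * c0 + r
        if (abs(den) < 1e-12) 0 else 0.5 * (l - r) / den
      }
      sub <- sub + c(para(cc[peak[1] - 1, peak[2]], cc[peak[1], peak[2]],
                          cc[peak[1] + 1, peak[2]]),
                     para(cc[peak[1], peak[2] - 1], cc[peak[1], peak[2]],
                          cc[peak[1], peak[2] + 1]))
    }
    out[, , f] <- shift_matrix(img, dx, dy)
    res[f, c("dx_px", "dy_px")] <- sub
    res[f, c("dx_mm", "dy_mm")] <- sub * stack$grid$spacing
    res$ncc[f] <- max(cc)
  }
  list(stack = dwi_stack(out, stack$grid, stack$table), shifts = res)
}

#' Denoising hook
#'
#' Placeholder in the correction stage of the pipeline: returns the stack
#' unchanged. PCA- and learning-based denoisers can be slotted in here by
#' passing a function `stack -> stack`.
#'
#' @param stack A [dwi_stack()].
#' @param method A function `stack -> stack`, or `NULL` for the no-op.
#' @return A [dwi_stack()].
#' @export
denoise_hook <- function(stack, method = NULL) {
  if (is.null(method)) stack else method(stack)
}

#' Run the preprocessing QC stage
#'
#' Data inspection (corrupted-frame scores and rejection), the attenuation
#' sanity check, and optional rigid registration, assembled into a QC
#' report.
#'
#' @param stack A [dwi_stack()].
#' @param mask Logical myocardial (or septal) mask.
#' @param z_threshold Passed to [detect_corrupted_frames()].
#' @param band Passed to [attenuation_check()].
#' @param b_low,b_high Passed to [attenuation_check()].
#' @param register Run rigid registration (default TRUE).
#' @param reference_frame Registration reference.
#' @return Object of class `qc_report` with fields `attenuation`,
#'   `rejection`, `registration`, `kept_frames` and `notes`; the registered,
#'   frame-pruned inputs are under `stack` and `kept_frames` (rejected
#'   frames are retained in the stack but excluded via `kept_frames`).
#' @export
run_qc <- function(stack, mask, z_threshold = 3, band = c(0.30, 0.50),
                   b_low = 50, b_high = 450, register = TRUE,
                   reference_frame = 1) {
  att <- attenuation_check(stack, mask, b_low = b_low, b_high = b_high,
                           band = band)
  rej <- detect_corrupted_frames(stack, mask, z_threshold = z_threshold)
  reg <- NULL
  out_stack <- stack
  if (register) {
    reg <- rigid_register(stack, reference_frame = reference_frame)
    out_stack <- reg$stack
  }
  notes <- character(0)
  if (!att$pass) {
    notes <- c(notes, sprintf(
      "attenuation reduction %.1f%% outside the %d-%d%% band",
      100 * att$reduction, 100 * band[1], 100 * band[2]))
  }
  if (length(rej$rejected)) {
    notes <- c(notes, sprintf("rejected %d corrupted frame(s): %s",
                              length(rej$rejected),
                              paste(rej$rejected, collapse = ", ")))
  }
  if (!is.null(reg) && any(reg$shifts$boundary_flag)) {
    notes <- c(notes, "registration hit the search-window boundary for ",
               "frame(s): ", paste(which(reg$shifts$boundary_flag),
                                   collapse = ", "))
  }
  structure(list(attenuation = att, rejection = rej, registration = reg,
                 stack = out_stack, kept_frames = rej$kept, notes = notes),
            class = "qc_report")
}

#' Write a QC report as machine-readable text plus a per-frame score CSV
#'
#' @param qc A [run_qc()] report.
#' @param prefix Output prefix; writes `<prefix>_qc.txt` and
#'   `<prefix>_frame_scores.csv`.
#' @return Invisibly the report path.
#' @export
write_qc_report <- function(qc, prefix) {
  txt <- paste0(prefix, "_qc.txt")
  lines <- c("# cdtikit QC report v1",
             sprintf("attenuation_ratio: %.6f", qc$attenuation$ratio),
             sprintf("attenuation_reduction_percent: %.3f",
                     100 * qc$attenuation$reduction),
             sprintf("attenuation_pass: %s", qc$attenuation$pass),
             sprintf("rejected_frames: %s",
                     paste(qc$rejection$rejected, collapse = " ")),
             sprintf("kept_frames: %s", paste(qc$kept_frames, collapse = " ")))
  if (!is.null(qc$registration)) {
    lines <- c(lines, sprintf("max_shift_mm: %.4f",
                              max(abs(c(qc$registration$shifts$dx_mm,
                                        qc$registration$shifts$dy_mm)))))
  }
  if (length(qc$notes)) lines <- c(lines, paste("note:", qc$notes))
  writeLines(lines, txt)
  utils::write.csv(qc$rejection$scores,
                   paste0(prefix, "_frame_scores.csv"), row.names = FALSE)
  invisible(txt)
}
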