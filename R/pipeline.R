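#' Run the full cDTI postprocessing pipeline
#'
#' Data inspection (corrupted-frame rejection and attenuation check),
#' optional rigid registration, overdetermined log-linear tensor fitting,
#' eigendecomposition, scalar and angle maps, septal-ROI summary and
#' normal-range QC — the consensus postprocessing workflow in one call.
#'
#' @param stack A [dwi_stack()].
#' @param contours An [lv_contours()] covering the stack.
#' @param sequence_kind Overrides the stack's sequence kind for QC row
#'   selection; defaults to the gradient table's.
#' @param phase Cardiac phase for normal-range QC.
#' @param reject_outliers Run corrupted-frame rejection (default TRUE).
#' @param register Run rigid registration (default FALSE: the phantom and
#'   breath-hold data are already aligned; enable for in-vivo stacks).
#' @param weighted Weighted tensor fit.
#' @param frames Optional precomputed [local_frame_field()]; built from the
#'   contours otherwise.
#' @param roi Optional ROI matrix; defaults to the septal ROI when landmarks
#'   exist, else the full myocardium.
#' @param n_bins Transmural profile bins.
#' @param min_voxels Minimum ROI size.
#' @return List with `qc`, `tensor_field`, `eigen`, `scalars`, `angles`,
#'   `frames`, `roi`, `summary`, `qc_flags`, `mask`.
#' @export
run_pipeline <- function(stack, contours, sequence_kind = NULL,
                         phase = "systole", reject_outliers = TRUE,
                         register = FALSE, weighted = FALSE, frames = NULL,
                         roi = NULL, n_bins = 10, min_voxels = 50) {
  mask <- contour_mask(contours, stack$grid)
  qc <- run_qc(stack, mask, register = register)
  work <- qc$stack
  keep <- if (reject_outliers) qc$kept_frames else seq_len(dim(stack$data)[3])
  tf <- fit_tensor(work, mask, weighted = weighted, keep_frames = keep)
  eig <- eigendecompose(tf)
  sc <- scalar_maps(eig)
  if (is.null(frames)) frames <- build_local_frames(contours, stack$grid, mask)
  ang <- angle_maps(eig, frames)
  if (is.null(roi)) {
    roi <- if (!is.null(contours$rv_insertion)) {
      septal_roi(contours, stack$grid, mask, min_voxels = min_voxels)$roi
    } else mask
  }
  summ <- summarize_roi(sc, ang, frames, roi, n_bins = n_bins,
                        min_voxels = min_voxels)
  kind <- if (is.null(sequence_kind)) stack$table$sequence_kind else sequence_kind
  flags <- normal_range_qc(summ, kind, phase)
  list(qc = qc, tensor_field = tf, eigen = eig, scalars = sc, angles = ang,
       frames = frames, roi = roi, summary = summ, qc_flags = flags,
       mask = mask)
}
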