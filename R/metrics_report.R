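# angular helpers (degrees)
.deg_mod <- function(a) ((a %% 360) + 360) %% 360

#' Septal ROI and 6-segment partition
#'
#' The septal ROI contains myocardial voxels whose polar angle about the LV
#' centroid lies on the septal arc between the two RV-insertion landmarks
#' (the arc spanning less than 180 degrees), over the full transmural
#' extent; any trabeculation region is excluded. A 6-segment equal-angle
#' partition referenced to the first (anterior) insertion landmark is also
#' returned.
#'
#' @param contours An [lv_contours()] with two RV-insertion landmarks.
#' @param grid An [image_grid()].
#' @param mask Logical myocardial mask; defaults to [contour_mask()].
#' @param min_voxels Minimum acceptable ROI size (sampling-error guard).
#' @return List with `roi` (logical matrix), `segments` (integer matrix,
#'   1-6, NA outside mask), `arc_deg` and the insertion angles.
#' @export
septal_roi <- function(contours, grid, mask = contour_mask(contours, grid),
                       min_voxels = 50) {
  if (is.null(contours$rv_insertion)) {
    stop("septal_roi(): RV-insertion landmarks are required")
  }
  cen <- colMeans(contours$endo)
  ang <- function(p) atan2(p[2] - cen[2], p[1] - cen[1]) * 180 / pi
  a1 <- ang(contours$rv_insertion[1, ])
  a2 <- ang(contours$rv_insertion[2, ])
  ctr <- grid_centers(grid)
  va <- atan2(ctr$y - cen[2], ctr$x - cen[1]) * 180 / pi
  width <- .deg_mod(a2 - a1)
  if (width > 180) { tmp <- a1; a1 <- a2; a2 <- tmp; width <- 360 - width }
  in_arc <- .deg_mod(va - a1) <= width
  roi <- mask & in_arc
  if (!is.null(contours$trabeculation)) {
    trab <- matrix(points_in_polygon(ctr$x, ctr$y, contours$trabeculation),
                   grid$dim[1], grid$dim[2])
    roi <- roi & !trab
  }
  if (sum(roi) < min_voxels) {
    stop("septal_roi(): ROI has ", sum(roi), " voxels, below the minimum of ",
         min_voxels)
  }
  seg <- matrix(NA_integer_, grid$dim[1], grid$dim[2])
  seg[mask] <- 1L + (floor(.deg_mod(va[mask] - a1) / 60) %% 6L)
  list(roi = roi, segments = seg, arc_deg = width,
       insertion_angles = c(a1, a2))
}

#' Transmural helix-angle profile
#'
#' Bins ROI voxels by transmural depth and computes a circular-aware mean
#' helix angle per bin: angles are averaged on the doubled-angle circle
#' (period 180 degrees), which treats values just below +90 and just above
#' -90 as near neighbors, and the endo-to-epi bin sequence is then unwrapped
#' so no spurious 180-degree jumps remain.
#'
#' @param ha Helix angle vector over masked voxels (degrees).
#' @param depth Transmural depth vector (same order, percent).
#' @param roi_sel Logical vector selecting ROI voxels (same order).
#' @param n_bins Number of depth bins (default 10).
#' @param min_bins Minimum populated bins required (default 5).
#' @return Data frame with `depth` (bin center, %), `ha` (unwrapped bin mean,
#'   degrees; may leave [-90, 90) after unwrapping) and `n` (voxel count);
#'   empty bins are reported with `n = 0` and `NA` means.
#' @export
transmural_profile <- function(ha, depth, roi_sel = rep(TRUE, length(ha)),
                               n_bins = 10, min_bins = 5) {
  stopifnot(length(ha) == length(depth), length(roi_sel) == length(ha))
  ha <- ha[roi_sel]; depth <- depth[roi_sel]
  ok <- is.finite(ha) & is.finite(depth)
  ha <- ha[ok]; depth <- depth[ok]
  edges <- seq(0, 100, length.out = n_bins + 1)
  bin <- cut(depth, edges, include.lowest = TRUE, labels = FALSE)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mean_axial <- function(a) {
    # mean on the doubled angle: respects the +/-90 degree wrap
    r <- a * pi / 90                       # 2 * angle in radians
    atan2(mean(sin(r)), mean(cos(r))) * 90 / pi
  }
  m <- vapply(seq_len(n_bins), function(k) {
    v <- ha[bin == k]
    if (length(v) == 0) NA_real_ else mean_axial(v)
  }, numeric(1))
  n <- tabulate(bin, nbins = n_bins)
  pop <- which(!is.na(m))
  if (length(pop) < min_bins) {
    stop("transmural_profile(): only ", length(pop),
         " populated depth bins; at least ", min_bins, " required")
  }
  # unwrap the endo->epi sequence on the 180-degree period
  for (i in seq_along(pop)[-1]) {
    d <- m[pop[i]] - m[pop[i - 1]]
    if (is.na(d)) next
    m[pop[i]] <- m[pop[i]] - 180 * round(d / 180)
  }
  data.frame(depth = centers, ha = m, n = n)
}

#' Helix-angle transmurality (HAT) and HA range
#'
#' Fits an ordinary least-squares line to the per-bin helix angle versus
#' transmural depth. HAT is the slope, in degrees per percent wall depth and
#' (scaled by the mean wall thickness) in degrees per mm. The HA range is
#' the endocardium-to-epicardium extent of the fitted line, i.e. the
#' difference between its values at 0% and 100% depth; the raw max-minus-min
#' of the bin means is also reported (it understates the surface-to-surface
#' range by half a bin width at each end).
#'
#' @param profile A [transmural_profile()] data frame.
#' @param wall_thickness Mean wall thickness in mm.
#' @return List with `hat_per_percent`, `hat_per_mm`, `ha_range` (fitted
#'   endo-to-epi extent, degrees), `ha_range_bins` (max - min of bin means)
#'   and the endocardial / epicardial intercepts `ha_endo`, `ha_epi`.
#' @export
ha_transmurality <- function(profile, wall_thickness) {
  ok <- is.finite(profile$ha)
  if (sum(ok) < 3) stop("ha_transmurality(): fewer than 3 populated bins")
  fit <- stats::lm(ha ~ depth, data = profile[ok, ])
  slope <- unname(stats::coef(fit)[2])
  ends <- unname(stats::predict(fit, data.frame(depth = c(0, 100))))
  list(hat_per_percent = slope,
       hat_per_mm = slope * 100 / wall_thickness,
       ha_range = abs(diff(ends)),
       ha_range_bins = diff(range(profile$ha[ok])),
       ha_endo = ends[1], ha_epi = ends[2])
}

#' E2A mobility
#'
#' Difference between the median absolute sheetlet angle in systole and
#' diastole over the same ROI definition: sheetlets re-orient radially in
#' systole, so healthy mobility is large and positive. A negative value
#' (diastolic above systolic) is reported as-is with a reduced-mobility
#' flag.
#'
#' @param e2a_systole,e2a_diastole Either numeric vectors of absolute E2A
#'   over the ROI, or the median values themselves (scalars).
#' @return List with `mobility` (degrees), the two medians, and
#'   `reduced_flag`.
#' @export
e2a_mobility <- function(e2a_systole, e2a_diastole) {
  med <- function(x) if (length(x) == 1) x else
    stats::median(abs(x), na.rm = TRUE)
  ms <- med(e2a_systole); md <- med(e2a_diastole)
  mob <- ms - md
  list(mobility = mob, median_systole = ms, median_diastole = md,
       reduced_flag = mob < 0)
}

#' Consensus normal-value reference table
#'
#' Approximate normal values for healthy myocardium by sequence kind and
#' cardiac phase, with the reported mean, SD and typical range, plus the
#' hard free-water ceiling on any diffusivity measure (3e-3 mm^2/s at body
#' temperature). MD entries are in mm^2/s.
#'
#' @return Data frame with columns `metric`, `sequence`, `phase`, `mean`,
#'   `sd`, `lo`, `hi`.
#' @export
normal_ranges <- function() {
  data.frame(
    metric = c("md", "fa", "fa", "e2a", "e2a",
               "md", "fa", "e2a",
               "ha_range", "hat_per_percent", "e2a_mobility"),
    sequence = c("STEAM", "STEAM", "STEAM", "STEAM", "STEAM",
                 "MCSE", "MCSE", "MCSE",
                 "any", "any", "any"),
    phase = c("any", "systole", "diastole", "diastole", "systole",
              "systole", "systole", "systole",
              "any", "any", "any"),
    mean = c(1.03e-3, 0.47, 0.58, 13, 62, 1.45e-3, 0.36, 38, NA, -1, 45),
    sd   = c(0.11e-3, 0.04, 0.04, 6, 5, 0.23e-3, 0.04, 8, NA, 0.06, NA),
    lo   = c(0.8e-3, 0.43, 0.54, 7, 51, 1.22e-3, 0.22, 34, 95, NA, 39),
    hi   = c(1.2e-3, 0.51, 0.62, 20, 67, 1.68e-3, 0.58, 47, 110, NA, 50))
}

#' Free-water diffusivity ceiling (mm^2/s)
#' @export
FREE_WATER_MD <- 3e-3

#' Summarize scalar and angle maps over an ROI
#'
#' @param scalars A [scalar_maps()] result.
#' @param angles An [angle_maps()] result over the same voxel order.
#' @param frames A [local_frame_field()] (for depth and wall thickness).
#' @param roi Logical matrix; summarized voxels are `roi & mask`.
#' @param n_bins Bins for the transmural profile.
#' @param min_voxels Minimum ROI voxel count.
#' @return Object of class `summary_metrics`: per-metric mean/median/SD,
#'   HAT and HA range from the transmural profile, E2A median, voxel count.
#' @export
summarize_roi <- function(scalars, angles, frames, roi, n_bins = 10,
                          min_voxels = 50) {
  sel <- roi[scalars$idx]
  if (sum(sel) < min_voxels) {
    stop("summarize_roi(): ROI has ", sum(sel), " voxels, below the minimum ",
         "of ", min_voxels)
  }
  st <- function(x) c(mean = mean(x, na.rm = TRUE),
                      median = stats::median(x, na.rm = TRUE),
                      sd = stats::sd(x, na.rm = TRUE))
  prof <- transmural_profile(angles$ha, frames$depth, sel, n_bins = n_bins)
  hat <- ha_transmurality(prof, mean(frames$wall_thickness[sel]))
  structure(list(
    md = st(scalars$md[sel]), fa = st(scalars$fa[sel]),
    mode = st(scalars$mode[sel]),
    e2a = st(abs(angles$e2a[sel])),
    ta = st(angles$ta[sel]),
    profile = prof, hat = hat,
    wall_thickness = mean(frames$wall_thickness[sel]),
    n_voxels = sum(sel),
    n_negative_eig = sum(scalars$negative_flag[sel])),
    class = "summary_metrics")
}

#' @export
print.summary_metrics <- function(x, ...) {
  cat("<summary_metrics>\n")
  cat(sprintf("  MD     %.3f x 10^-3 mm^2/s (median %.3f, sd %.3f)\n",
              1e3 * x$md["mean"], 1e3 * x$md["median"], 1e3 * x$md["sd"]))
  cat(sprintf("  FA     %.3f (median %.3f, sd %.3f)\n",
              x$fa["mean"], x$fa["median"], x$fa["sd"]))
  cat(sprintf("  mode   %.3f\n", x$mode["mean"]))
  cat(sprintf("  E2A    median %.1f deg\n", x$e2a["median"]))
  cat(sprintf("  HAT    %.3f deg/%% (%.3f deg/mm), HA range %.1f deg\n",
              x$hat$hat_per_percent, x$hat$hat_per_mm, x$hat$ha_range))
  cat(sprintf("  voxels %d\n", x$n_voxels))
  invisible(x)
}

#' QC against consensus normal ranges
#'
#' Flags each summarized metric as inside or outside the matching reference
#' entry for the sequence kind and cardiac phase. Where a typical range is
#' published it is used directly; otherwise mean +/- 2 SD is used, and the
#' rule that fired is recorded. Any MD above the free-water ceiling is
#' always hard-flagged regardless of range checks. STEAM and MCSE values are
#' never compared against each other's reference rows.
#'
#' @param summary A [summarize_roi()] result.
#' @param sequence_kind `"STEAM"` or `"MCSE"`.
#' @param phase `"systole"` or `"diastole"`.
#' @param table Reference table (default [normal_ranges()]).
#' @param e2a_mobility Optional mobility value (degrees) to check.
#' @return Data frame with columns `metric`, `value`, `lo`, `hi`, `rule`,
#'   `in_range`, `hard_flag`.
#' @export
normal_range_qc <- function(summary, sequence_kind = c("STEAM", "MCSE"),
                            phase = c("systole", "diastole"),
                            table = normal_ranges(), e2a_mobility = NULL) {
  sequence_kind <- match.arg(sequence_kind)
  phase <- match.arg(phase)
  lookup <- function(metric) {
    rows <- table[table$metric == metric &
                  table$sequence %in% c(sequence_kind, "any") &
                  table$phase %in% c(phase, "any"), , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    rows[order(rows$sequence == "any", rows$phase == "any"), ][1, ]
  }
  vals <- c(md = unname(summary$md["median"]),
            fa = unname(summary$fa["median"]),
            e2a = unname(summary$e2a["median"]),
            ha_range = summary$hat$ha_range,
            hat_per_percent = summary$hat$hat_per_percent)
  if (!is.null(e2a_mobility)) vals <- c(vals, e2a_mobility = e2a_mobility)
  out <- do.call(rbind, lapply(names(vals), function(metric) {
    row <- lookup(metric)
    if (is.null(row)) {
      stop("normal_range_qc(): no reference entry for metric '", metric,
           "', sequence ", sequence_kind, ", phase ", phase)
    }
    if (is.finite(row$lo) && is.finite(row$hi)) {
      lo <- row$lo; hi <- row$hi; rule <- "typical_range"
    } else {
      lo <- row$mean - 2 * row$sd; hi <- row$mean + 2 * row$sd
      rule <- "mean_pm_2sd"
    }
    v <- vals[[metric]]
    data.frame(metric = metric, value = v, lo = lo, hi = hi, rule = rule,
               in_range = v >= lo & v <= hi,
               hard_flag = metric == "md" && v > FREE_WATER_MD)
  }))
  rownames(out) <- NULL
  out
}

#' Write summary metrics and QC flags to CSV / text
#'
#' Also emits a parameter-reporting manifest listing the recommended
#' acquisition metadata fields with "missing" markers for any not present in
#' the gradient table's metadata.
#'
#' @param summary A [summarize_roi()] result.
#' @param qc_flags A [normal_range_qc()] data frame.
#' @param table A [gradient_table()] (for the metadata manifest), or NULL.
#' @param prefix Output prefix.
#' @return Invisibly the summary CSV path.
#' @export
write_report <- function(summary, qc_flags, table = NULL, prefix) {
  rows <- data.frame(
    metric = c("md_mean", "md_median", "fa_mean", "fa_median", "mode_mean",
               "e2a_median", "ta_median", "hat_per_percent", "hat_per_mm",
               "ha_range", "n_voxels"),
    value = c(summary$md["mean"], summary$md["median"], summary$fa["mean"],
              summary$fa["median"], summary$mode["mean"],
              summary$e2a["median"], summary$ta["median"],
              summary$hat$hat_per_percent, summary$hat$hat_per_mm,
              summary$hat$ha_range, summary$n_voxels))
  csv <- paste0(prefix, "_summary.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  utils::write.csv(qc_flags, paste0(prefix, "_qc_flags.csv"), row.names = FALSE)
  fields <- c("n_reference_frames", "reference_bvalue", "n_directions",
              "bvalue", "gradient_max_amplitude", "gradient_slew_rate",
              "motion_compensation", "te", "echo_spacing", "bandwidth",
              "matrix_size", "fov", "slice_thickness", "acceleration",
              "fat_suppression", "tr", "breath_hold", "n_averages",
              "trigger_delay", "rf_type")
  have <- if (is.null(table)) character(0) else names(table$metadata)
  manifest <- vapply(fields, function(f) {
    if (f %in% have) paste0(f, ": ", format(table$metadata[[f]]))
    else paste0(f, ": missing")
  }, character(1))
  writeLines(c("# acquisition parameter reporting manifest", manifest),
             paste0(prefix, "_parameters.txt"))
  invisible(csv)
}
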