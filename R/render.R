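#' Color mapping for cDTI scalar maps
#'
#' Returns a function mapping map values to colors. Helix-angle maps use a
#' cyclic hue scale that wraps at +/-90 degrees, so values just below +90 and
#' just above -90 render nearly identically and no false discontinuity
#' appears at the wrap. MD, FA and E2A use sequential perceptually-uniform
#' scales. `NA` (outside the mask) maps to transparent.
#'
#' @param metric One of `"ha"`, `"ta"`, `"md"`, `"fa"`, `"mode"`, `"e2a"`.
#' @return A list with elements `fun` (values -> colors), `limits` and
#'   `cyclic`.
#' @export
cdti_colormap <- function(metric = c("ha", "ta", "md", "fa", "mode", "e2a")) {
  metric <- match.arg(metric)
  seq_map <- function(limits, palette) {
    cols <- grDevices::hcl.colors(256, palette)
    list(fun = function(v) {
      t <- (v - limits[1]) / (limits[2] - limits[1])
      t <- pmin(pmax(t, 0), 1)
      out <- cols[1 + round(t * 255)]
      out[is.na(v)] <- NA
      out
    }, limits = limits, cyclic = FALSE)
  }
  switch(metric,
    ha = list(
      fun = function(v) {
        out <- rep(NA_character_, length(v))
        ok <- !is.na(v)
        hue <- ((v[ok] + 90) / 180) %% 1
        out[ok] <- grDevices::hsv(hue, 0.85, 0.95)
        out
      },
      limits = c(-90, 90), cyclic = TRUE),
    ta = seq_map(c(-90, 90), "Blue-Red 3"),
    md = seq_map(c(0, 3e-3), "Viridis"),
    fa = seq_map(c(0, 1), "Viridis"),
    mode = seq_map(c(-1, 1), "Blue-Red 3"),
    e2a = seq_map(c(0, 90), "Inferno")
  )
}

#' Render a scalar map to PNG with a labeled color bar
#'
#' Every render carries a labeled color bar; voxels outside the mask (`NA`)
#' are drawn as background.
#'
#' @param map Numeric matrix.
#' @param metric Metric name passed to [cdti_colormap()].
#' @param path Output PNG path.
#' @param title Plot title.
#' @param label Color-bar label (units).
#' @return Invisibly `path`.
#' @export
render_map <- function(map, metric, path, title = toupper(metric),
                       label = "") {
  cm <- cdti_colormap(metric)
  grDevices::png(path, width = 640, height = 520)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(c(1, 2), nrow = 1), widths = c(4, 1))
  op <- graphics::par(mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  nx <- nrow(map); ny <- ncol(map)
  graphics::plot(NA, xlim = c(0, nx), ylim = c(0, ny), asp = 1,
                 xlab = "", ylab = "", main = title, axes = FALSE)
  cols <- matrix(cm$fun(map), nx, ny)
  ok <- which(!is.na(cols), arr.ind = TRUE)
  if (nrow(ok)) {
    graphics::rect(ok[, 1] - 1, ok[, 2] - 1, ok[, 1], ok[, 2],
                   col = cols[ok], border = NA)
  }
  # color bar
  graphics::par(mar = c(2, 1, 3, 3))
  bar_vals <- seq(cm$limits[1], cm$limits[2], length.out = 128)
  graphics::image(z = matrix(bar_vals, nrow = 1), col = cm$fun(bar_vals),
                  axes = FALSE, main = label)
  ticks <- pretty(cm$limits, 5)
  ticks <- ticks[ticks >= cm$limits[1] & ticks <= cm$limits[2]]
  graphics::axis(4, at = (ticks - cm$limits[1]) / diff(cm$limits),
                 labels = ticks, las = 1)
  invisible(path)
}

#' Write a set of scalar maps (NIfTI + rendered PNG)
#'
#' @param maps Named list of numeric matrices; names must be metric names
#'   understood by [cdti_colormap()] (`ha`, `ta`, `md`, `fa`, `mode`, `e2a`).
#' @param grid An [image_grid()].
#' @param prefix Output prefix; writes `<prefix>_<name>.nii.gz` and
#'   `<prefix>_<name>.png` per map.
#' @param render Also write PNG renders (default `TRUE`).
#' @return Invisibly a character vector of written paths.
#' @export
write_maps <- function(maps, grid, prefix, render = TRUE) {
  units <- c(ha = "degrees", ta = "degrees", e2a = "degrees",
             md = "mm^2/s", fa = "", mode = "")
  written <- character(0)
  for (nm in names(maps)) {
    nii <- paste0(prefix, "_", nm, ".nii.gz")
    write_map_nifti(maps[[nm]], grid, nii)
    written <- c(written, nii)
    if (render) {
      png_path <- paste0(prefix, "_", nm, ".png")
      render_map(maps[[nm]], nm, png_path,
                 label = if (nm %in% names(units)) units[[nm]] else "")
      written <- c(written, png_path)
    }
  }
  invisible(written)
}
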