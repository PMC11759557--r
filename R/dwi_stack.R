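#' Diffusion-weighted image stack
#'
#' Multi-frame short-axis image stack with its geometry and the mapping from
#' frame to (b-value, direction, repeat).
#'
#' @param data 3-D array `nx x ny x frames` of non-negative signal.
#' @param grid An [image_grid()].
#' @param table A [gradient_table()] with one entry per frame.
#' @return An object of class `dwi_stack` with a `frame_map` data frame
#'   (columns `frame`, `b`, `dir_index`, `rep_index`): frames sharing the same
#'   (b, direction) pair are numbered as repeats.
#' @export
dwi_stack <- function(data, grid, table) {
  data <- as.array(data)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stop("dwi_stack(): data must be nx x ny x frames")
  if (!all(dim(data)[1:2] == grid$dim)) {
    stop("dwi_stack(): image dimensions do not match the grid")
  }
  if (dim(data)[3] != length(table)) {
    stop("dwi_stack(): ", dim(data)[3], " frames but gradient table has ",
         length(table), " entries")
  }
  if (any(data < 0, na.rm = TRUE)) stop("dwi_stack(): signal must be >= 0")
  structure(list(data = data, grid = grid, table = table,
                 frame_map = build_frame_map(table)),
            class = "dwi_stack")
}

build_frame_map <- function(table) {
  n <- length(table)
  key_dir <- apply(round(table$directions, 6), 1, paste, collapse = ",")
  dir_index <- as.integer(factor(key_dir, levels = unique(key_dir)))
  key <- paste(round(table$bvalues, 3), dir_index)
  rep_index <- integer(n)
  counts <- new.env()
  for (i in seq_len(n)) {
    k <- key[i]
    prev <- if (is.null(counts[[k]])) 0L else counts[[k]]
    rep_index[i] <- prev + 1L
    counts[[k]] <- prev + 1L
  }
  data.frame(frame = seq_len(n), b = table$bvalues,
             dir_index = dir_index, rep_index = rep_index)
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf("<dwi_stack> %d x %d x %d frames, %.3g x %.3g mm pixels\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$grid$spacing[1], x$grid$spacing[2]))
  print(x$table)
  invisible(x)
}

#' Read a DWI stack (NIfTI + .bval/.bvec)
#'
#' @param nifti_path NIfTI image, frames along the 3rd (or 4th) dimension.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @param ... Passed to [read_bval_bvec()] (e.g. `sequence_kind`,
#'   `rr_intervals`).
#' @return A [dwi_stack()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, ...) {
  if (!file.exists(nifti_path)) stop("missing NIfTI file: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4) {
    if (d[3] != 1) stop("read_dwi(): expected a single-slice stack")
    arr <- array(arr, dim = d[c(1, 2, 4)])
  } else if (length(d) != 3) {
    stop("read_dwi(): expected a 3-D or single-slice 4-D NIfTI")
  }
  pd <- RNifti::pixdim(img)
  grid <- image_grid(dim(arr)[1:2], spacing = pd[1:2],
                     thickness = if (length(pd) >= 3) pd[3] else 8)
  table <- read_bval_bvec(bval_path, bvec_path, ...)
  dwi_stack(arr, grid, table)
}

#' Write a DWI stack as NIfTI + .bval/.bvec
#'
#' @param stack A [dwi_stack()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly the NIfTI path.
#' @export
write_dwi <- function(stack, prefix) {
  stopifnot(inherits(stack, "dwi_stack"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$grid$spacing, stack$grid$thickness)
  RNifti::writeNifti(img, nii)
  write_bval_bvec(stack$table, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(nii)
}

#' Write a scalar map as NIfTI
#'
#' @param map Numeric matrix (NA outside the mask).
#' @param grid An [image_grid()].
#' @param path Output NIfTI path.
#' @return Invisibly `path`.
#' @export
write_map_nifti <- function(map, grid, path) {
  img <- RNifti::asNifti(array(map, dim = c(dim(map), 1L)))
  RNifti::pixdim(img) <- c(grid$spacing, grid$thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar map written by [write_map_nifti()]
#' @param path NIfTI path.
#' @return Numeric matrix.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  matrix(arr, d[1], d[2])
}
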