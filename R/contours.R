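#' Left-ventricular contour set
#'
#' Endocardial and epicardial polygons in mm world coordinates, plus the two
#' right-ventricular insertion landmarks that bound the interventricular
#' septum, and an optional trabeculation exclusion region. Polygon winding is
#' normalized counterclockwise on construction.
#'
#' @param endo,epi n x 2 matrices of mm coordinates (implicitly closed).
#' @param rv_insertion Either `NULL` or a 2 x 2 matrix (two landmark points on
#'   or near the epicardial contour).
#' @param trabeculation Optional polygon (n x 2) marking trabeculated voxels
#'   to exclude from analysis.
#' @return An object of class `lv_contours`.
#' @export
lv_contours <- function(endo, epi, rv_insertion = NULL, trabeculation = NULL) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (ncol(endo) != 2 || ncol(epi) != 2) stop("contours must be n x 2 matrices")
  if (nrow(endo) < 8 || nrow(epi) < 8) stop("contours need at least 8 points")
  if (!polygon_is_simple(endo)) stop("endocardial contour is self-intersecting")
  if (!polygon_is_simple(epi)) stop("epicardial contour is self-intersecting")
  endo <- normalize_winding(endo)
  epi <- normalize_winding(epi)
  if (!all(points_in_polygon(endo[, 1], endo[, 2], epi))) {
    stop("endocardial contour must lie strictly inside the epicardial contour")
  }
  if (!is.null(rv_insertion)) {
    rv_insertion <- as.matrix(rv_insertion)
    if (nrow(rv_insertion) != 2 || ncol(rv_insertion) != 2) {
      stop("rv_insertion must contain exactly two landmark points")
    }
  }
  if (!is.null(trabeculation)) {
    trabeculation <- normalize_winding(as.matrix(trabeculation))
  }
  structure(list(endo = endo, epi = epi, rv_insertion = rv_insertion,
                 trabeculation = trabeculation),
            class = "lv_contours")
}

#' @export
print.lv_contours <- function(x, ...) {
  cat(sprintf("<lv_contours> endo %d pts, epi %d pts, %s landmarks%s\n",
              nrow(x$endo), nrow(x$epi),
              if (is.null(x$rv_insertion)) "no" else "2 RV-insertion",
              if (is.null(x$trabeculation)) "" else ", trabeculation region"))
  invisible(x)
}

# The contour file is a named-section plain-text format (diff-able, desk
# scale); no standard interchange format exists for cDTI contours.
#
#   # cdtikit contours v1
#   units: mm
#   [endo]
#   x y        (one point per line)
#   [epi]
#   [rv_insertion]   (exactly 2 points when present)
#   [trabeculation]  (optional)

#' Read an LV contour file
#' @param path Contour text file (see [write_contours()] for the format).
#' @return An [lv_contours()] object.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("missing contour file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!grepl("^units:", lines)]
  section <- NA_character_
  pts <- list()
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      section <- gsub("\\[|\\]", "", ln)
      pts[[section]] <- numeric(0)
    } else {
      if (is.na(section)) stop("contour file: point data before any section")
      xy <- as.numeric(strsplit(ln, "[[:space:],]+")[[1]])
      if (length(xy) != 2 || any(!is.finite(xy))) {
        stop("contour file: malformed point line '", ln, "'")
      }
      pts[[section]] <- c(pts[[section]], xy)
    }
  }
  as_mat <- function(v) if (length(v)) matrix(v, ncol = 2, byrow = TRUE) else NULL
  endo <- as_mat(pts[["endo"]]); epi <- as_mat(pts[["epi"]])
  if (is.null(endo) || is.null(epi)) {
    stop("contour file must contain [endo] and [epi] sections")
  }
  rv <- as_mat(pts[["rv_insertion"]])
  if (!is.null(rv) && nrow(rv) != 2) {
    stop("contour file: [rv_insertion] must contain exactly two points, found ",
         nrow(rv))
  }
  lv_contours(endo, epi, rv_insertion = rv,
              trabeculation = as_mat(pts[["trabeculation"]]))
}

#' Write an LV contour file
#' @param contours An [lv_contours()] object.
#' @param path Output path.
#' @param digits Coordinate formatting precision.
#' @return Invisibly `path`.
#' @export
write_contours <- function(contours, path, digits = 12) {
  stopifnot(inherits(contours, "lv_contours"))
  fmt <- function(m) apply(m, 1, function(p)
    paste(formatC(p, digits = digits, format = "g"), collapse = " "))
  out <- c("# cdtikit contours v1", "units: mm",
           "[endo]", fmt(contours$endo),
           "[epi]", fmt(contours$epi))
  if (!is.null(contours$rv_insertion)) {
    out <- c(out, "[rv_insertion]", fmt(contours$rv_insertion))
  }
  if (!is.null(contours$trabeculation)) {
    out <- c(out, "[trabeculation]", fmt(contours$trabeculation))
  }
  writeLines(out, path)
  invisible(path)
}

#' Myocardial mask from contours
#'
#' Voxels whose centers lie between the endocardial and epicardial contours;
#' any trabeculation region can be excluded separately (see [septal_roi()]).
#'
#' @param contours An [lv_contours()] object.
#' @param grid An [image_grid()].
#' @return Logical matrix of `grid$dim`.
#' @export
contour_mask <- function(contours, grid) {
  ctr <- grid_centers(grid)
  inside_epi <- points_in_polygon(ctr$x, ctr$y, contours$epi)
  inside_endo <- points_in_polygon(ctr$x, ctr$y, contours$endo)
  matrix(inside_epi & !inside_endo, grid$dim[1], grid$dim[2])
}
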