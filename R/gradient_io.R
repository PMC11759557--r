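#' Read an FSL-dialect .bval/.bvec pair
#'
#' `.bval` holds one whitespace-separated row of b-values; `.bvec` holds three
#' rows (x, y, z components), one column per frame. Zero-norm columns (true
#' b = 0 frames) are replaced by the +x unit vector so the table validates;
#' their b-value keeps them classified as reference frames.
#'
#' @param bval_path,bvec_path File paths.
#' @param ... Passed to [gradient_table()] (`sequence_kind`, `rr_intervals`, ...).
#' @return A [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path, ...) {
  if (!file.exists(bval_path)) stop("missing .bval file: ", bval_path)
  if (!file.exists(bvec_path)) stop("missing .bvec file: ", bvec_path)
  b <- scan(bval_path, quiet = TRUE)
  vec <- as.matrix(read.table(bvec_path))
  if (nrow(vec) != 3) stop(".bvec must have exactly three rows (x, y, z)")
  if (ncol(vec) != length(b)) {
    stop(".bval has ", length(b), " entries but .bvec has ", ncol(vec),
         " columns")
  }
  dirs <- t(vec)
  norms <- sqrt(rowSums(dirs^2))
  zero <- norms < 1e-12
  if (any(zero)) {
    dirs[zero, ] <- rep(c(1, 0, 0), each = sum(zero))
    norms[zero] <- 1
  }
  dirs <- dirs / norms
  gradient_table(dirs, b, ...)
}

#' Write an FSL-dialect .bval/.bvec pair
#'
#' @param table A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @param digits Number formatting precision.
#' @return Invisibly the two paths.
#' @export
write_bval_bvec <- function(table, bval_path, bvec_path, digits = 10) {
  stopifnot(inherits(table, "gradient_table"))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  writeLines(paste(fmt(table$bvalues), collapse = " "), bval_path)
  vec <- t(table$directions)
  writeLines(apply(vec, 1, function(r) paste(fmt(r), collapse = " ")),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}
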