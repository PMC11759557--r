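#' Mono-exponential diffusion attenuation
#'
#' Signal model for a diffusion-weighted acquisition: `S = S0 * exp(-b * d)`.
#' This is the forward model shared by the phantom simulator and the
#' attenuation sanity check, and the model inverted by the tensor fit.
#'
#' @param s0 Non-diffusion-weighted signal intensity (arbitrary units, >= 0).
#' @param b Diffusion weighting in s/mm^2 (>= 0).
#' @param d Apparent diffusivity in mm^2/s (>= 0). Myocardial values are of
#'   order 1e-3 mm^2/s; free water at body temperature is about 3e-3 mm^2/s.
#'
#' @return Attenuated signal, same shape as the broadcast of the inputs.
#' @examples
#' attenuate(1000, 450, 1e-3)
#' @export
attenuate <- function(s0, b, d) {
  if (any(s0 < 0, na.rm = TRUE)) stop("attenuate(): s0 must be non-negative")
  if (any(b < 0, na.rm = TRUE)) stop("attenuate(): b must be non-negative")
  if (any(d < 0, na.rm = TRUE)) stop("attenuate(): d must be non-negative")
  s0 * exp(-b * d)
}

#' Gyromagnetic ratio of the proton (rad s^-1 T^-1)
#' @export
GAMMA_PROTON <- 2.6752e8

#' STEAM diffusion-encoding timing parameters
#'
#' Container for the monopolar stimulated-echo diffusion experiment, in which
#' the two encoding gradients sit one cardiac cycle apart so the diffusion
#' time equals the RR interval.
#'
#' @param delta Encoding-gradient duration in ms (typically 1-10 ms).
#' @param big_delta Time between the paired gradients in ms (one RR interval,
#'   ~1000 ms, for STEAM).
#' @param amplitude Gradient amplitude in mT/m (typically 40-80 mT/m; 0 is
#'   allowed and yields b = 0, i.e. no diffusion weighting).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1; defaults to the proton
#'   value.
#'
#' @return An object of class `steam_timing`.
#' @export
steam_timing <- function(delta, big_delta, amplitude, gamma = GAMMA_PROTON) {
  vals <- c(delta = delta, big_delta = big_delta, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("steam_timing(): timing parameters must be finite and > 0")
  }
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("steam_timing(): gradient amplitude must be finite and >= 0")
  }
  if (delta >= big_delta) {
    stop("steam_timing(): delta must be smaller than big_delta")
  }
  structure(list(delta = delta, big_delta = big_delta,
                 amplitude = amplitude, gamma = gamma),
            class = "steam_timing")
}

#' b-value of the monopolar STEAM diffusion experiment
#'
#' Computes `b = gamma^2 * delta^2 * G^2 * (Delta - delta/3)` in s/mm^2.
#' This holds for the monopolar stimulated-echo gradient pair only; it does
#' not hold for moment-nulled (M1/M2-compensated) spin-echo waveforms, whose
#' b-values must be taken as given.
#'
#' @param timing A [steam_timing()] object.
#' @return b-value in s/mm^2.
#' @examples
#' steam_bvalue(steam_timing(delta = 2, big_delta = 1000, amplitude = 40))
#' @export
steam_bvalue <- function(timing) {
  if (!inherits(timing, "steam_timing")) {
    stop("steam_bvalue(): expected a steam_timing object")
  }
  delta_s <- timing$delta * 1e-3          # ms -> s
  bigd_s <- timing$big_delta * 1e-3       # ms -> s
  g_tm <- timing$amplitude * 1e-3         # mT/m -> T/m
  b_si <- timing$gamma^2 * delta_s^2 * g_tm^2 * (bigd_s - delta_s / 3)
  b_si * 1e-6                             # s/m^2 -> s/mm^2
}

# Fixed, documented encoding direction sets. Shipping literal coordinates
# (rather than generating points at run time) keeps schemes reproducible
# across sessions and platforms.
.DIRECTION_SETS <- local({
  s2 <- 1 / sqrt(2)
  s3 <- 1 / sqrt(3)
  list(
    # orthonormal triad: the minimal scheme for mean-ADC (trace) imaging
    "3" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    # classic dual-gradient six-direction tensor scheme
    "6" = rbind(c(1,  1, 0), c(1, -1, 0),
                c(0,  1, 1), c(0, -1, 1),
                c(1,  0, 1), c(-1, 0, 1)) * s2,
    # six-direction scheme + axes + body diagonals: 12 well-spread directions
    "12" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1,  1, 0) * s2, c(1, -1, 0) * s2,
                 c(0,  1, 1) * s2, c(0, -1, 1) * s2,
                 c(1,  0, 1) * s2, c(-1, 0, 1) * s2,
                 c(1,  1, 1) * s3, c(-1, 1, 1) * s3, c(1, -1, 1) * s3)
  )
})

#' Built-in diffusion-encoding direction schemes
#'
#' Tensor estimation requires at least six non-collinear encoding directions
#' plus one reference image; the shipped sets are fixed coordinate lists whose
#' 6-column diffusion design matrices have full rank.
#'
#' @param n Number of directions; one of 3, 6 or 12. The 3-direction set is an
#'   orthonormal triad (sufficient for mean-ADC, not for a tensor).
#' @return An `n x 3` matrix of unit row vectors.
#' @export
builtin_directions <- function(n) {
  key <- as.character(n)
  if (length(n) != 1 || !key %in% names(.DIRECTION_SETS)) {
    stop("builtin_directions(): supported direction counts are 3, 6 and 12 ",
         "(tensor work requires at least 6 non-collinear directions)")
  }
  .DIRECTION_SETS[[key]]
}

#' Log-linear diffusion design row
#'
#' Row of the log-signal design matrix for one frame, ordered
#' `(xx, yy, zz, xy, xz, yz)` so that `row %*% vec(D) = -b * t(g) D g` for a
#' symmetric tensor packed as a 6-vector with the same ordering.
#'
#' @param direction Unit 3-vector (encoding direction).
#' @param b b-value in s/mm^2.
#' @return Numeric 6-vector.
#' @export
design_row <- function(direction, b) {
  g <- as.numeric(direction)
  if (length(g) != 3 || abs(sqrt(sum(g^2)) - 1) > 1e-6) {
    stop("design_row(): direction must be a unit 3-vector")
  }
  -b * c(g[1]^2, g[2]^2, g[3]^2,
         2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
}

# design matrix (frames x 6) for a direction matrix and per-frame b
design_matrix <- function(directions, bvalues) {
  g <- directions
  cols <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  -bvalues * cols
}

#' Gradient table
#'
#' Per-frame encoding directions and b-values, with optional per-frame RR
#' intervals (used for STEAM per-beat b-value correction) and free-form
#' acquisition metadata (TE/TR/TM/trigger delay and similar reporting fields,
#' stored but never computed on).
#'
#' @param directions Frames x 3 matrix of unit vectors (the direction stored
#'   for reference frames with very low b is still required to be a unit
#'   vector).
#' @param bvalues Per-frame diffusion weighting in s/mm^2.
#' @param rr_intervals Optional per-frame RR interval in ms; when present and
#'   `sequence_kind == "STEAM"` the effective per-frame b-value is rescaled
#'   with the beat's RR as the diffusion time (see [effective_bvalues()]).
#' @param sequence_kind `"STEAM"` or `"MCSE"`.
#' @param delta Encoding-gradient duration in ms (STEAM b-value rescaling).
#' @param big_delta_nominal Nominal diffusion time in ms that the stated
#'   b-values assume (one nominal RR for STEAM).
#' @param metadata Named list of acquisition metadata.
#'
#' @return An object of class `gradient_table`.
#' @export
gradient_table <- function(directions, bvalues, rr_intervals = NULL,
                           sequence_kind = c("STEAM", "MCSE"),
                           delta = 2, big_delta_nominal = 1000,
                           metadata = list()) {
  sequence_kind <- match.arg(sequence_kind)
  directions <- as.matrix(directions)
  bvalues <- as.numeric(bvalues)
  if (ncol(directions) != 3) stop("gradient_table(): directions must be n x 3")
  if (nrow(directions) != length(bvalues)) {
    stop("gradient_table(): directions and bvalues lengths differ")
  }
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("gradient_table(): every direction must have unit norm (within 1e-9)")
  }
  if (any(bvalues < 0)) stop("gradient_table(): b-values must be >= 0")
  if (!is.null(rr_intervals)) {
    rr_intervals <- as.numeric(rr_intervals)
    if (length(rr_intervals) != length(bvalues)) {
      stop("gradient_table(): rr_intervals length must match frame count")
    }
    if (any(rr_intervals <= 0)) stop("gradient_table(): RR intervals must be > 0")
  }
  structure(list(directions = directions, bvalues = bvalues,
                 rr_intervals = rr_intervals, sequence_kind = sequence_kind,
                 delta = delta, big_delta_nominal = big_delta_nominal,
                 metadata = metadata),
            class = "gradient_table")
}

#' @export
length.gradient_table <- function(x) length(x$bvalues)

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d frames, %s\n", length(x), x$sequence_kind))
  cat("  b-values (s/mm^2):", paste(unique(round(x$bvalues, 1)), collapse = ", "), "\n")
  if (!is.null(x$rr_intervals)) cat("  per-frame RR intervals present\n")
  invisible(x)
}

# threshold separating "reference / low-b" frames from diffusion-weighted
# ones; typical protocols use b_low 50-100 and b_high 350-500 s/mm^2
LOW_B_MAX <- 150

#' Effective per-frame b-values
#'
#' For STEAM tables with per-frame RR intervals, the diffusion time of frame i
#' is that beat's RR rather than the nominal value, so (with gamma, delta and
#' G fixed) the stated b-value rescales by
#' `(RR_i - delta/3) / (big_delta_nominal - delta/3)`. MCSE b-values, and
#' STEAM tables without RR data, are returned unchanged: the monopolar b-value
#' expression does not apply to moment-compensated waveforms.
#'
#' @param table A [gradient_table()].
#' @return Numeric vector of per-frame b-values in s/mm^2.
#' @export
effective_bvalues <- function(table) {
  stopifnot(inherits(table, "gradient_table"))
  b <- table$bvalues
  if (table$sequence_kind == "STEAM" && !is.null(table$rr_intervals)) {
    d3 <- table$delta / 3
    b <- b * (table$rr_intervals - d3) / (table$big_delta_nominal - d3)
  }
  b
}

# classify frames into low-b (reference) and high-b (diffusion-weighted)
is_low_b <- function(bvalues) bvalues <= LOW_B_MAX

# number of non-collinear directions among the high-b frames (unique up to
# sign, at ~0.5 degree tolerance)
count_unique_directions <- function(directions, tol = 1e-2) {
  if (nrow(directions) == 0) return(0L)
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(directions))) {
    g <- directions[i, ]
    dup <- FALSE
    if (nrow(kept) > 0) {
      dots <- abs(kept %*% g)
      dup <- any(dots > 1 - tol)
    }
    if (!dup) kept <- rbind(kept, g)
  }
  nrow(kept)
}

#' Check a gradient table supports tensor estimation
#'
#' Tensor work needs at least one reference (low-b) frame and at least six
#' non-collinear diffusion-weighted directions whose design matrix has full
#' rank 6.
#'
#' @param table A [gradient_table()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_tensor_table <- function(table) {
  low <- is_low_b(table$bvalues)
  if (!any(low)) {
    stop("gradient table has no low-b reference frame (b <= ", LOW_B_MAX, ")")
  }
  high_dirs <- table$directions[!low, , drop = FALSE]
  n_uniq <- count_unique_directions(high_dirs)
  if (n_uniq < 6) {
    stop("gradient table has only ", n_uniq, " non-collinear high-b ",
         "directions; tensor estimation requires at least 6")
  }
  x <- design_matrix(high_dirs, table$bvalues[!low])
  if (qr(x)$rank < 6) {
    stop("diffusion design matrix is rank-deficient (rank ", qr(x)$rank,
         " < 6); directions do not span the tensor space")
  }
  invisible(TRUE)
}

#' Default acquisition scheme
#'
#' One low-b reference frame plus `n_dir` diffusion-weighted directions,
#' optionally repeated `averages` times (repetitions are kept as separate
#' frames, never averaged, so the fit stays overdetermined and per-beat
#' b-value correction remains possible).
#'
#' @param n_dir Number of encoding directions (6 or 12).
#' @param b_low Reference b-value in s/mm^2 (default 50; a true b = 0 is
#'   avoided so perfusion does not confound the reference).
#' @param b_high Diffusion-weighted b-value in s/mm^2 (default 450).
#' @param averages Number of repeats of the whole scheme.
#' @param sequence_kind `"STEAM"` or `"MCSE"`.
#' @param rr_intervals Optional per-frame RR in ms (length must equal the
#'   total frame count).
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(n_dir = 12, b_low = 50, b_high = 450,
                                   averages = 1,
                                   sequence_kind = "STEAM",
                                   rr_intervals = NULL) {
  dirs1 <- rbind(c(1, 0, 0), builtin_directions(n_dir))
  b1 <- c(b_low, rep(b_high, n_dir))
  dirs <- dirs1[rep(seq_len(nrow(dirs1)), times = averages), , drop = FALSE]
  b <- rep(b1, times = averages)
  gradient_table(dirs, b, rr_intervals = rr_intervals,
                 sequence_kind = sequence_kind)
}
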