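test_that("attenuation check passes in the 30-50% band and fails outside it", {
  ph <- default_phantom()   # consensus STEAM-normal MD/FA, b 50/450
  roi <- septal_roi(ph$contours, ph$stack$grid, ph$geom$mask)$roi
  att <- attenuation_check(ph$stack, roi, b_low = 50, b_high = 450)
  expect_gt(att$reduction, 0.30)
  expect_lt(att$reduction, 0.50)
  expect_true(att$pass)
  # identical b-levels: zero reduction, no diffusion contrast -> fail
  same <- attenuation_check(ph$stack, roi, b_low = 450, b_high = 450)
  expect_equal(same$reduction, 0)
  expect_false(same$pass)
  # free diffusion at 3e-3 mm^2/s over delta-b 400 over-attenuates (~70%)
  iso <- 3e-3
  fast <- build_phantom(phantom_spec(eigenvalues = c(iso, iso, iso)))
  att2 <- attenuation_check(fast$stack, fast$geom$mask)
  expect_equal(att2$reduction, 1 - exp(-400 * iso), tolerance = 0.01)
  expect_false(att2$pass)
  expect_error(attenuation_check(ph$stack, ph$geom$mask & FALSE), "empty mask")
  expect_error(attenuation_check(ph$stack, roi, b_high = 900), "no frames")
})

test_that("injected dropout frames are rejected exactly; clean stacks are untouched", {
  gt <- default_gradient_table(averages = 2)       # 26 frames
  drop <- c(5L, 12L, 20L)                          # high-b frames
  spec <- phantom_spec(corrupted_frames = cbind(drop, 0.3))
  ph <- build_phantom(spec, gt)
  det <- detect_corrupted_frames(ph$stack, ph$geom$mask)
  expect_setequal(det$rejected, drop)
  expect_equal(sort(det$scores$frame[det$scores$rejected]), drop)
  clean <- build_phantom(phantom_spec(), gt)
  det0 <- detect_corrupted_frames(clean$stack, clean$geom$mask)
  expect_length(det0$rejected, 0)
})

test_that("rejection never drops below six directions plus a reference", {
  gt <- default_gradient_table(n_dir = 6)          # minimal geometry
  spec <- phantom_spec(corrupted_frames = cbind(c(3L, 5L), 0.1))
  ph <- build_phantom(spec, gt)
  expect_error(detect_corrupted_frames(ph$stack, ph$geom$mask),
               "at least 6")
})

test_that("rigid registration recovers known shifts and flags the window boundary", {
  ph <- build_phantom(small_spec())
  ref <- ph$stack$data[, , 1]
  shifted <- cdtikit:::shift_matrix(ref, 2, 3)
  arr <- array(c(ref, shifted, ref), dim = c(dim(ref), 3))
  gt <- gradient_table(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       c(50, 50, 50))
  stack <- dwi_stack(arr, ph$stack$grid, gt)
  reg <- rigid_register(stack, reference_frame = 1)
  expect_equal(round(reg$shifts$dx_px[2]), -2)
  expect_equal(round(reg$shifts$dy_px[2]), -3)
  expect_equal(reg$shifts[3, c("dx_px", "dy_px")], data.frame(dx_px = 0, dy_px = 0),
               ignore_attr = TRUE)
  # registered frame matches the reference
  expect_all_close(reg$stack$data[, , 2] - ref, 0, 1e-9)
  # a shift beyond the window is flagged, not applied
  far <- cdtikit:::shift_matrix(ref, 15, 0)
  stack2 <- dwi_stack(array(c(ref, far), dim = c(dim(ref), 2)),
                      ph$stack$grid,
                      gradient_table(rbind(c(1, 0, 0), c(0, 1, 0)), c(50, 50)))
  reg2 <- rigid_register(stack2, max_shift = 10)
  expect_true(reg2$shifts$boundary_flag[2])
  expect_equal(as.numeric(reg2$stack$data), as.numeric(stack2$data))
  expect_error(rigid_register(stack, reference_frame = 9), "invalid reference")
})

test_that("registration is idempotent", {
  ph <- build_phantom(small_spec(snr = 30, seed = 9L))
  reg1 <- rigid_register(ph$stack)
  reg2 <- rigid_register(reg1$stack)
  expect_all_close(reg2$shifts$dx_px, 0, 0.5)
  expect_all_close(reg2$shifts$dy_px, 0, 0.5)
})

test_that("outlier rejection brings MD and FA maps closer to truth on corrupted data", {
  gt <- default_gradient_table(averages = 2)
  drop <- c(3L, 9L, 17L)
  spec <- phantom_spec(corrupted_frames = cbind(drop, 0.3))
  ph <- build_phantom(spec, gt)
  md_true <- mean(spec$eigenvalues)
  fa_true <- compute_fa(matrix(spec$eigenvalues, 1))
  fit_with <- function(keep) {
    eig <- eigendecompose(fit_tensor(ph$stack, ph$geom$mask, keep_frames = keep))
    list(md = compute_md(eig), fa = compute_fa(eig))
  }
  det <- detect_corrupted_frames(ph$stack, ph$geom$mask)
  with_rej <- fit_with(det$kept)
  without <- fit_with(NULL)
  frac_md <- mean(abs(with_rej$md - md_true) < abs(without$md - md_true))
  frac_fa <- mean(abs(with_rej$fa - fa_true) < abs(without$fa - fa_true))
  expect_gte(frac_md, 0.9)
  expect_gte(frac_fa, 0.9)
  # signal dropout inflates apparent diffusivity; rejection undoes it
  expect_lt(median(with_rej$md), median(without$md))
})

test_that("QC report assembles the stage outputs and writes machine-readable text", {
  gt <- default_gradient_table(averages = 2)
  spec <- phantom_spec(corrupted_frames = cbind(12L, 0.3))
  ph <- build_phantom(spec, gt)
  qc <- run_qc(ph$stack, ph$geom$mask, register = FALSE)
  expect_s3_class(qc, "qc_report")
  expect_equal(qc$rejection$rejected, 12L)
  expect_true(qc$attenuation$pass)
  prefix <- file.path(withr::local_tempdir(), "phantom")
  write_qc_report(qc, prefix)
  lines <- readLines(paste0(prefix, "_qc.txt"))
  expect_true(any(grepl("rejected_frames: 12", lines)))
  scores <- read.csv(paste0(prefix, "_frame_scores.csv"))
  expect_equal(nrow(scores), 26L)
})
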