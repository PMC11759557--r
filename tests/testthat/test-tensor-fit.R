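test_that("noiseless overdetermined fit recovers generating tensors to 1e-9", {
  ph <- default_phantom()
  tf <- fit_tensor(ph$stack, ph$geom$mask)
  scale <- max(abs(ph$truth$tensors))
  expect_all_close((tf$tensors - ph$truth$tensors) / scale, 0, 1e-9)
  # the estimated reference signal matches the phantom baseline
  expect_all_close(tf$s_ref / ph$spec$s0 - 1, 0, 1e-9)
  # doubling every signal leaves the fitted tensor unchanged
  doubled <- dwi_stack(2 * ph$stack$data, ph$stack$grid, ph$stack$table)
  tf2 <- fit_tensor(doubled, ph$geom$mask)
  expect_all_close((tf2$tensors - tf$tensors) / scale, 0, 1e-12)
})

test_that("fewer than six non-collinear directions is refused", {
  dirs <- rbind(c(1, 0, 0), builtin_directions(6)[1:5, ])
  gt <- gradient_table(dirs, c(50, rep(450, 5)))
  ph <- default_phantom()
  arr <- ph$stack$data[, , 1:6]
  stack <- dwi_stack(arr, ph$stack$grid, gt)
  expect_error(fit_tensor(stack, ph$geom$mask), "at least 6")
})

test_that("per-beat b-value correction removes RR-jitter bias in STEAM fits", {
  set.seed(21)
  rr <- 1000 * runif(13, 0.9, 1.1)              # +/-10% RR variability
  spec <- phantom_spec(rr_profile = rr)
  ph <- build_phantom(spec)                      # simulated with true b_i
  md_true <- mean(spec$eigenvalues)
  # correction on: the stack's table carries the RR profile
  eig_on <- eigendecompose(fit_tensor(ph$stack, ph$geom$mask))
  md_on <- compute_md(eig_on)
  expect_lt(max(abs(md_on - md_true)) / md_true, 0.005)
  # correction off: refit pretending the nominal b-values applied
  gt_off <- gradient_table(ph$stack$table$directions, ph$stack$table$bvalues,
                           sequence_kind = "STEAM")
  eig_off <- eigendecompose(fit_tensor(ph$stack, ph$geom$mask, table = gt_off))
  md_off <- compute_md(eig_off)
  expect_gt(median(abs(md_off - md_true)) / md_true,
            10 * median(abs(md_on - md_true)) / md_true)
  # the uncorrected fit equals the exact linear-algebra prediction:
  # beta_off = (X'X)^-1 X' X_true beta_true (noiseless misspecified OLS)
  x_true <- cbind(1, cdtikit:::design_matrix(ph$stack$table$directions,
                                             effective_bvalues(ph$stack$table)))
  x_nom <- cbind(1, cdtikit:::design_matrix(gt_off$directions, gt_off$bvalues))
  beta_true <- rbind(log(spec$s0), t(ph$truth$tensors))
  beta_pred <- solve(crossprod(x_nom), crossprod(x_nom, x_true %*% beta_true))
  tf_off <- fit_tensor(ph$stack, ph$geom$mask, table = gt_off)
  expect_all_close((t(beta_pred[2:7, ]) - tf_off$tensors) / md_true, 0, 1e-9)
})

test_that("eigendecomposition sorts, rotates, and flags correctly", {
  lam <- c(1.6e-3, 0.9e-3, 0.59e-3)
  tfd <- list(tensors = matrix(c(lam, 0, 0, 0), 1), idx = 1L,
              grid = image_grid(4), mask = matrix(TRUE, 1, 1))
  eig <- eigendecompose(tfd)
  expect_equal(drop(eig$values), lam)
  expect_equal(abs(drop(eig$e1)), c(1, 0, 0))
  # rotated tensor: same eigenvalues, rotated eigenvectors (oracle rotation)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  d <- rot %*% diag(lam) %*% t(rot)
  tfr <- tfd
  tfr$tensors <- matrix(c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3]), 1)
  eigr <- eigendecompose(tfr)
  expect_equal(drop(eigr$values), lam, tolerance = 1e-12)
  expect_equal(abs(sum(eigr$e1 * rot[, 1])), 1, tolerance = 1e-9)
  expect_false(eig$negative_flag)
  # negative third eigenvalue: flagged, reported unchanged, never clamped
  tfn <- tfd
  tfn$tensors <- matrix(c(1e-3, 5e-4, -1e-5, 0, 0, 0), 1)
  eign <- eigendecompose(tfn)
  expect_true(eign$negative_flag)
  expect_equal(eign$values[1, 3], -1e-5)
  tfb <- tfd; tfb$tensors[1] <- NaN
  expect_error(eigendecompose(tfb), "non-finite")
})

test_that("MD, FA and mode match their defining formulas and limits", {
  lam <- matrix(c(1.6, 0.9, 0.59) * 1e-3, 1)
  expect_equal(compute_md(lam), 1.03e-3)
  expect_equal(compute_fa(lam), 0.4648, tolerance = 1e-4)
  expect_equal(compute_md(matrix(rep(1e-3, 3), 1)), 1e-3)
  # FA limits: 0 for isotropic, 1 for a stick
  expect_equal(compute_fa(matrix(rep(2e-3, 3), 1)), 0)
  expect_equal(compute_fa(matrix(c(1, 0, 0), 1)), 1)
  expect_true(is.na(compute_fa(matrix(0, 1, 3))))
  # mode limits: +1 stick, -1 disk, 0 (flagged) isotropic
  expect_equal(compute_mode(matrix(c(2, 1, 1), 1))$mode, 1, tolerance = 1e-12)
  expect_equal(compute_mode(matrix(c(2, 2, 1), 1))$mode, -1, tolerance = 1e-12)
  iso <- compute_mode(matrix(c(1, 1, 1), 1))
  expect_equal(iso$mode, 0)
  expect_true(iso$isotropic_flag)
})

test_that("MD, FA and mode are rotation invariant", {
  lam <- c(1.7e-3, 1.0e-3, 0.5e-3)
  set.seed(31)
  vals <- matrix(0, 100, 3)
  for (i in 1:100) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    d <- q %*% diag(lam) %*% t(q)
    t6 <- c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
    tfd <- list(tensors = matrix(t6, 1), idx = 1L, grid = image_grid(4),
                mask = matrix(TRUE, 1, 1))
    eig <- eigendecompose(tfd)
    vals[i, ] <- c(compute_md(eig), compute_fa(eig), compute_mode(eig)$mode)
  }
  ref <- c(mean(lam), compute_fa(matrix(lam, 1)),
           compute_mode(matrix(lam, 1))$mode)
  for (k in 1:3) expect_all_close(vals[, k] - ref[k], 0, 1e-9)
})

test_that("two-point ADC and the mean-ADC/MD trace identity", {
  got <- adc_from_pair(800, 560, 50, 450)
  expect_equal(got$adc, 8.916874e-4, tolerance = 1e-6)
  expect_false(got$negative_flag)
  expect_equal(adc_from_pair(700, 700, 50, 450)$adc, 0)
  expect_true(adc_from_pair(560, 800, 50, 450)$negative_flag)
  expect_error(adc_from_pair(800, 560, 450, 50), "exceed")
  expect_error(adc_from_pair(0, 560, 50, 450), "positive")
  expect_error(mean_adc(c(1e-3, 2e-3)), "three")
  # noiseless tensor signals measured along any orthonormal triad:
  # mean ADC equals MD exactly (trace invariance)
  lam <- c(1.6e-3, 0.9e-3, 0.59e-3)
  set.seed(41)
  for (i in 1:20) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    d <- diag(lam)
    adc3 <- vapply(1:3, function(k) {
      g <- q[, k]
      dg <- drop(t(g) %*% d %*% g)
      s_low <- attenuate(1000, 50, dg)
      s_high <- attenuate(1000, 450, dg)
      adc_from_pair(s_low, s_high, 50, 450)$adc
    }, numeric(1))
    expect_equal(mean_adc(adc3), mean(lam), tolerance = 1e-12)
  }
})

test_that("weighted fit agrees with OLS on noiseless data", {
  ph <- build_phantom(small_spec())
  t_ols <- fit_tensor(ph$stack, ph$geom$mask)
  t_wls <- fit_tensor(ph$stack, ph$geom$mask, weighted = TRUE)
  expect_all_close((t_wls$tensors - t_ols$tensors) / max(abs(t_ols$tensors)),
                   0, 1e-9)
})
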