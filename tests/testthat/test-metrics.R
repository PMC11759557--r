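test_that("septal ROI spans the insertion arc and excludes trabeculation", {
  ph <- default_phantom()
  roi <- septal_roi(ph$contours, ph$stack$grid, ph$geom$mask)
  expect_equal(roi$arc_deg, 120, tolerance = 1e-6)
  # every ROI voxel's polar angle lies between the landmarks
  ctr <- cdtikit:::grid_centers(ph$stack$grid)
  cen <- colMeans(ph$contours$endo)
  ang <- atan2(ctr$y - cen[2], ctr$x - cen[1]) * 180 / pi
  expect_true(all(abs(ang[roi$roi]) <= 60 + 1e-6))
  # full transmural extent
  depth <- ph$geom$depth[roi$roi]
  expect_lt(min(depth), 5); expect_gt(max(depth), 95)
  # six equal-angle segments cover the myocardium
  seg <- roi$segments[ph$geom$mask]
  expect_setequal(unique(seg), 1:6)
  expect_lt(diff(range(tabulate(seg, 6))) / mean(tabulate(seg, 6)), 0.2)
  # trabeculation blobs inside the arc are excluded from the ROI
  phT <- build_phantom(phantom_spec(trabeculation = c(0, 1.5)))
  roiT <- septal_roi(phT$contours, phT$stack$grid, phT$geom$mask)
  trab <- phT$geom$trabeculation_mask
  expect_gt(sum(trab), 0)
  expect_equal(sum(roiT$roi & trab), 0L)
  # landmarks are mandatory; tiny ROIs are refused
  no_lm <- lv_contours(ph$contours$endo, ph$contours$epi)
  expect_error(septal_roi(no_lm, ph$stack$grid, ph$geom$mask), "landmarks")
  expect_error(septal_roi(ph$contours, ph$stack$grid, ph$geom$mask,
                          min_voxels = 1e5), "below the minimum")
})

test_that("transmural profile follows the prescribed line and handles wrap and gaps", {
  ph <- default_phantom()
  tr <- ph$truth
  prof <- transmural_profile(tr$ha, tr$depth)
  expect_equal(nrow(prof), 10L)
  # bin means lie on the prescribed line evaluated at each bin's actual mean
  # voxel depth (exact for a linear profile), and near the bin centers
  bin <- cut(tr$depth, seq(0, 100, 10), include.lowest = TRUE, labels = FALSE)
  d_mean <- tapply(tr$depth, bin, mean)
  expect_all_close(prof$ha - (50 - d_mean), 0, 0.05)
  expect_all_close(prof$ha - (50 - prof$depth), 0, 1.5)
  # constant-HA phantom: all bins equal
  flat <- prescribe_microstructure(phantom_spec(ha_endo = 30, ha_epi = 30))
  pf <- transmural_profile(flat$ha, flat$depth)
  expect_all_close(pf$ha - 30, 0, 1e-9)
  # profile crossing the +/-90 wrap: unwrapped monotone, no 180-degree jumps
  set.seed(61)
  d <- runif(4000, 0, 100)
  theta <- 70 + 0.4 * d                       # 70 -> 110 degrees
  wrapped <- ((theta + 90) %% 180) - 90
  pw <- transmural_profile(wrapped, d)
  expect_all_close(pw$ha - (70 + 0.4 * pw$depth), 0, 1.0)
  expect_true(all(abs(diff(pw$ha)) < 20))
  # angles near +90 and just above -90 are axial near-neighbors, not a mean
  # near zero
  pair <- transmural_profile(rep(c(89, -89), 50), rep(seq(5, 95, 10), 10),
                             n_bins = 10)
  expect_true(all(abs(abs(pair$ha) - 90) < 1.5))
  # too few populated bins is an error
  expect_error(transmural_profile(rep(10, 50), rep(c(5, 15, 25), 17)[1:50]),
               "populated depth bins")
})

test_that("HAT slope, units identity, and HA range", {
  ph <- default_phantom()
  tr <- ph$truth
  prof <- transmural_profile(tr$ha, tr$depth)
  hat <- ha_transmurality(prof, mean(tr$frames$wall_thickness))
  expect_equal(hat$hat_per_percent, -1, tolerance = 0.01)
  expect_equal(hat$hat_per_mm * mean(tr$frames$wall_thickness),
               hat$hat_per_percent * 100, tolerance = 1e-9)
  expect_equal(hat$ha_range, 100, tolerance = 1)
  # bin-mean extremes understate the surface-to-surface range by a bin width
  expect_equal(hat$ha_range_bins, 90, tolerance = 1)
  expect_equal(hat$ha_endo, 50, tolerance = 0.5)
  expect_equal(hat$ha_epi, -50, tolerance = 0.5)
  # slope is invariant to a uniform HA offset
  prof2 <- prof; prof2$ha <- prof$ha + 20
  hat2 <- ha_transmurality(prof2, 7)
  expect_equal(hat2$hat_per_percent, hat$hat_per_percent, tolerance = 1e-12)
  # constant profile: zero slope, zero range
  pf <- prof; pf$ha <- rep(30, 10)
  hat0 <- ha_transmurality(pf, 7)
  expect_equal(hat0$hat_per_percent, 0, tolerance = 1e-12)
  expect_equal(hat0$ha_range, 0, tolerance = 1e-9)
  expect_error(ha_transmurality(prof[1:2, ], 7), "3 populated bins")
})

test_that("E2A mobility semantics", {
  m <- e2a_mobility(62, 13)
  expect_equal(m$mobility, 49)
  expect_false(m$reduced_flag)
  expect_equal(e2a_mobility(40, 40)$mobility, 0)
  # vectors are reduced by the median of absolute values
  expect_equal(e2a_mobility(c(60, 62, 64), c(-13, 13, 15))$mobility, 62 - 13)
  rev <- e2a_mobility(10, 30)
  expect_equal(rev$mobility, -20)
  expect_true(rev$reduced_flag)
})

test_that("normal-range QC separates sequences and hard-flags free-water MD", {
  fake_summary <- function(md, fa, e2a, ha_range = 100, hat = -1) {
    structure(list(md = c(median = md), fa = c(median = fa),
                   e2a = c(median = e2a),
                   hat = list(ha_range = ha_range, hat_per_percent = hat)),
              class = "summary_metrics")
  }
  s <- fake_summary(1.03e-3, 0.47, 62)
  qc <- normal_range_qc(s, "STEAM", "systole")
  expect_true(all(qc$in_range))
  expect_false(any(qc$hard_flag))
  # free-water ceiling: always hard-flagged
  bad <- normal_range_qc(fake_summary(3.2e-3, 0.47, 62), "STEAM", "systole")
  expect_true(bad$hard_flag[bad$metric == "md"])
  # MCSE systolic FA 0.36: in range under MCSE, out of range under STEAM
  qc_mcse <- normal_range_qc(fake_summary(1.45e-3, 0.36, 38), "MCSE", "systole")
  expect_true(all(qc_mcse$in_range))
  qc_cross <- normal_range_qc(fake_summary(1.45e-3, 0.36, 38), "STEAM", "systole")
  expect_false(qc_cross$in_range[qc_cross$metric == "fa"])
  # HAT has no printed typical range: the mean +/- 2 SD rule fires
  expect_equal(unique(qc$rule[qc$metric == "hat_per_percent"]), "mean_pm_2sd")
  # unknown sequence/phase combination errors
  expect_error(normal_range_qc(fake_summary(1.4e-3, 0.4, 38), "MCSE",
                               "diastole"), "no reference entry")
})

test_that("ROI summaries match prescription exactly when noiseless, within normals at SNR 20", {
  ph <- default_phantom()
  res <- run_pipeline(ph$stack, ph$contours)
  expect_equal(unname(res$summary$md["median"]), 1.03e-3, tolerance = 1e-9)
  expect_equal(unname(res$summary$fa["median"]), 0.47, tolerance = 1e-7)
  expect_equal(unname(res$summary$e2a["median"]), 62, tolerance = 1e-6)
  expect_true(all(res$qc_flags$in_range))
  # prescribed at the centers of the typical ranges, SNR 20, 10 seeds:
  # septal medians stay inside the published typical ranges
  lam <- eigenvalues_from_md_fa(1.0e-3, 0.47)
  for (s in 1:10) {
    phn <- build_phantom(phantom_spec(eigenvalues = lam, snr = 20,
                                      seed = 200L + s))
    resn <- run_pipeline(phn$stack, phn$contours)
    expect_gt(unname(resn$summary$md["median"]), 0.8e-3)
    expect_lt(unname(resn$summary$md["median"]), 1.2e-3)
    expect_gt(unname(resn$summary$fa["median"]), 0.43)
    expect_lt(unname(resn$summary$fa["median"]), 0.51)
  }
})

test_that("report files carry the summary, flags and parameter manifest", {
  ph <- default_phantom()
  res <- run_pipeline(ph$stack, ph$contours)
  prefix <- file.path(withr::local_tempdir(), "phantom")
  gt <- ph$stack$table
  gt$metadata <- list(te = 25, n_directions = 12)
  write_report(res$summary, res$qc_flags, gt, prefix)
  sm <- read.csv(paste0(prefix, "_summary.csv"))
  expect_equal(sm$value[sm$metric == "hat_per_percent"],
               res$summary$hat$hat_per_percent)
  man <- readLines(paste0(prefix, "_parameters.txt"))
  expect_true(any(grepl("^te: 25", man)))
  expect_true(any(grepl("^fov: missing", man)))
})
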