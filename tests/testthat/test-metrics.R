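# a minimal stack/region pair for synthetic-array metric tests:
# 100 x 70 x 4 voxels of 2 x 2 x 4 um, gel strip y in [40, 240],
# opening x in [30, 110]
mk_env <- function() {
  geom <- test_geom(nz = 4L)
  arr <- array(0, c(140, 70, 4))
  st <- image_stack(list(cyto = arr, hoechst = arr), c(4, 2, 2))
  reg <- gel_region(list(line1 = c(intercept = 40, angle_deg = 0),
                         line2 = c(intercept = 240, angle_deg = 0)),
                    lateral_bounds = c(30, 110))
  list(geom = geom, stack = st, region = reg,
       curve = monolayer_curve(c(0, 47, 93, 140), rep(40, 4)))
}

test_that("integration region covers the offset gel strip to within a voxel layer", {
  e <- mk_env()
  m0 <- integration_region(e$stack, e$region, e$curve, 0)
  area0 <- sum(m0$mask2d) * 4               # pixel area 2x2 um
  expect_equal(area0, 200 * 80, tolerance = 2 * 80 * 2 / (200 * 80) * 1.5)

  m10 <- integration_region(e$stack, e$region, e$curve, 10)
  area10 <- sum(m10$mask2d) * 4
  expect_equal(area10, (200 - 10) * 80,
               tolerance = 2 * 80 * 2 / (190 * 80) * 1.5)

  expect_error(integration_region(e$stack, e$region, e$curve, 200),
               "empty")
})

test_that("offset monotonicity: M and J never increase with the offset", {
  r <- recover_phantom(4)
  vals <- t(sapply(c(0, 5, 10, 20, 40), function(d) {
    m <- compute_metrics(r$stack, r$region, r$curve, d)
    c(m$M_cyto, m$J_cyto)
  }))
  expect_true(all(diff(vals[, 1]) <= 1e-9))
  expect_true(all(diff(vals[, 2]) <= 1e-9))
})

test_that("distance fields are exact for straight curves and match brute force for splines", {
  e <- mk_env()
  f <- distance_field(e$stack, e$curve)
  # voxel centered at y = 65 um sits 25 um from the curve at y = 40
  iy <- which(abs((seq_len(140) - 0.5) * 2 - 65) < 1)[1]
  expect_equal(f$r[iy, 10], 65 - 40, tolerance = 1e-6)

  # rigid invariance: translating curve and query together leaves r fixed
  cv2 <- monolayer_curve(e$curve$control_u, e$curve$control_r + 30)
  f2 <- distance_field(e$stack, cv2)
  expect_equal(f2$r[iy + 15, 10], f$r[iy, 10], tolerance = 1e-6)

  # sinusoidal curve vs dense nearest-point search
  u4 <- c(0, 47, 93, 140)
  cvs <- monolayer_curve(u4, 60 + 15 * sin(u4 / 140 * pi))
  fs <- distance_field(e$stack, cvs)
  uu <- seq(-20, 160, by = 0.02)
  cxy <- cbind(uu, curve_eval(cvs, uu))
  for (pt in list(c(60, 100), c(20, 150), c(120, 80))) {
    iy <- round(pt[2] / 2 + 0.5); ix <- round(pt[1] / 2 + 0.5)
    px <- (ix - 0.5) * 2; py <- (iy - 0.5) * 2
    d_brute <- sqrt(min((cxy[, 1] - px)^2 + (cxy[, 2] - py)^2))
    expect_equal(abs(fs$r[iy, ix]), d_brute, tolerance = 0.1)
  }
})

test_that("total integral and first moment follow their defining sums", {
  e <- mk_env()
  mask <- integration_region(e$stack, e$region, e$curve, 0)
  vol <- 2 * 2 * 4

  # uniform cube strictly inside the mask
  sig <- array(0, c(140, 70, 4))
  sig[40:49, 20:29, 1:4] <- 1          # 10 x 10 x 4 voxels
  expect_equal(total_integral(sig, mask), 10 * 10 * 4 * vol)
  expect_equal(total_integral(array(0, dim(sig)), mask), 0)

  # additivity over disjoint blobs
  sig2 <- array(0, c(140, 70, 4))
  sig2[60:64, 40:44, 1:2] <- 0.5
  both <- sig + sig2
  expect_equal(total_integral(both, mask),
               total_integral(sig, mask) + total_integral(sig2, mask))

  # point-like blob at r = 40: J = 40 M
  f <- mask$field
  blob <- array(0, c(140, 70, 4))
  iy <- which(abs(f$r[, 35] - 40) < 1)[1]
  blob[iy, 35, 2] <- 1
  expect_equal(first_moment(blob, mask) / total_integral(blob, mask),
               f$r[iy, 35], tolerance = 1e-9)

  # uniform rod spanning r in [10, 60]: centroid at 35 um
  rod <- array(0, c(140, 70, 4))
  rows <- which(f$r[, 35] >= 10 & f$r[, 35] <= 60)
  rod[rows, 35, ] <- 1
  expect_equal(first_moment(rod, mask) / total_integral(rod, mask), 35,
               tolerance = 1)
})

test_that("aspect ratio behaves like penetration over lateral spread", {
  e <- mk_env()
  mask <- integration_region(e$stack, e$region, e$curve, 0)
  f <- mask$field

  # isotropic thin disc centered at r0 = 150: AR ~ r0 / mean lateral dev
  sig <- array(0, c(140, 70, 4))
  ys <- (seq_len(140) - 0.5) * 2; xs <- (seq_len(70) - 0.5) * 2
  R <- 20; r0 <- 150; u0 <- 70
  d2 <- outer((ys - (40 + r0))^2, (xs - u0)^2, `+`)
  sig[, , 2][d2 <= R^2] <- 1
  ar <- aspect_ratio(sig, mask)
  # mean |u - ubar| over a uniform disc of radius R is 4R/(3 pi)
  expect_equal(as.numeric(ar), r0 / (4 * R / (3 * pi)), tolerance = 0.1)

  # mirror symmetry about the sprout axis leaves AR unchanged
  sigm <- sig[, rev(seq_len(70)), , drop = FALSE]
  expect_equal(as.numeric(aspect_ratio(sigm, mask)), as.numeric(ar),
               tolerance = 0.05)

  expect_true(is.na(aspect_ratio(array(0, dim(sig)), mask)))
})

test_that("elongating a sprout at fixed radius strictly increases AR", {
  geom <- test_geom(); ml <- test_monolayer(geom)
  ars <- sapply(c(20, 40, 80), function(L) {
    ph <- render_stack(geom, ml,
                       list(sprout_spec(70, 0, L, 10, n_nuclei = 1L)),
                       noise_spec(0, 0, 1))
    reg <- detect_gel_boundaries(preprocess_stack(ph$stack), geom)
    compute_metrics(preprocess_stack(ph$stack), reg, ml, 10)$AR_cyto
  })
  expect_true(all(diff(ars) > 0))
})

test_that("pipeline metrics recover analytic truth on noiseless phantoms", {
  r <- recover_phantom(1, sd = 0)
  expect_lt(abs(r$M_rel), 0.05)
  expect_lt(abs(r$J_rel), 0.05)
  expect_lt(abs(r$Mh_rel), 0.08)
})

test_that("nuclear metrics recover analytic truth at nucleus-resolving sampling", {
  geom <- test_geom(nz = 16L, vz = 2)
  ml <- test_monolayer(geom)
  sp <- list(sprout_spec(60, 0, 80, 12, n_nuclei = 3L, nucleus_radius_um = 7),
             sprout_spec(88, 5, 70, 12, n_nuclei = 3L, nucleus_radius_um = 7))
  ph <- render_stack(geom, ml, sp, noise_spec(0, 0, 1))
  pp <- preprocess_stack(ph$stack)
  reg <- detect_gel_boundaries(pp, geom)
  m <- compute_metrics(pp, reg, ml, 10)
  gt <- ph$ground_truth$metrics_true
  expect_equal(m$M_hoechst, gt$M_hoechst, tolerance = 0.05)
  expect_equal(m$J_hoechst, gt$J_hoechst, tolerance = 0.05)
})

test_that("empty-gel phantoms give zero metrics with AR flagged", {
  geom <- test_geom(); ml <- test_monolayer(geom)
  ph <- render_stack(geom, ml, list(), noise_spec(0, 0, 1),
                     blur_sigma_px = 0)
  reg <- suppressWarnings(detect_gel_boundaries(
    suppressWarnings(preprocess_stack(ph$stack)), geom))
  m <- suppressWarnings(
    compute_metrics(suppressWarnings(preprocess_stack(ph$stack)), reg, ml, 10))
  expect_equal(m$M_cyto, 0, tolerance = 1e-6)
  expect_equal(m$J_cyto, 0, tolerance = 1e-4)
  expect_true(any(grepl("AR_undefined", m$flags)))
})

test_that("cytosolic and nuclear metrics are channel-independent", {
  r <- recover_phantom(2)
  st <- r$stack
  st$channels$hoechst <- st$channels$hoechst * 2
  m2 <- compute_metrics(st, r$region, r$curve, 10)
  expect_identical(m2$M_cyto, r$metrics$M_cyto)
  expect_identical(m2$J_cyto, r$metrics$J_cyto)
  expect_equal(m2$M_hoechst, 2 * r$metrics$M_hoechst, tolerance = 1e-9)
})

test_that("differential metrics subtract records and enforce identifiers", {
  m0 <- angiogenic_metrics(10, 100, 2, 5, 50, 3, "0hr", "dev", 1L)
  m48 <- angiogenic_metrics(25, 300, 2.5, 9, 120, 3.5, "48hr", "dev", 1L)
  d <- differential_metrics(m0, m48)
  expect_equal(d$M_cyto, 15)
  expect_equal(d$J_cyto, 200)
  expect_equal(d$AR_cyto, 0.5)
  expect_identical(d$timepoint_label, "diff")

  same <- differential_metrics(m0, m0)
  expect_equal(same$M_cyto, 0)
  expect_equal(same$J_cyto, 0)

  dbl <- differential_metrics(m0, angiogenic_metrics(20, 200, 2, 10, 100, 3,
                                                     "48hr", "dev", 1L))
  expect_equal(dbl$M_cyto, m0$M_cyto)

  other <- angiogenic_metrics(1, 1, 1, 1, 1, 1, "48hr", "dev", 2L)
  expect_error(differential_metrics(m0, other), "identifiers")
})

test_that("zero-mean noise below the background threshold barely moves M", {
  r <- recover_phantom(3)
  thr <- r$stack$meta$background$cyto$threshold
  pert <- r$stack
  set.seed(9)
  eps <- array(rnorm(length(pert$channels$cyto), 0, thr / 6),
               dim(pert$channels$cyto))
  pert$channels$cyto <- pmax(pert$channels$cyto + eps, 0)
  pert$channels$cyto[pert$channels$cyto <= thr] <- 0
  m2 <- compute_metrics(pert, r$region, r$curve, 10)
  expect_equal(m2$M_cyto, r$metrics$M_cyto, tolerance = 0.01)
})
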