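test_that("device geometry defaults describe the study device and overrides validate", {
  g <- device_geometry()
  expect_identical(g$n_regions, 37L)
  expect_equal(g$post_base_angle_deg, 60)
  expect_equal(g$post_spacing_um, 100)
  expect_equal(g$gel_width_um, 1300)
  expect_true(g$stack_depth_um >= 150 && g$stack_depth_um <= 170)
  expect_true(g$n_z_sections >= 18 - 1 && g$n_z_sections <= 20)

  g1 <- device_geometry(n_regions = 1)
  expect_identical(g1$n_regions, 1L)
  expect_equal(g1$gel_width_um, g$gel_width_um)

  expect_error(device_geometry(post_spacing_um = -5), "post_spacing_um")
  expect_error(device_geometry(post_base_angle_deg = 95), "post_base_angle_deg")
  expect_error(device_geometry(nonsense = 1), "unknown")
})

test_that("closed-form ground-truth metrics match a numeric quadrature oracle", {
  ml <- test_monolayer()
  s <- 0.8; rho <- 7; L <- 60
  for (d in c(0, 10, 25)) {
    gt <- ground_truth_metrics(list(sprout_spec(70, 0, L, rho, s,
                                                n_nuclei = 0L)), ml, d)
    expect_equal(gt$M_cyto, s * pi * rho^2 * (L - d), tolerance = 1e-10)
    expect_equal(gt$J_cyto, s * pi * rho^2 * (L^2 - d^2) / 2,
                 tolerance = 1e-10)
    # independent oracle: midpoint quadrature over the cylinder volume
    tt <- seq(0, L, length.out = 2001); dt <- tt[2] - tt[1]
    area <- pi * rho^2
    keep <- tt >= d
    M_or <- s * area * sum(keep) * dt
    J_or <- s * area * sum(tt[keep]) * dt
    expect_equal(gt$M_cyto, M_or, tolerance = 1e-3)
    expect_equal(gt$J_cyto, J_or, tolerance = 1e-3)
  }
})

test_that("angled sprouts and clipped nuclei follow the analytic geometry", {
  ml <- test_monolayer()
  th <- 20 * pi / 180
  gt <- ground_truth_metrics(list(sprout_spec(70, 20, 60, 8, 1,
                                              n_nuclei = 0L)), ml, 10)
  expect_equal(gt$M_cyto, pi * 64 * (60 - 10 / cos(th)), tolerance = 1e-10)
  expect_equal(gt$J_cyto, pi * 64 * cos(th) * (60^2 - (10 / cos(th))^2) / 2,
               tolerance = 1e-10)

  # one nucleus centered exactly on the offset plane: exactly half its
  # volume (and the corresponding cap moment) lies beyond it
  sp <- sprout_spec(70, 0, 20, 8, 0.8, n_nuclei = 1L, nucleus_radius_um = 6)
  gt2 <- ground_truth_metrics(list(sp), ml, offset_um = 10)
  expect_equal(gt2$M_hoechst, 0.5 * 4 / 3 * pi * 6^3, tolerance = 1e-10)
})

test_that("ground-truth metrics are exactly additive over disjoint sprouts", {
  ml <- test_monolayer()
  a <- sprout_spec(50, 0, 50, 8, 0.6, n_nuclei = 2L)
  b <- sprout_spec(90, 10, 70, 10, 0.9, n_nuclei = 3L)
  ga <- ground_truth_metrics(list(a), ml, 10)
  gb <- ground_truth_metrics(list(b), ml, 10)
  gab <- ground_truth_metrics(list(a, b), ml, 10)
  expect_equal(gab$M_cyto, ga$M_cyto + gb$M_cyto, tolerance = 1e-12)
  expect_equal(gab$J_cyto, ga$J_cyto + gb$J_cyto, tolerance = 1e-12)
  expect_equal(gab$M_hoechst, ga$M_hoechst + gb$M_hoechst, tolerance = 1e-12)
  expect_equal(gab$J_hoechst, ga$J_hoechst + gb$J_hoechst, tolerance = 1e-12)
})

test_that("empty sprout list yields zero metrics with AR flagged", {
  gt <- ground_truth_metrics(list(), test_monolayer(), 10)
  expect_equal(gt$M_cyto, 0)
  expect_equal(gt$J_cyto, 0)
  expect_true(is.na(gt$AR_cyto))
  expect_true("AR_undefined" %in% gt$flags)
})

test_that("rendering reproduces structures: empty gel, cylinder volume, seeds", {
  geom <- test_geom(); ml <- test_monolayer(geom)

  # no sprouts, no noise: cytosolic signal only near the monolayer band
  ph0 <- render_stack(geom, ml, list(), noise_spec(0, 0, 1))
  cyto <- ph0$stack$channels$cyto
  ys <- (seq_len(dim(cyto)[1]) - 0.5) * 2
  far <- ys > 48 + 15 | ys < 48 - 15
  expect_lt(max(cyto[far, , ]), 1e-6)
  expect_equal(ph0$ground_truth$metrics_true$M_cyto, 0)

  # one perpendicular sprout, no noise, no blur: voxel sum ~ cylinder volume
  sp <- sprout_spec(70, 0, 60, 12, 0.8, n_nuclei = 0L)
  ph1 <- render_stack(geom, ml, list(sp), noise_spec(0, 0, 1),
                      blur_sigma_px = 0)
  vol_vox <- 2 * 2 * 4
  mask_far <- array(rep(matrix(ys > 60, length(ys), dim(cyto)[2]), 8),
                    dim(cyto))   # past the band, sprout only
  got <- sum(ph1$stack$channels$cyto[mask_far]) * vol_vox
  want <- 0.8 * pi * 12^2 * (60 - 12)  # cylinder beyond y = 60
  expect_equal(got, want, tolerance = 0.05)

  # seed contract: identical structures, different noise fields
  pha <- render_stack(geom, ml, list(sp), noise_spec(0.1, 0.05, 1))
  phb <- render_stack(geom, ml, list(sp), noise_spec(0.1, 0.05, 2))
  phc <- render_stack(geom, ml, list(sp), noise_spec(0.1, 0.05, 1))
  expect_identical(pha$stack$channels$cyto, phc$stack$channels$cyto)
  expect_false(identical(pha$stack$channels$cyto, phb$stack$channels$cyto))
  expect_identical(pha$ground_truth$metrics_true$M_cyto,
                   phb$ground_truth$metrics_true$M_cyto)
})

test_that("rendered reflectance histograms are bimodal with well-separated modes", {
  geom <- test_geom(); ml <- test_monolayer(geom)
  for (seed in 1:3) {
    ph <- render_stack(geom, ml, test_sprouts(), noise_spec(0.1, 0.05, seed))
    v <- as.vector(ph$stack$channels$reflect)
    thr <- stats::quantile(v, 0.5)
    lo <- v[v <= thr]; hi <- v[v > thr]
    # split at the gel/PDMS midpoint: modes > 4x the intra-mode SD apart
    mid <- (mean(lo) + mean(hi)) / 2
    lo <- v[v <= mid]; hi <- v[v > mid]
    expect_gt(mean(hi) - mean(lo), 4 * max(sd(lo), sd(hi)))
  }
})

test_that("sprouts leaving the growth region warn and are recorded as clipped", {
  geom <- test_geom(); ml <- test_monolayer(geom)
  long <- sprout_spec(70, 45, 120, 8)   # heads toward the lateral post face
  expect_warning(ph <- render_stack(geom, ml, list(long),
                                    noise_spec(0, 0, 1)), "clipped")
  expect_true(ph$ground_truth$clipped[1])
})
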