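small_tgeom <- function() device_geometry(n_regions = 6)

test_that("Peclet calculators follow their formulas", {
  expect_equal(peclet(1e-4, 5e-4, 1.5e-2, 5e-11), 33.3, tolerance = 1e-2)
  expect_equal(peclet(1e-4, 5e-4, 1.5e-2, Inf), 0)
  expect_equal(peclet(2e-4, 5e-4, 1.5e-2, 5e-11),
               2 * peclet(1e-4, 5e-4, 1.5e-2, 5e-11))
  expect_equal(peclet_axial(1e-4, 1.5e-2, 5e-11), 3e4)
})

test_that("Young-Laplace pressure handles symmetry, flat directions and errors", {
  expect_equal(laplace_pressure(0.07, 50e-6, 50e-6), 2 * 0.07 / 50e-6)
  expect_equal(laplace_pressure(0.07, Inf, 60e-6), 0.07 / 60e-6)
  expect_equal(laplace_pressure(0.07, 50e-6, 60e-6), 2566.667,
               tolerance = 1e-4)
  expect_error(laplace_pressure(0.07, -1e-6, 60e-6), "positive")
})

test_that("post angle is supplementary to the contact angle", {
  expect_identical(supplement_angle(120), 60)
  expect_identical(supplement_angle(90), 90)
  expect_identical(supplement_angle(60), 120)
  expect_error(supplement_angle(0), "contact_angle_deg")
  expect_error(supplement_angle(180), "contact_angle_deg")
})

test_that("zero-flow diffusion across a uniform strip is linear with midpoint 30", {
  cfg <- transport_config(flow_rate_ul_min = Inf, geom = small_tgeom(),
                          include_posts = FALSE, dx_um = 50)
  f <- solve_steady(cfg)
  gel <- f$gel_rows
  cj <- round(ncol(f$C) / 2)
  prof <- f$C[gel, cj]; ys <- f$y[gel]
  mid <- stats::approx(ys, prof, xout = mean(range(ys)))$y
  expect_equal(mid, 30, tolerance = 0.01 * 30)
  fit <- stats::lm(prof ~ ys)
  expect_lt(max(abs(stats::resid(fit))), 0.01 * diff(range(prof)))

  # equal source and sink -> uniform field
  cfg2 <- transport_config(flow_rate_ul_min = Inf, geom = small_tgeom(),
                           C_source = 25, C_sink = 25, dx_um = 50)
  f2 <- solve_steady(cfg2)
  expect_equal(range(f2$C, na.rm = TRUE), c(25, 25), tolerance = 1e-9)
})

test_that("the maximum principle holds on every solved field", {
  for (cfg in list(
    transport_config(flow_rate_ul_min = 1, geom = small_tgeom(), dx_um = 50),
    transport_config(flow_rate_ul_min = 0.01, geom = small_tgeom(),
                     dx_um = 50),
    transport_config(flow_rate_ul_min = Inf, geom = small_tgeom(),
                     dx_um = 50),
    transport_config(flow_rate_ul_min = 1, geom = small_tgeom(), dx_um = 50,
                     gel_port_sink = TRUE),
    transport_config(flow_rate_ul_min = 0, geom = small_tgeom(),
                     dx_um = 50))) {
    f <- solve_steady(cfg)
    expect_gte(min(f$C, na.rm = TRUE), cfg$C_sink - 1e-9)
    expect_lte(max(f$C, na.rm = TRUE), cfg$C_source + 1e-9)
    expect_lt(f$residual, 1e-8)
  }
})

test_that("axial uniformity improves with flow rate and is zero for ideal channels", {
  g <- small_tgeom()
  u <- sapply(c(0.01, 0.1, 1), function(q)
    axial_uniformity(solve_steady(transport_config(flow_rate_ul_min = q,
                                                   geom = g, dx_um = 50))))
  expect_true(all(diff(u) < 0))
  # idealized fixed-concentration channels on the smooth domain: the
  # field is axially uniform to solver precision
  ideal <- axial_uniformity(solve_steady(
    transport_config(flow_rate_ul_min = Inf, geom = g, dx_um = 50,
                     include_posts = FALSE)))
  expect_lt(ideal, 1e-9)
})

test_that("cross-gel profiles far apart agree at high flow", {
  g <- device_geometry(n_regions = 12)
  f <- solve_steady(transport_config(flow_rate_ul_min = 1, geom = g,
                                     dx_um = 50))
  gr <- region_gradients(f)
  # regions 10 apart (2 and 12 would touch the ports; use 2 and 11)
  expect_equal(gr$grad_end[11], gr$grad_end[2], tolerance = 0.05)
})

test_that("a gel-port sink steepens the outermost region gradients", {
  f <- solve_steady(transport_config(flow_rate_ul_min = 1,
                                     geom = small_tgeom(), dx_um = 50,
                                     gel_port_sink = TRUE))
  gr <- region_gradients(f)
  inner <- gr$grad_max[3:4]
  expect_gt(gr$grad_max[1], max(inner))
  expect_gt(gr$grad_max[nrow(gr)], max(inner))
})

test_that("halving the grid changes the mid-gel gradient by under 2 percent", {
  g <- small_tgeom()
  slope_mid <- function(dx) {
    f <- solve_steady(transport_config(flow_rate_ul_min = 1, geom = g,
                                       include_posts = FALSE, dx_um = dx))
    cj <- round(ncol(f$C) / 2)
    prof <- f$C[f$gel_rows, cj]; ys <- f$y[f$gel_rows]
    core <- ys > stats::quantile(ys, 0.25) & ys < stats::quantile(ys, 0.75)
    unname(stats::coef(stats::lm(prof[core] ~ ys[core]))[2])
  }
  s1 <- slope_mid(50); s2 <- slope_mid(25)
  expect_lt(abs(s2 - s1) / abs(s2), 0.02)
})

test_that("too-coarse grids are rejected", {
  expect_error(transport_config(geom = small_tgeom(), dx_um = 500),
               "4 nodes")
})
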