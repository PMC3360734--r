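test_that("condition definitions carry the published concentrations", {
  vg <- condition_from_table1("VEGF Grad.")
  expect_equal(unname(vg$nominal_average["VEGF"]), 30)
  expect_equal(unname(vg$nominal_gradient["VEGF"]), 20)

  vs <- condition_from_table1("VEGF + S1P")
  expect_equal(unname(vs$nominal_average["S1P"]), 125)
  expect_equal(unname(vs$nominal_gradient["S1P"]), 250)
  expect_equal(unname(vs$nominal_gradient["VEGF"]), 0)

  ctrl <- condition_from_table1("Control")
  expect_true(all(ctrl$nominal_gradient == 0))

  expect_error(condition_from_table1("nonsense"), "valid labels")
})

test_that("aggregation uses devices as the replication unit", {
  tab <- data.frame(condition = "c", device = "d1", region = 1:3,
                    timepoint = "diff", M_cyto = c(2, 4, 6))
  agg <- aggregate_ensemble(tab)
  expect_equal(agg$devices$mean, 4)
  expect_equal(agg$devices$sd, 2)

  tab2 <- rbind(tab,
                data.frame(condition = "c", device = "d2", region = 1:3,
                           timepoint = "diff", M_cyto = c(4, 5, 6)))
  agg2 <- aggregate_ensemble(tab2)
  expect_equal(agg2$conditions$mean, mean(c(4, 5)))
  expect_equal(agg2$conditions$se, sd(c(4, 5)) / sqrt(2))

  # permutation invariance over record order
  agg3 <- aggregate_ensemble(tab2[sample(nrow(tab2)), ])
  expect_equal(agg3$devices, agg2$devices)

  expect_error(aggregate_ensemble(tab2[0, ]), "empty")
  expect_error(aggregate_ensemble(tab2, "absent"), "absent")
})

test_that("significance markers follow the published thresholds", {
  expect_identical(significance_marker(0.07), "*")
  expect_identical(significance_marker(0.03), "**")
  expect_identical(significance_marker(0.001), "***")
  expect_identical(significance_marker(0.2), "")
})

test_that("t-tests against control behave on degenerate and shifted samples", {
  r <- test_vs_control(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r$p_value, 1)
  expect_identical(r$marker, "")

  set.seed(30)
  x <- rnorm(30, 2, 1); y <- rnorm(30, 0, 1)   # shift = 2 sigma
  r2 <- test_vs_control(x, y)
  expect_lt(r2$p_value, 0.005)
  expect_identical(r2$marker, "***")
  # Welch result matches a direct reference computation
  ref <- stats::t.test(x, y)$p.value
  expect_equal(r2$p_value, ref)

  expect_error(test_vs_control(1, c(1, 2)), "at least 2")
})

test_that("mean-SD regression is exact on exact data and sane on simulations", {
  d <- data.frame(mean = c(1, 2, 5, 10), sd = 0.4 * c(1, 2, 5, 10))
  fit <- mean_sd_regression(d)
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  d2 <- data.frame(mean = c(1, 2, 5, 10), sd = rep(0.7, 4))
  fit2 <- mean_sd_regression(d2)
  expect_equal(fit2$slope, 0, tolerance = 1e-12)

  tab <- simulate_ensemble(14, 37, c(1, 10), 0.4, seed = 42)
  fit3 <- mean_sd_regression(aggregate_ensemble(tab)$devices)
  expect_gt(fit3$slope, 0.3)
  expect_lt(fit3$slope, 0.5)

  expect_error(mean_sd_regression(d[1:2, ]), "3 devices")
})

test_that("the generative model is a seeded gamma process", {
  # expectation: region mean = device mean within 3 SE at n = 1e4
  tab <- simulate_ensemble(1, 1e4, c(5, 5 + 1e-12), 0.4, seed = 7)
  mod <- attr(tab, "model")
  mu <- mod$device_means[1]
  se <- sd(tab$M_cyto) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$M_cyto) - mu), 3 * se)

  # region totals are gamma(shape N, scale mu/N) by construction
  ks <- stats::ks.test(tab$M_cyto, stats::pgamma, shape = mod$N,
                       scale = mu / mod$N)
  expect_gt(ks$p.value, 0.01)

  # determinism and regime checks
  expect_identical(simulate_ensemble(3, 5, c(1, 10), 0.4, seed = 3),
                   simulate_ensemble(3, 5, c(1, 10), 0.4, seed = 3))
  tf <- simulate_ensemble(10, 200, c(2, 20), 0.4, seed = 5,
                          regime = "constant-fano", cell_event_scale = 0.5)
  agg <- aggregate_ensemble(tf)
  # variance ~ scale * mean in the constant-Fano regime
  fano <- agg$devices$sd^2 / agg$devices$mean
  expect_lt(stats::sd(fano) / mean(fano), 0.5)
  expect_equal(mean(fano), 0.5, tolerance = 0.3)
})

test_that("constant-CV scaling: SD-mean slope approaches the CV at many regions", {
  tab <- simulate_ensemble(12, 500, c(1, 10), 0.4, seed = 8)
  fit <- mean_sd_regression(aggregate_ensemble(tab)$devices)
  cv_real <- attr(tab, "model")$cv_realized
  expect_equal(fit$slope, cv_real, tolerance = 0.1)
  expect_lt(abs(fit$intercept), 0.1)
})

test_that("the allocation optimizer matches the brute-force oracle", {
  # the published-scale example: variance ratio 7, overhead 5, budget 200
  m <- allocation_model(sqrt(7), 1, 200, 5)
  a <- optimal_allocation(m); b <- allocation_oracle(m)
  expect_equal(a$n_per_device, b$n_per_device)
  expect_equal(a$n_devices, b$n_devices)
  expect_equal(a$se, b$se)
  # continuous optimum is sqrt(overhead * ratio) ~ 5.9 regions per device
  expect_true(a$n_per_device %in% 5:7)

  set.seed(17)
  for (i in 1:100) {
    m <- allocation_model(runif(1, 0, 5), runif(1, 0.05, 5),
                          sample(10:800, 1), sample(0:12, 1))
    a <- optimal_allocation(m); b <- allocation_oracle(m)
    expect_equal(c(a$n_per_device, a$n_devices),
                 c(b$n_per_device, b$n_devices))
    expect_lte(b$se, a$se + 1e-12)
  }
})

test_that("degenerate allocation models resolve by the declared tie rules", {
  # no between-device variance, no overhead: all m*n = k tie; most devices
  m0 <- allocation_model(1, 0, 60, 0)
  a <- optimal_allocation(m0)
  expect_true(a$tie)
  expect_equal(a$n_per_device, 1)
  expect_equal(a$n_devices, 60)

  # no within-device variance: replicate devices, one region each
  m1 <- allocation_model(0, 1, 60, 2)
  a1 <- optimal_allocation(m1)
  expect_equal(a1$n_per_device, 1)
  expect_equal(a1$n_devices, 20)

  k1 <- allocation_model(1, 1, 1, 0)
  o <- allocation_oracle(k1)
  expect_equal(c(o$n_per_device, o$n_devices), c(1, 1))

  expect_error(allocation_model(1, 1, 10, 10), "overhead")
})

test_that("variance decomposition identities hold on balanced tables", {
  set.seed(1)
  tab <- do.call(rbind, lapply(1:50, function(d)
    data.frame(condition = "c", device = sprintf("d%02d", d), region = 1:37,
               timepoint = "diff",
               M_cyto = rnorm(37, rnorm(1, 20, 1), sqrt(7)))))
  # estimated components recover sigma_d^2 / sigma_m^2 = 7
  vr <- variance_ratio(tab)
  expect_gt(vr, 5); expect_lt(vr, 9)

  # one-way sum-of-squares identity: total = within + between
  v <- tab$M_cyto
  sp <- split(v, tab$device)
  ss_w <- sum(vapply(sp, function(x) sum((x - mean(x))^2), 0))
  ss_b <- sum(vapply(sp, function(x) length(x) * (mean(x) - mean(v))^2, 0))
  expect_equal(ss_w + ss_b, sum((v - mean(v))^2), tolerance = 1e-8)

  # degenerate cases
  t0 <- data.frame(condition = "c", device = rep(c("a", "b"), each = 2),
                   region = c(1, 2, 1, 2), timepoint = "diff",
                   M_cyto = c(3, 3, 9, 9))
  expect_identical(variance_ratio(t0), 0)
  expect_error(variance_ratio(t0[1:2, ]), "2 devices")
})

test_that("allocation SE falls with ensemble size under the published ratio", {
  ses <- sapply(c(50, 100, 400), function(k)
    optimal_allocation(allocation_model(sqrt(7), 1, k, 5))$se)
  expect_true(all(diff(ses) < 0))
})
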