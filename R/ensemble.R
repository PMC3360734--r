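#' Experimental condition definitions
#'
#' Returns the growth-factor composition of one of the four test
#' conditions: the concentrations applied at the monolayer channel and the
#' opposite channel, and the derived nominal average and nominal gradient
#' across the gel region (the arithmetic mean and difference of the two
#' channel values, per species). VEGF in ng/mL, S1P in nM, in excess of
#' basal media.
#'
#' @param label one of `"Control"`, `"VEGF Grad."`, `"VEGF + S1P"`,
#'   `"VEGF Grad. + S1P"`.
#' @return Object of class `condition_spec`.
#' @examples
#' condition_from_table1("VEGF Grad.")$nominal_average  # VEGF 30 ng/mL
#' @export
condition_from_table1 <- function(label) {
  defs <- list(
    "Control"          = list(monolayer = c(VEGF = 0,  S1P = 0),
                              opposite  = c(VEGF = 0,  S1P = 0)),
    "VEGF Grad."       = list(monolayer = c(VEGF = 20, S1P = 0),
                              opposite  = c(VEGF = 40, S1P = 0)),
    "VEGF + S1P"       = list(monolayer = c(VEGF = 20, S1P = 0),
                              opposite  = c(VEGF = 20, S1P = 250)),
    "VEGF Grad. + S1P" = list(monolayer = c(VEGF = 20, S1P = 0),
                              opposite  = c(VEGF = 40, S1P = 250)))
  if (!label %in% names(defs))
    stop("unknown condition label '", label, "'; valid labels: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  d <- defs[[label]]
  structure(list(label = label,
                 monolayer_channel = d$monolayer,
                 opposite_channel = d$opposite,
                 nominal_average = (d$monolayer + d$opposite) / 2,
                 nominal_gradient = d$opposite - d$monolayer,
                 units = c(VEGF = "ng/mL", S1P = "nM")),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("condition '%s':\n", x$label))
  cat(sprintf("  monolayer channel: VEGF %g ng/mL, S1P %g nM\n",
              x$monolayer_channel["VEGF"], x$monolayer_channel["S1P"]))
  cat(sprintf("  opposite channel:  VEGF %g ng/mL, S1P %g nM\n",
              x$opposite_channel["VEGF"], x$opposite_channel["S1P"]))
  cat(sprintf("  nominal average:   VEGF %g ng/mL, S1P %g nM\n",
              x$nominal_average["VEGF"], x$nominal_average["S1P"]))
  cat(sprintf("  nominal gradient:  VEGF %g ng/mL, S1P %g nM per channel\n",
              x$nominal_gradient["VEGF"], x$nominal_gradient["S1P"]))
  invisible(x)
}

.check_table <- function(table, metric) {
  stopifnot(is.data.frame(table))
  need <- c("condition", "device", "region", metric)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("ensemble table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(table)
}

#' Aggregate an ensemble table
#'
#' Device-level means and standard deviations of one metric, plus
#' condition summaries. The device is the independent replication unit:
#' the condition mean is the mean of device means and the condition
#' standard error is the SD of device means over sqrt(number of devices).
#'
#' @param table long-format data.frame with columns `condition`, `device`,
#'   `region` and the metric.
#' @param metric metric column name (e.g. `"M_cyto"`).
#' @return list with `devices` (device, condition, mean, sd, n_regions)
#'   and `conditions` (condition, mean, se, n_devices) data.frames.
#' @export
aggregate_ensemble <- function(table, metric = "M_cyto") {
  .check_table(table, metric)
  if (!nrow(table)) stop("empty ensemble table", call. = FALSE)
  v <- table[[metric]]
  dev <- do.call(rbind, lapply(
    split(table, list(table$condition, table$device), drop = TRUE),
    function(d) data.frame(condition = d$condition[1], device = d$device[1],
                           mean = mean(d[[metric]]),
                           sd = if (nrow(d) >= 2) stats::sd(d[[metric]])
                                else NA_real_,
                           n_regions = nrow(d))))
  rownames(dev) <- NULL
  dev <- dev[order(dev$condition, dev$device), , drop = FALSE]
  cond <- do.call(rbind, lapply(split(dev, dev$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$mean),
               se = if (nrow(d) >= 2) stats::sd(d$mean) / sqrt(nrow(d))
                    else NA_real_,
               n_devices = nrow(d))))
  rownames(cond) <- NULL
  list(devices = dev, conditions = cond)
}

#' Significance marker for a p-value
#'
#' `"*"` for p < 0.1, `"**"` for p < 0.05, `"***"` for p < 0.005,
#' otherwise `""`.
#'
#' @param p p-value.
#' @return Character marker.
#' @export
significance_marker <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.005) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

#' Test a condition against its basal control
#'
#' Two-sample t-test of a condition's metric values against the matched
#' basal-control values (Welch by default; the classical pooled-variance
#' variant is selectable). Degenerate input (zero variance in both groups
#' with equal means) returns p = 1 by convention.
#'
#' @param condition_values,control_values numeric vectors (>= 2 values each).
#' @param var_equal use the pooled-variance t-test.
#' @return list(p_value, marker, estimate, statistic).
#' @export
test_vs_control <- function(condition_values, control_values,
                            var_equal = FALSE) {
  if (length(condition_values) < 2 || length(control_values) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  if (stats::sd(condition_values) == 0 && stats::sd(control_values) == 0) {
    p <- if (mean(condition_values) == mean(control_values)) 1 else 0
    return(list(p_value = p, marker = significance_marker(p),
                estimate = mean(condition_values) - mean(control_values),
                statistic = NA_real_))
  }
  tt <- stats::t.test(condition_values, control_values,
                      var.equal = var_equal)
  list(p_value = tt$p.value, marker = significance_marker(tt$p.value),
       estimate = unname(diff(rev(tt$estimate))),
       statistic = unname(tt$statistic))
}

#' Mean-SD scaling regression
#'
#' Ordinary least squares of the within-device standard deviation on the
#' within-device mean across devices. A strong linear relation (high r2,
#' positive slope through the origin) is the signature of multiplicative
#' noise: responses accumulated from independent exponential cell-level
#' events have SD proportional to the mean.
#'
#' @param device_stats data.frame with columns `mean` and `sd` (one row
#'   per device), e.g. `aggregate_ensemble(...)$devices`.
#' @return list(slope, intercept, r_squared, n).
#' @export
mean_sd_regression <- function(device_stats) {
  d <- device_stats[is.finite(device_stats$mean) &
                      is.finite(device_stats$sd), , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 devices for the mean-SD regression", call. = FALSE)
  fit <- stats::lm(sd ~ mean, data = d)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = nrow(d))
}

#' Simulate an ensemble of device responses
#'
#' Generative model of the stochastic angiogenic response: each region's
#' metric is the sum of independent exponentially distributed cell-level
#' contributions, hence gamma-distributed. Two regimes:
#' \describe{
#'   \item{`constant-cv`}{the number of events per region is fixed at
#'     `N = round(1 / cv^2)` and the event scale varies with the device
#'     mean, so the region-level coefficient of variation is `1/sqrt(N)`
#'     (close to `cv`) at every mean -- SD proportional to the mean
#'     (multiplicative noise).}
#'   \item{`constant-fano`}{the event scale is fixed at
#'     `cell_event_scale` and the event count varies with the device
#'     mean, so the variance (not the SD) is proportional to the mean.}
#' }
#' Device means are log-uniform over `device_mean_range`.
#'
#' @param n_devices,n_regions ensemble size (devices x regions per device).
#' @param device_mean_range length-2 positive range of device means.
#' @param cv target region-level coefficient of variation
#'   (`constant-cv` regime).
#' @param cell_event_scale mean of one exponential event
#'   (`constant-fano` regime).
#' @param seed integer RNG seed.
#' @param regime `"constant-cv"` or `"constant-fano"`.
#' @param metric name of the generated metric column.
#' @param condition condition label stored in the table.
#' @return Long-format data.frame (condition, device, region, timepoint,
#'   metric column) with attribute `model` recording the realized
#'   parameters.
#' @export
simulate_ensemble <- function(n_devices = 14, n_regions = 37,
                              device_mean_range = c(1, 10), cv = 0.4,
                              cell_event_scale = NULL, seed = 1L,
                              regime = c("constant-cv", "constant-fano"),
                              metric = "M_cyto", condition = "simulated") {
  regime <- match.arg(regime)
  .assert_scalar_num(cv, "cv", lower = 0, strict_lower = TRUE)
  if (any(device_mean_range <= 0) || length(device_mean_range) != 2)
    stop("'device_mean_range' must be two positive values", call. = FALSE)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(seed))
  mus <- exp(stats::runif(n_devices, log(device_mean_range[1]),
                          log(device_mean_range[2])))
  if (regime == "constant-cv") {
    N <- max(1L, as.integer(round(1 / cv^2)))
    if (abs(1 / sqrt(N) - cv) / cv > 0.25)
      stop(sprintf("cv = %g is not attainable with an integer event count; nearest feasible cv is %.3f",
                   cv, 1 / sqrt(N)), call. = FALSE)
    draw <- function(mu) {
      ev <- matrix(stats::rexp(n_regions * N, rate = N / mu), n_regions, N)
      rowSums(ev)
    }
    model <- list(regime = regime, N = N, cv_realized = 1 / sqrt(N))
  } else {
    scale <- cell_event_scale %||% (cv^2 * mean(device_mean_range))
    draw <- function(mu) {
      N <- max(1L, as.integer(round(mu / scale)))
      ev <- matrix(stats::rexp(n_regions * N, rate = 1 / scale),
                   n_regions, N)
      rowSums(ev)
    }
    model <- list(regime = regime, cell_event_scale = scale)
  }
  rows <- lapply(seq_len(n_devices), function(i) {
    d <- data.frame(condition = condition,
                    device = sprintf("device%02d", i),
                    region = seq_len(n_regions), timepoint = "diff")
    d[[metric]] <- draw(mus[i])
    d
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- c(model, list(device_means = mus, seed = seed))
  out
}

#' Within/between variance ratio of an ensemble
#'
#' One-way variance-components decomposition of a metric: the pooled
#' within-device (region-to-region) variance `sigma_d^2` divided by the
#' between-device variance component `sigma_m^2`. The between component
#' uses the standard method-of-moments correction -- the raw variance of
#' device means overstates `sigma_m^2` by `sigma_d^2 / n` (the sampling
#' noise of each device mean) -- so the ratio estimates
#' `sigma_d^2 / sigma_m^2`, the quantity steering the allocation model.
#'
#' @inheritParams aggregate_ensemble
#' @return Scalar ratio (within / between); `Inf` when the between
#'   component estimate is zero or negative.
#' @export
variance_ratio <- function(table, metric = "M_cyto") {
  .check_table(table, metric)
  sp <- split(table[[metric]], table$device)
  if (length(sp) < 2)
    stop("need at least 2 devices", call. = FALSE)
  if (any(vapply(sp, length, 1L) < 2))
    stop("need at least 2 regions per device", call. = FALSE)
  within <- mean(vapply(sp, stats::var, 0))
  if (within == 0) return(0)
  n_bar <- mean(vapply(sp, length, 1L))
  between <- stats::var(vapply(sp, mean, 0)) - within / n_bar
  if (between <= 0) return(Inf)
  within / between
}

.allocation_se2 <- function(m, n, sigma_d, sigma_m) {
  sigma_m^2 / m + sigma_d^2 / (m * n)
}

#' Allocation model
#'
#' @param sigma_d within-device (region-to-region) SD.
#' @param sigma_m between-device SD of device means.
#' @param k_total total region budget.
#' @param overhead per-device cost in region-equivalents (each device
#'   consumes `n + overhead` units of the budget).
#' @return Object of class `allocation_model`.
#' @export
allocation_model <- function(sigma_d, sigma_m, k_total, overhead = 5) {
  .assert_scalar_num(sigma_d, "sigma_d", lower = 0)
  .assert_scalar_num(sigma_m, "sigma_m", lower = 0)
  .assert_scalar_num(k_total, "k_total", lower = 1)
  .assert_scalar_num(overhead, "overhead", lower = 0)
  if (sigma_d == 0 && sigma_m == 0)
    stop("at least one of sigma_d, sigma_m must be positive", call. = FALSE)
  if (overhead >= k_total)
    stop("overhead must be smaller than the total budget", call. = FALSE)
  structure(list(sigma_d = sigma_d, sigma_m = sigma_m,
                 k_total = as.integer(k_total), overhead = overhead),
            class = "allocation_model")
}

# shared tie-break: smallest SE, then most devices, then fewest regions
.alloc_better <- function(cand, best, tol = 0) {
  if (is.null(best)) return(TRUE)
  if (cand$se < best$se - tol) return(TRUE)
  if (cand$se > best$se + tol) return(FALSE)
  if (cand$m != best$m) return(cand$m > best$m)
  cand$n < best$n
}

#' Optimal region-per-device allocation
#'
#' Minimizes the standard error of the condition mean,
#' `SE^2 = sigma_m^2 / m + sigma_d^2 / (m n)`, over integer numbers of
#' devices `m` and regions per device `n`, subject to the budget
#' `m (n + overhead) <= k_total`. Large `sigma_d^2 / sigma_m^2` favors
#' more regions per device; large relative between-device variance favors
#' more devices. Ties are broken toward more devices (flagged).
#'
#' @param model an [allocation_model()].
#' @return list(n_per_device, n_devices, se, tie).
#' @export
optimal_allocation <- function(model) {
  stopifnot(inherits(model, "allocation_model"))
  k <- model$k_total; c0 <- model$overhead
  n_max <- floor(k - c0)
  if (n_max < 1) stop("budget admits no feasible allocation", call. = FALSE)
  best <- NULL; tie <- FALSE
  for (n in seq_len(n_max)) {
    m <- floor(k / (n + c0))
    if (m < 1) break
    cand <- list(m = m, n = n,
                 se = sqrt(.allocation_se2(m, n, model$sigma_d,
                                           model$sigma_m)))
    if (!is.null(best) && cand$se == best$se &&
        !(cand$m == best$m && cand$n == best$n)) tie <- TRUE
    if (.alloc_better(cand, best)) best <- cand
  }
  list(n_per_device = best$n, n_devices = best$m, se = best$se, tie = tie)
}

#' Brute-force allocation oracle
#'
#' Exhaustive search over all feasible integer (devices, regions) pairs;
#' the exact arg-min of the allocation standard error under the same cost
#' model and tie-break as [optimal_allocation()].
#'
#' @param model an [allocation_model()] with `k_total <= 1e4`.
#' @return list(n_per_device, n_devices, se).
#' @export
allocation_oracle <- function(model) {
  stopifnot(inherits(model, "allocation_model"))
  k <- model$k_total; c0 <- model$overhead
  if (k > 1e4) stop("oracle restricted to k_total <= 1e4", call. = FALSE)
  best <- NULL
  m_max <- floor(k / (1 + c0))
  for (m in seq_len(max(1, m_max))) {
    n_cap <- floor(k / m - c0)
    if (n_cap < 1) next
    for (n in seq_len(n_cap)) {
      cand <- list(m = m, n = n,
                   se = sqrt(.allocation_se2(m, n, model$sigma_d,
                                             model$sigma_m)))
      if (.alloc_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) stop("budget admits no feasible allocation",
                          call. = FALSE)
  list(n_per_device = best$n, n_devices = best$m, se = best$se)
}
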