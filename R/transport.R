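#' Transport configuration
#'
#' Parameters of the steady chemoattractant transport model: a 2D plan
#' view of the device with two media channels flanking the gel strip and
#' trapezoidal posts partially occluding the gel-channel interfaces.
#' Channel flow is plug advection along x; the gel carries pure diffusion
#' (growth-factor binding is neglected). The channel on the monolayer side
#' holds the sink concentration, the opposite channel the source.
#'
#' @param D_gel,D_med diffusivities (m^2/s); default 5e-11 (40 kDa growth
#'   factor in collagen / medium).
#' @param flow_rate_ul_min channel flow rate (uL/min); `Inf` idealizes the
#'   channels as fixed-concentration boundaries; `0` is pure diffusion.
#' @param C_source,C_sink channel concentrations (arbitrary units).
#' @param geom a [device_geometry()].
#' @param gel_port_sink impose the sink concentration at the gel strip's
#'   axial ends (the gel filling ports).
#' @param include_posts block grid cells inside the post trapezoids.
#' @param dx_um target grid spacing (um).
#' @return Object of class `transport_config`.
#' @export
transport_config <- function(D_gel = 5e-11, D_med = 5e-11,
                             flow_rate_ul_min = 1, C_source = 40,
                             C_sink = 20, geom = device_geometry(),
                             gel_port_sink = FALSE, include_posts = TRUE,
                             dx_um = 50) {
  .assert_scalar_num(D_gel, "D_gel", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(D_med, "D_med", lower = 0, strict_lower = TRUE)
  if (!identical(flow_rate_ul_min, Inf))
    .assert_scalar_num(flow_rate_ul_min, "flow_rate_ul_min", lower = 0)
  .assert_scalar_num(dx_um, "dx_um", lower = 0, strict_lower = TRUE)
  if (geom$gel_width_um / dx_um < 4)
    stop("grid resolution must give at least 4 nodes across the gel gap",
         call. = FALSE)
  structure(list(D_gel = D_gel, D_med = D_med,
                 flow_rate_ul_min = flow_rate_ul_min,
                 C_source = C_source, C_sink = C_sink, geom = geom,
                 gel_port_sink = gel_port_sink,
                 include_posts = include_posts, dx_um = dx_um),
            class = "transport_config")
}

# Post x-intervals along the device: post k (k = 0..n_regions) spans
# [k * period, k * period + post_top].
.device_posts_x <- function(geom) {
  period <- geom$post_top_um + geom$post_spacing_um
  k <- 0:geom$n_regions
  cbind(x0 = k * period, x1 = k * period + geom$post_top_um)
}

# Growth-region center x positions.
.device_region_centers <- function(geom) {
  period <- geom$post_top_um + geom$post_spacing_um
  (seq_len(geom$n_regions) - 1) * period + geom$post_top_um +
    geom$post_spacing_um / 2
}

#' Solve steady advection-diffusion transport in the device
#'
#' Finite-volume discretization on a uniform 2D grid: harmonic-mean face
#' diffusion, first-order upwind advection in the channels, Dirichlet
#' source/sink at the channel inlets, convective outflow at the channel
#' outlets (no diffusive flux, advection carries `u C` out), optional
#' Dirichlet sink at the gel-port ends, no-flux elsewhere and around post
#' cells. The sparse linear system is solved directly.
#'
#' @param config a [transport_config()].
#' @return Object of class `concentration_field`: node coordinates `x`,
#'   `y` (um), concentration matrix `C` (ny x nx, NA at post cells),
#'   relative residual, and the config.
#' @export
solve_steady <- function(config) {
  stopifnot(inherits(config, "transport_config"))
  geom <- config$geom
  dx <- config$dx_um
  period <- geom$post_top_um + geom$post_spacing_um
  Lx <- geom$n_regions * period + geom$post_top_um
  cw <- geom$channel_width_um; gw <- geom$gel_width_um
  Ly <- 2 * cw + gw
  nx <- max(4L, round(Lx / dx)); ny <- max(6L, round(Ly / dx))
  hx <- Lx / nx; hy <- Ly / ny
  xs <- .axis_coords(nx, hx); ys <- .axis_coords(ny, hy)

  in_ch1 <- ys < cw                 # monolayer-side channel (sink)
  in_ch2 <- ys > cw + gw            # opposite channel (source)
  in_gel <- !(in_ch1 | in_ch2)
  if (sum(in_gel) < 4)
    stop("grid resolution must give at least 4 nodes across the gel gap",
         call. = FALSE)

  # post occlusion: trapezoids flush with each interface, extending into
  # the channels; base angle sets the sidewall slope
  blocked <- matrix(FALSE, ny, nx)
  if (config$include_posts) {
    run <- geom$post_depth_um / tan(geom$post_base_angle_deg * pi / 180)
    px <- .device_posts_x(geom)
    for (k in seq_len(nrow(px))) {
      for (side in 1:2) {
        face_y <- if (side == 1) cw else cw + gw
        for (j in which(if (side == 1)
          ys >= face_y - geom$post_depth_um & ys < face_y else
            ys > face_y & ys <= face_y + geom$post_depth_um)) {
          d <- abs(ys[j] - face_y)
          xin <- xs >= px[k, "x0"] - d * run / geom$post_depth_um &
            xs <= px[k, "x1"] + d * run / geom$post_depth_um
          blocked[j, xin] <- TRUE
        }
      }
    }
  }

  Dmap <- matrix(config$D_med, ny, nx)
  Dmap[in_gel, ] <- config$D_gel
  ideal <- identical(config$flow_rate_ul_min, Inf)
  u <- if (ideal || config$flow_rate_ul_min == 0) 0 else
    (config$flow_rate_ul_min * 1e-9 / 60) /
      (geom$channel_width_um * 1e-6 * geom$channel_height_um * 1e-6)

  idx <- matrix(seq_len(ny * nx), ny, nx)
  hx_m <- hx * 1e-6; hy_m <- hy * 1e-6

  dir_val <- matrix(NA_real_, ny, nx)
  if (ideal) {
    dir_val[in_ch1, ] <- config$C_sink
    dir_val[in_ch2, ] <- config$C_source
  } else {
    dir_val[in_ch1, 1] <- config$C_sink
    dir_val[in_ch2, 1] <- config$C_source
  }
  if (config$gel_port_sink) {
    dir_val[in_gel, 1] <- config$C_sink
    dir_val[in_gel, nx] <- config$C_sink
  }
  dir_val[blocked] <- NA_real_

  rhs <- numeric(ny * nx)
  # vectorized assembly: build neighbor tables
  cells <- which(!blocked)
  is_dir <- !is.na(dir_val)
  rowi <- ((cells - 1L) %% ny) + 1L
  colj <- ((cells - 1L) %/% ny) + 1L
  diag_c <- numeric(ny * nx)
  tI <- vector("list", 4); tJ <- vector("list", 4); tX <- vector("list", 4)
  nb_off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  hface <- c(hy_m, hy_m, hx_m, hx_m)
  # plug flow in the clear channel only: the recesses between posts are
  # stagnant (no through-flow), so advection stops one post depth short of
  # each gel interface when posts are modeled
  ui <- matrix(0, ny, nx)
  rec <- if (config$include_posts) geom$post_depth_um else 0
  # a row is stagnant if any part of the cell overlaps the recess, so the
  # flow/stagnation boundary falls on the same grid face at any resolution
  flow1 <- in_ch1 & (ys + hy / 2) <= cw - rec
  flow2 <- in_ch2 & (ys - hy / 2) >= cw + gw + rec
  ui[flow1 | flow2, ] <- u
  ui[blocked] <- 0

  for (q in seq_along(nb_off)) {
    oi <- nb_off[[q]][1]; oj <- nb_off[[q]][2]
    ri <- rowi + oi; cj <- colj + oj
    ok <- ri >= 1L & ri <= ny & cj >= 1L & cj <= nx
    src <- cells[ok]
    nbr <- idx[cbind(ri[ok], cj[ok])]
    open <- !blocked[nbr]
    src <- src[open]; nbr <- nbr[open]
    # harmonic-mean face diffusivity
    Dface <- 2 / (1 / Dmap[src] + 1 / Dmap[nbr])
    cond <- Dface / hface[q]^2
    skip_dir <- is_dir[src]
    src2 <- src[!skip_dir]; nbr2 <- nbr[!skip_dir]; cond2 <- cond[!skip_dir]
    diag_c[src2] <- diag_c[src2] + cond2
    tI[[q]] <- src2; tJ[[q]] <- nbr2; tX[[q]] <- -cond2
    # upwind advection along +x in channels
    if (oj == -1L) {  # neighbor to the left feeds this cell
      uu <- ui[src2]
      adv <- uu / hx_m
      diag_c[src2] <- diag_c[src2] + adv     # outflow u*C_i (to the right)
      tX[[q]] <- tX[[q]] - adv               # inflow u*C_{i-1}
    }
  }
  # right-edge channel cells: advective outflow only (no right neighbor):
  # outflow term u/hx was added above via the left-neighbor pass, which
  # credits every cell's outflow; cells in column nx already have it.

  # Dirichlet rows
  dir_cells <- which(is_dir & !blocked)
  diag_c[dir_cells] <- 1
  rhs[dir_cells] <- dir_val[dir_cells]

  blocked_cells <- which(blocked)
  diag_c[blocked_cells] <- 1
  rhs[blocked_cells] <- 0

  Ai <- c(unlist(tI), seq_len(ny * nx))
  Aj <- c(unlist(tJ), seq_len(ny * nx))
  Ax <- c(unlist(tX), diag_c)
  keep <- Ax != 0 | Ai == Aj
  A <- Matrix::sparseMatrix(i = Ai[keep], j = Aj[keep], x = Ax[keep],
                            dims = c(ny * nx, ny * nx))
  sol <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(A %*% sol - rhs)) / max(abs(rhs), 1)
  if (resid > 1e-8)
    stop(sprintf("transport solve did not converge: relative residual %.3g", resid))
  C <- matrix(sol, ny, nx)
  C[blocked] <- NA_real_
  structure(list(x = xs, y = ys, C = C, residual = resid,
                 gel_rows = which(in_gel), config = config),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("concentration_field: %d x %d nodes, C in [%.3g, %.3g], residual %.2g\n",
              nrow(x$C), ncol(x$C), min(x$C, na.rm = TRUE),
              max(x$C, na.rm = TRUE), x$residual))
  invisible(x)
}

#' Cross-gel gradient per growth region
#'
#' For each growth region (at the opening centers between posts) reports
#' the end-to-end cross-gel gradient and the maximum local slope of the
#' concentration profile across the gel.
#'
#' @param field a [solve_steady()] result.
#' @return data.frame with columns region, x_um, grad_end (conc/um),
#'   grad_max (conc/um).
#' @export
region_gradients <- function(field) {
  geom <- field$config$geom
  centers <- .device_region_centers(geom)
  gel <- field$gel_rows
  hy <- field$y[2] - field$y[1]
  out <- lapply(seq_along(centers), function(j) {
    cj <- which.min(abs(field$x - centers[j]))
    prof <- field$C[gel, cj]
    ok <- is.finite(prof)
    prof <- prof[ok]
    data.frame(region = j, x_um = centers[j],
               grad_end = (prof[length(prof)] - prof[1]) /
                 (hy * (length(prof) - 1)),
               grad_max = max(abs(diff(prof))) / hy)
  })
  do.call(rbind, out)
}

#' Axial uniformity of the cross-gel gradient
#'
#' The relative deviation of the cross-gel gradient between the first and
#' last interior growth regions -- small values mean the gradient is
#' axially uniform along the device (the high-flow regime).
#'
#' @param field a [solve_steady()] result.
#' @return Scalar relative variation (0 = perfectly uniform).
#' @export
axial_uniformity <- function(field) {
  g <- region_gradients(field)
  n <- nrow(g)
  if (n < 4) stop("need at least 4 regions for an interior comparison",
                  call. = FALSE)
  gi <- g$grad_end[2:(n - 1)]
  abs(gi[1] - gi[length(gi)]) / max(abs(gi), 1e-300)
}

#' Peclet number (lateral-corrected form)
#'
#' `Pe = u (h / L) h / D`: ratio of convective to diffusive transport
#' accounting for both axial (along-channel) and lateral (across-gel)
#' directions, with `h` the channel width and `L` the device length.
#'
#' @param u velocity (m/s); @param h channel width (m);
#' @param L device length (m); @param D diffusivity (m^2/s).
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(u, h, L, D) {
  .assert_scalar_num(u, "u", lower = 0)
  .assert_scalar_num(h, "h", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(L, "L", lower = 0, strict_lower = TRUE)
  if (!identical(D, Inf))
    .assert_scalar_num(D, "D", lower = 0, strict_lower = TRUE)
  u * (h / L) * h / D
}

#' Peclet number (simple axial form)
#'
#' `Pe = u L / D`, the classical axial form.
#'
#' @inheritParams peclet
#' @export
peclet_axial <- function(u, L, D) {
  .assert_scalar_num(u, "u", lower = 0)
  .assert_scalar_num(L, "L", lower = 0, strict_lower = TRUE)
  if (!identical(D, Inf))
    .assert_scalar_num(D, "D", lower = 0, strict_lower = TRUE)
  u * L / D
}

#' Young-Laplace containment pressure
#'
#' Pressure differential sustained by the surface tension of a gel-air
#' meniscus with principal radii of curvature `Rx` (in-plane, set by the
#' post spacing) and `Rz` (vertical, set by the channel height):
#' `dP = gamma (1/Rx + 1/Rz)`. An infinite radius (flat direction)
#' contributes zero.
#'
#' @param gamma surface tension (N/m).
#' @param Rx,Rz radii of curvature (m); `Inf` for a flat direction.
#' @return Pressure differential (Pa).
#' @export
laplace_pressure <- function(gamma, Rx, Rz) {
  .assert_scalar_num(gamma, "gamma", lower = 0, strict_lower = TRUE)
  for (r in list(Rx = Rx, Rz = Rz)) if (!is.infinite(r) && r <= 0)
    stop("radii of curvature must be positive (or Inf for flat)",
         call. = FALSE)
  gamma * (1 / Rx + 1 / Rz)
}

#' Supplementary angle
#'
#' The post base angle is chosen supplementary to the contact angle of
#' liquid collagen on treated PDMS, so the advancing gel interface meets
#' the post flush: `supplement_angle(120) = 60`.
#'
#' @param contact_angle_deg contact angle in degrees, in (0, 180).
#' @return `180 - contact_angle_deg`.
#' @export
supplement_angle <- function(contact_angle_deg) {
  .assert_scalar_num(contact_angle_deg, "contact_angle_deg", lower = 0,
                     upper = 180, strict_lower = TRUE, strict_upper = TRUE)
  180 - contact_angle_deg
}
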