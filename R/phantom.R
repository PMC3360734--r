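#' Sprout specification
#'
#' Parameterizes one synthetic angiogenic sprout: a capped cylinder of
#' cytosolic signal anchored on the monolayer, invading the gel at an angle
#' from the local monolayer normal, carrying a chain of spherical nuclei.
#'
#' @param base_u_um position of the sprout base along the monolayer (um).
#' @param direction_deg angle from the monolayer normal, in-plane (deg);
#'   0 is straight into the gel.
#' @param length_um sprout length along its axis (um).
#' @param radius_um cylinder radius (um).
#' @param cyto_intensity uniform cytosolic amplitude (normalized units).
#' @param n_nuclei number of nuclei evenly spaced along the axis.
#' @param nucleus_intensity nuclear-channel amplitude.
#' @param nucleus_radius_um nucleus (sphere) radius (um).
#' @return Object of class `sprout_spec`.
#' @export
sprout_spec <- function(base_u_um, direction_deg = 0, length_um = 60,
                        radius_um = 8, cyto_intensity = 0.8,
                        n_nuclei = 3L, nucleus_intensity = 1,
                        nucleus_radius_um = 6) {
  .assert_scalar_num(length_um, "length_um", lower = 0)
  .assert_scalar_num(radius_um, "radius_um", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(cyto_intensity, "cyto_intensity", lower = 0)
  .assert_scalar_num(nucleus_intensity, "nucleus_intensity", lower = 0)
  .assert_scalar_num(direction_deg, "direction_deg", lower = -90, upper = 90,
                     strict_lower = TRUE, strict_upper = TRUE)
  structure(list(base_u_um = base_u_um, direction_deg = direction_deg,
                 length_um = length_um, radius_um = radius_um,
                 cyto_intensity = cyto_intensity,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_intensity = nucleus_intensity,
                 nucleus_radius_um = nucleus_radius_um),
            class = "sprout_spec")
}

#' Background noise specification
#'
#' Additive Gaussian background for the fluorescence channels, matching the
#' Gaussian background model used during preprocessing.
#'
#' @param background_mean mean background level (normalized units).
#' @param background_sd background standard deviation (>= 0).
#' @param seed integer RNG seed; the same seed reproduces the same stack.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(background_mean = 0.1, background_sd = 0.05,
                       seed = 1L) {
  .assert_scalar_num(background_sd, "background_sd", lower = 0)
  .assert_scalar_num(background_mean, "background_mean", lower = 0)
  structure(list(background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# Default rendering intensities (normalized grayscale). The monolayer band
# anchors the cytosolic channel at 1.0 so grayscale normalization is close
# to the identity on phantoms.
.default_intensities <- function() {
  list(gel_reflect = 0.2, pdms_reflect = 0.8, channel_reflect = 0.7,
       monolayer = 1.0, monolayer_halfwidth_um = 6,
       trans_post_atten = 0.6, trans_cell_atten = 0.4)
}

# Base point, axis direction (unit xy vector) and along-monolayer
# coordinate of a sprout on a monolayer curve.
.sprout_frame <- function(sprout, curve) {
  u <- sprout$base_u_um
  base <- c(u, curve_eval(curve, u))
  tn <- .curve_normal(curve, u)
  phi <- sprout$direction_deg * pi / 180
  d <- cos(phi) * tn$normal[1, ] + sin(phi) * tn$tangent[1, ]
  list(base = base, dir = d, u_base = u)
}

#' Analytic ground-truth metrics for a sprout configuration
#'
#' Computes the invasion metrics M (signal integral), J (first moment of
#' signal about the monolayer) and AR (normal penetration over lateral
#' spread) directly from the continuous sprout geometry, independent of any
#' rendering. For a cylinder at angle theta from the normal of a straight
#' monolayer, with the integration region offset by `offset_um`:
#' `M = s pi rho^2 (L - d/cos theta)` and
#' `J = s pi rho^2 cos(theta) (L^2 - (d/cos theta)^2) / 2`,
#' which for a normal cylinder reduce to `s pi rho^2 (L - d)` and
#' `s pi rho^2 (L^2 - d^2) / 2`. Nuclei are spheres; a nucleus cut by the
#' offset plane contributes the exact spherical-cap volume and moment.
#' Aspect ratios are evaluated by deterministic quadrature over the same
#' continuous geometry.
#'
#' @param sprouts list of [sprout_spec()] objects (possibly empty).
#' @param monolayer a [monolayer_curve()]; ground truth assumes a straight
#'   monolayer (a warning is issued and the closed forms are approximate
#'   otherwise).
#' @param offset_um integration-region offset past the monolayer (um).
#' @return An [angiogenic_metrics()] record (`M`, `J`, `AR` for the
#'   cytosolic and nuclear channels). `AR` is `NA` with flag
#'   `"AR_undefined"` when the corresponding `M` is zero.
#' @export
ground_truth_metrics <- function(sprouts, monolayer, offset_um = 10) {
  .assert_scalar_num(offset_um, "offset_um", lower = 0)
  stopifnot(inherits(monolayer, "monolayer_curve"))
  if (length(sprouts) && diff(range(monolayer$control_r)) > 1e-9)
    warning("ground truth assumes a straight monolayer; closed forms are ",
            "approximate for curved control points")
  flags <- character()
  M_c <- J_c <- M_h <- J_h <- 0
  pts <- list()  # pooled quadrature points: w, r, u, channel

  for (sp in sprouts) {
    if (!inherits(sp, "sprout_spec")) stop("sprouts must be sprout_spec")
    fr <- .sprout_frame(sp, monolayer)
    th <- sp$direction_deg * pi / 180
    ct <- cos(th); st <- sin(th)
    L <- sp$length_um; rho <- sp$radius_um; s <- sp$cyto_intensity
    t0 <- offset_um / ct
    if (L > t0) {
      M_c <- M_c + s * pi * rho^2 * (L - t0)
      J_c <- J_c + s * pi * rho^2 * ct * (L^2 - t0^2) / 2
    }
    # cylinder quadrature (t along axis, a in-plane radial; z chord weight)
    tt <- seq(0, L, length.out = 401L); dt <- tt[2] - tt[1]
    aa <- seq(-rho, rho, length.out = 161L); da <- aa[2] - aa[1]
    g <- expand.grid(t = tt, a = aa)
    w <- s * 2 * sqrt(pmax(0, rho^2 - g$a^2)) * dt * da
    r <- g$t * ct - g$a * st
    u <- fr$u_base + g$t * st + g$a * ct
    keep <- r >= offset_um & w > 0
    if (any(keep))
      pts[[length(pts) + 1L]] <-
        data.frame(w = w[keep], r = r[keep], u = u[keep], channel = "cyto")
    # nuclei
    if (sp$n_nuclei > 0L && L > 0) {
      tj <- (seq_len(sp$n_nuclei) - 0.5) * L / sp$n_nuclei
      rn <- sp$nucleus_radius_um; sn <- sp$nucleus_intensity
      for (t1 in tj) {
        rc <- t1 * ct; uc <- fr$u_base + t1 * st
        a <- rc - offset_um        # center height above the cut plane
        if (a <= -rn) next         # nucleus entirely inside the offset
        b <- max(-rn, -a)          # exact sphere-cap integrals over x >= b
        Mn <- sn * pi * (2 * rn^3 / 3 - rn^2 * b + b^3 / 3)
        Jn <- rc * Mn + sn * pi * (rn^4 / 4 - (rn^2 * b^2 / 2 - b^4 / 4))
        M_h <- M_h + Mn
        J_h <- J_h + Jn
        qq <- seq(-rn, rn, length.out = 61L); dq <- qq[2] - qq[1]
        gq <- expand.grid(qu = qq, qr = qq)
        wq <- sn * 2 * sqrt(pmax(0, rn^2 - gq$qu^2 - gq$qr^2)) * dq^2
        keepq <- wq > 0 & (rc + gq$qr) >= offset_um
        if (any(keepq))
          pts[[length(pts) + 1L]] <-
            data.frame(w = wq[keepq], r = rc + gq$qr[keepq],
                       u = uc + gq$qu[keepq], channel = "hoechst")
      }
    }
  }

  ar_of <- function(ch) {
    if (!length(pts)) return(NA_real_)
    p <- do.call(rbind, pts)
    p <- p[p$channel == ch, , drop = FALSE]
    if (!nrow(p) || sum(p$w) == 0) return(NA_real_)
    ubar <- sum(p$w * p$u) / sum(p$w)
    lat <- sum(p$w * abs(p$u - ubar)) / sum(p$w)
    pen <- sum(p$w * p$r) / sum(p$w)
    if (lat < 1e-9) return(1e6)
    pen / lat
  }
  AR_c <- if (M_c > 0) ar_of("cyto") else NA_real_
  AR_h <- if (M_h > 0) ar_of("hoechst") else NA_real_
  if (M_c == 0 || M_h == 0) flags <- c(flags, "AR_undefined")

  angiogenic_metrics(M_cyto = M_c, J_cyto = J_c, AR_cyto = AR_c,
                     M_hoechst = M_h, J_hoechst = J_h, AR_hoechst = AR_h,
                     flags = flags)
}

# Point-in-convex-polygon test, vectorized over matrices X, Y.
# poly: n x 2 (x, y), vertices in order.
.in_polygon <- function(X, Y, poly) {
  n <- nrow(poly)
  inside <- NULL
  sgn <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (Y - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (X - poly[i, 1])
    s <- cr >= 0
    if (is.null(inside)) { inside <- s; sgn <- cr <= 0 }
    else { inside <- inside & s; sgn <- sgn & (cr <= 0) }
  }
  inside | sgn
}

# Inverse rigid transform applied to points.
.apply_rigid_inv <- function(tf, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  th <- tf$rotation_deg * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  ctr <- sweep(xy, 2L, tf$pivot + tf$translation)
  sweep(ctr %*% t(Rinv), 2L, tf$pivot, `+`)
}

# Line through two points -> (intercept at x = 0, angle_deg) with
# y = intercept + tan(angle) * x.
.line_from_points <- function(p1, p2) {
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  c(intercept = p1[2] - slope * p1[1], angle_deg = atan(slope) * 180 / pi)
}

# 2D Gaussian blur of each z-slice of a 3D array; kernel is normalized so
# total signal is conserved away from borders.
.blur_slices <- function(arr, sigma_px) {
  if (sigma_px <= 0) return(arr)
  for (k in seq_len(dim(arr)[3]))
    arr[, , k] <- EBImage::imageData(EBImage::gblur(arr[, , k], sigma_px))
  arr
}

# Rasterize occupancy of a capped cylinder into a 3D array (adds, via pmax).
# Supersamples each voxel 3x3x3 so partial volumes are captured.
.raster_cylinder <- function(arr, coords, base_xy, dir_xy, L, rho, z_mid,
                             value) {
  xs <- coords$x; ys <- coords$y; zs <- coords$z
  b <- c(base_xy, z_mid); d3 <- c(dir_xy, 0)
  lo <- pmin(b, b + L * d3) - rho - 2
  hi <- pmax(b, b + L * d3) + rho + 2
  iy <- which(ys >= lo[2] & ys <= hi[2])
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(iy) || !length(ix) || !length(iz)) return(arr)
  vx <- xs[2] - xs[1]; vy <- ys[2] - ys[1]
  vz <- if (length(zs) > 1) zs[2] - zs[1] else 1
  off <- c(-1, 0, 1) / 3
  occ <- array(0, c(length(iy), length(ix), length(iz)))
  g <- expand.grid(y = ys[iy], x = xs[ix], z = zs[iz])
  for (oy in off) for (ox in off) for (oz in off) {
    px <- g$x + ox * vx; py <- g$y + oy * vy; pz <- g$z + oz * vz
    rx <- px - b[1]; ry <- py - b[2]; rz <- pz - b[3]
    t <- rx * d3[1] + ry * d3[2] + rz * d3[3]
    rad2 <- rx^2 + ry^2 + rz^2 - t^2
    occ <- occ + (t >= 0 & t <= L & rad2 <= rho^2)
  }
  occ <- occ / 27
  arr[iy, ix, iz] <- pmax(arr[iy, ix, iz], value * occ)
  arr
}

# Rasterize a sphere (same supersampling scheme).
.raster_sphere <- function(arr, coords, center, rho, value) {
  xs <- coords$x; ys <- coords$y; zs <- coords$z
  iy <- which(abs(ys - center[2]) <= rho + 2)
  ix <- which(abs(xs - center[1]) <= rho + 2)
  iz <- which(abs(zs - center[3]) <= rho + 2)
  if (!length(iy) || !length(ix) || !length(iz)) return(arr)
  vx <- xs[2] - xs[1]; vy <- ys[2] - ys[1]
  vz <- if (length(zs) > 1) zs[2] - zs[1] else 1
  off <- c(-1, 0, 1) / 3
  occ <- array(0, c(length(iy), length(ix), length(iz)))
  g <- expand.grid(y = ys[iy], x = xs[ix], z = zs[iz])
  for (oy in off) for (ox in off) for (oz in off) {
    d2 <- (g$x + ox * vx - center[1])^2 + (g$y + oy * vy - center[2])^2 +
          (g$z + oz * vz - center[3])^2
    occ <- occ + (d2 <= rho^2)
  }
  occ <- occ / 27
  arr[iy, ix, iz] <- pmax(arr[iy, ix, iz], value * occ)
  arr
}

#' Render a synthetic device region stack
#'
#' Builds a 4-channel phantom of one cell growth region with exactly known
#' geometry. The reflectance channel contrasts the collagen gel against the
#' PDMS posts (bimodal histogram); the cytosolic channel carries the
#' monolayer band and sprout cylinders over a Gaussian background; the
#' nuclear channel carries spherical nuclei along each sprout; the
#' transmitted channel is an attenuation image of posts and cells.
#' Channels are composited as `max(structure, background)` so structure
#' amplitudes are not biased by the background pedestal, then blurred
#' per z-slice with a volume-normalized Gaussian kernel to mimic optics.
#'
#' @param geom a [device_geometry()].
#' @param monolayer a [monolayer_curve()], or numeric control-point
#'   y-positions (um) placed at evenly spaced u-knots; default straight
#'   monolayer 8 um inside the gel.
#' @param sprouts list of [sprout_spec()].
#' @param noise a [noise_spec()].
#' @param transform a [rigid_transform()] applied to all structures
#'   (emulates stage repositioning between imaging days).
#' @param blur_sigma_px optics blur sigma in pixels (per z-slice; 0 = off).
#' @param offset_um integration offset used for the recorded ground-truth
#'   metrics.
#' @param intensities optional overrides of the rendering intensity levels.
#' @param timepoint_label,device_id,region_index stack identifiers.
#' @return A list with elements `stack` (an [image_stack()], which also
#'   carries the truth in `meta$ground_truth`) and `ground_truth` (gel
#'   boundary lines, landmark points, monolayer control points and analytic
#'   metrics, all in image coordinates).
#' @export
render_stack <- function(geom, monolayer = NULL, sprouts = list(),
                         noise = noise_spec(), transform = rigid_transform(),
                         blur_sigma_px = 1, offset_um = 10,
                         intensities = list(),
                         timepoint_label = "0hr", device_id = "phantom",
                         region_index = 1L) {
  stopifnot(inherits(geom, "device_geometry"))
  ints <- utils::modifyList(.default_intensities(), intensities)
  ext <- .region_extent(geom)
  if (is.null(monolayer)) monolayer <- .straight_monolayer(geom)
  if (is.numeric(monolayer)) {
    u <- seq(0, ext$x, length.out = length(monolayer))
    monolayer <- monolayer_curve(u, monolayer)
  }
  y0 <- geom$margin_um; y1 <- geom$margin_um + geom$gel_width_um
  if (any(curve_eval(monolayer, seq(0, ext$x, length.out = 32)) < y0 - 1e-6) ||
      any(curve_eval(monolayer, seq(0, ext$x, length.out = 32)) > y1 + 1e-6))
    stop("monolayer control points must lie within the gel region",
         call. = FALSE)

  vz <- geom$stack_depth_um / geom$n_z_sections
  vy <- unname(geom$voxel_size_um["y"])
  vx <- unname(geom$voxel_size_um["x"])
  ny <- as.integer(round(ext$y / vy)); nx <- as.integer(round(ext$x / vx))
  nz <- geom$n_z_sections
  xs <- .axis_coords(nx, vx); ys <- .axis_coords(ny, vy)
  zs <- .axis_coords(nz, vz)
  coords <- list(x = xs, y = ys, z = zs)
  if (identical(transform$pivot, c(0, 0)) &&
      (transform$rotation_deg != 0))
    transform$pivot <- c(ext$x / 2, ext$y / 2)

  # region coordinates of every image pixel (2D)
  Xi <- matrix(xs, ny, nx, byrow = TRUE)
  Yi <- matrix(ys, ny, nx)
  reg <- .apply_rigid_inv(transform, cbind(as.vector(Xi), as.vector(Yi)))
  Xr <- matrix(reg[, 1], ny, nx); Yr <- matrix(reg[, 2], ny, nx)

  # --- reflectance template ---------------------------------------------
  refl2d <- matrix(ints$channel_reflect, ny, nx)
  refl2d[Yr >= y0 & Yr <= y1] <- ints$gel_reflect
  post2d <- matrix(FALSE, ny, nx)
  polys <- .post_polygons(geom)
  for (p in polys) post2d <- post2d | .in_polygon(Xr, Yr, p)
  refl2d[post2d] <- ints$pdms_reflect

  # --- cytosolic structure ----------------------------------------------
  hw <- ints$monolayer_halfwidth_um
  cs <- .curve_samples(monolayer, c(-20, ext$x + 20), step = max(0.5, vx / 2))
  band2d <- matrix(0, ny, nx)
  fYr <- curve_eval(monolayer, as.vector(Xr))
  cand <- which(abs(as.vector(Yr) - fYr) <= hw + 4 * vy)
  if (length(cand)) {
    near <- .polyline_nearest(cbind(as.vector(Xr)[cand], as.vector(Yr)[cand]),
                              cs$xy, cs$arc)
    band2d[cand] <- pmin(1, pmax(0, 0.5 + (hw - near$dist) / vy)) *
      ints$monolayer
  }
  cyto <- array(rep(band2d, nz), c(ny, nx, nz))

  # sprouts are defined in region coordinates; rasterize in image
  # coordinates by transforming base point and direction
  clipped <- logical(length(sprouts))
  hoechst <- array(0, c(ny, nx, nz))
  z_mid <- geom$stack_depth_um / 2
  for (i in seq_along(sprouts)) {
    sp <- sprouts[[i]]
    fr <- .sprout_frame(sp, monolayer)
    tip <- fr$base + sp$length_um * fr$dir
    # the growth region is bounded laterally by the post faces
    if (tip[2] > y1 - sp$radius_um ||
        tip[1] < geom$post_top_um + sp$radius_um ||
        tip[1] > ext$x - geom$post_top_um - sp$radius_um) {
      clipped[i] <- TRUE
      warning(sprintf("sprout %d extends outside the gel region; rendering clipped", i))
    }
    bt <- apply_rigid(transform, rbind(fr$base, tip))
    dir_img <- (bt[2, ] - bt[1, ]) / sp$length_um
    cyto <- .raster_cylinder(cyto, coords, bt[1, ], dir_img, sp$length_um,
                             sp$radius_um, z_mid, sp$cyto_intensity)
    if (sp$n_nuclei > 0L) {
      tj <- (seq_len(sp$n_nuclei) - 0.5) * sp$length_um / sp$n_nuclei
      for (t1 in tj) {
        ctr <- bt[1, ] + t1 * dir_img
        hoechst <- .raster_sphere(hoechst, coords, c(ctr, z_mid),
                                  sp$nucleus_radius_um, sp$nucleus_intensity)
      }
    }
  }

  # --- transmitted light -------------------------------------------------
  cell2d <- pmin(1, band2d / max(ints$monolayer, 1e-9) +
                   apply(cyto, c(1, 2), max) / max(1e-9, max(cyto)))
  trans2d <- pmin(1, pmax(0, 1 - ints$trans_post_atten * post2d -
                            ints$trans_cell_atten * cell2d))
  trans <- array(rep(trans2d, nz), c(ny, nx, nz))
  refl <- array(rep(refl2d, nz), c(ny, nx, nz))

  # --- optics blur --------------------------------------------------------
  cyto <- .blur_slices(cyto, blur_sigma_px)
  hoechst <- .blur_slices(hoechst, blur_sigma_px)
  refl <- .blur_slices(refl, blur_sigma_px)
  trans <- .blur_slices(trans, blur_sigma_px)

  # --- background noise (seeded; RNG state restored afterwards) -----------
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(noise$seed)
  nvox <- ny * nx * nz
  bg <- function() array(pmax(0, stats::rnorm(nvox, noise$background_mean,
                                              noise$background_sd)),
                         c(ny, nx, nz))
  cyto <- pmax(cyto, bg())
  hoechst <- pmax(hoechst, bg())
  refl <- pmax(refl + array(stats::rnorm(nvox, 0, noise$background_sd),
                            c(ny, nx, nz)), 0)
  trans <- pmin(pmax(trans +
                       array(stats::rnorm(nvox, 0, noise$background_sd / 2),
                             c(ny, nx, nz)), 0), 1)

  # --- ground truth --------------------------------------------------------
  l1 <- apply_rigid(transform, rbind(c(0, y0), c(ext$x, y0)))
  l2 <- apply_rigid(transform, rbind(c(0, y1), c(ext$x, y1)))
  gt <- list(
    boundary_lines = list(line1 = .line_from_points(l1[1, ], l1[2, ]),
                          line2 = .line_from_points(l2[1, ], l2[2, ])),
    landmarks = apply_rigid(transform, .post_corners(geom)),
    monolayer_control_points =
      apply_rigid(transform, cbind(monolayer$control_u, monolayer$control_r)),
    transform = transform,
    metrics_true = ground_truth_metrics(sprouts, monolayer, offset_um),
    offset_um = offset_um,
    clipped = clipped,
    intensities = ints)

  stack <- image_stack(
    channels = list(cyto = cyto, hoechst = hoechst, reflect = refl,
                    trans = trans),
    voxel_size_um = c(vz, vy, vx),
    timepoint_label = timepoint_label, device_id = device_id,
    region_index = region_index,
    meta = list(ground_truth = gt, geom = geom))
  list(stack = stack, ground_truth = gt)
}
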