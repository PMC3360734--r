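#' Detected gel region
#'
#' One cell growth region's coordinate frame: the two straight gel/PDMS
#' boundary lines (each `c(intercept, angle_deg)` with
#' `y = intercept + tan(angle) * x`, um), the flanking trapezoidal post
#' polygons, the post-corner landmarks used for registration, and the
#' lateral bounds of the growth opening.
#'
#' @param boundary_lines list with elements `line1` (monolayer side) and
#'   `line2`, each `c(intercept, angle_deg)`.
#' @param post_polygons list of polygon vertex matrices (image um coords).
#' @param landmarks n x 2 matrix of post-corner landmarks.
#' @param lateral_bounds length-2 x-interval of the growth opening (um).
#' @param region_index region identifier.
#' @param expected_width_um expected gel width for validation (optional).
#' @param flags character QC flags.
#' @return Object of class `gel_region`.
#' @export
gel_region <- function(boundary_lines, post_polygons = list(),
                       landmarks = NULL, lateral_bounds = NULL,
                       region_index = 1L, expected_width_um = NULL,
                       flags = character()) {
  stopifnot(is.list(boundary_lines),
            all(c("line1", "line2") %in% names(boundary_lines)))
  w <- boundary_lines$line2["intercept"] - boundary_lines$line1["intercept"]
  if (w <= 0)
    stop("boundary lines are crossed: line2 must lie above line1",
         call. = FALSE)
  if (!is.null(expected_width_um) &&
      abs(w - expected_width_um) > 0.2 * expected_width_um) {
    warning(sprintf("detected gel width %.1f um deviates more than 20%% from expected %.1f um",
                    w, expected_width_um))
    flags <- c(flags, "width_mismatch")
  }
  structure(list(boundary_lines = boundary_lines,
                 post_polygons = post_polygons, landmarks = landmarks,
                 lateral_bounds = lateral_bounds,
                 region_index = as.integer(region_index),
                 gel_width_um = as.numeric(w), flags = flags),
            class = "gel_region")
}

#' @export
print.gel_region <- function(x, ...) {
  l1 <- x$boundary_lines$line1; l2 <- x$boundary_lines$line2
  cat(sprintf("gel_region %d: line1 y = %.2f + tan(%.3f deg) x; line2 y = %.2f + tan(%.3f deg) x\n",
              x$region_index, l1["intercept"], l1["angle_deg"],
              l2["intercept"], l2["angle_deg"]))
  cat(sprintf("  gel width %.1f um, %d post polygons\n",
              x$gel_width_um, length(x$post_polygons)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Histogram-separation score of a candidate boundary
#'
#' The boundary-search objective: the absolute difference between the mean
#' reflectance on the two sides of a candidate line, optionally restricted
#' to a window of rows around the line (so each boundary of the strip is
#' scored against its local PDMS band).
#'
#' @param boundary numeric `c(intercept, angle_deg)` in um.
#' @param reflectance 2D matrix (y, x), a z-projection.
#' @param voxel_yx pixel size `c(y, x)` in um.
#' @param window_um half-width of the scoring window around the line (um);
#'   `NULL` scores the full image.
#' @param soft use fractional side-membership for pixels the line crosses
#'   (a smoothed objective that makes derivative-free search sub-pixel
#'   accurate; the hard partition is the default).
#' @return Scalar score; 0 with attribute `flag = "empty_partition"` when a
#'   side is empty.
#' @export
separation_score <- function(boundary, reflectance, voxel_yx = c(1, 1),
                             window_um = NULL, soft = FALSE) {
  ny <- nrow(reflectance); nx <- ncol(reflectance)
  xs <- .axis_coords(nx, voxel_yx[2]); ys <- .axis_coords(ny, voxel_yx[1])
  Xi <- matrix(xs, ny, nx, byrow = TRUE)
  Yi <- matrix(ys, ny, nx)
  yline <- boundary[1] + tan(boundary[2] * pi / 180) * Xi
  dv <- Yi - yline
  sel <- if (is.null(window_um)) rep(TRUE, length(dv)) else
    abs(dv) <= window_um
  if (soft) {
    wa <- pmin(1, pmax(0, 0.5 + dv / voxel_yx[1]))[sel]  # membership above
    v <- reflectance[sel]
    if (sum(wa) <= 0 || sum(1 - wa) <= 0)
      return(structure(0, flag = "empty_partition"))
    return(abs(sum((1 - wa) * v) / sum(1 - wa) - sum(wa * v) / sum(wa)))
  }
  below <- reflectance[sel & dv < 0]
  above <- reflectance[sel & dv >= 0]
  if (!length(below) || !length(above))
    return(structure(0, flag = "empty_partition"))
  abs(mean(below) - mean(above))
}

# Row-profile initialization: classify rows as gel/non-gel via Otsu on the
# projection, return the y extent (um) of the longest gel run.
.initial_strip <- function(refl, voxel_y) {
  prof <- rowMeans(refl)
  thr <- .otsu(as.vector(refl))
  isgel <- prof < thr
  r <- rle(isgel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) stop("no gel-like rows found", call. = FALSE)
  best <- runs[which.max(r$lengths[runs])]
  c((starts[best] - 1L) * voxel_y, ends[best] * voxel_y)
}

# Soft separation score over a fixed pixel window (logical matrix). The
# window is frozen at the initialization so the optimizer cannot trade
# window content against partition means.
.sep_score_fixed <- function(boundary, refl, voxel_yx, sel) {
  ny <- nrow(refl); nx <- ncol(refl)
  xs <- .axis_coords(nx, voxel_yx[2]); ys <- .axis_coords(ny, voxel_yx[1])
  Xi <- matrix(xs, ny, nx, byrow = TRUE)
  Yi <- matrix(ys, ny, nx)
  dv <- Yi - (boundary[1] + tan(boundary[2] * pi / 180) * Xi)
  wa <- pmin(1, pmax(0, 0.5 + dv / voxel_yx[1]))[sel]
  v <- refl[sel]
  if (sum(wa) <= 0 || sum(1 - wa) <= 0) return(0)
  abs(sum((1 - wa) * v) / sum(1 - wa) - sum(wa * v) / sum(wa))
}

# Optimize one boundary line by multi-start Nelder-Mead on the windowed
# separation score; ties broken toward smaller |angle|.
.optimize_line <- function(refl, voxel_yx, init_intercept, window_um,
                           offsets = c(-6, 0, 6)) {
  ny <- nrow(refl); nx <- ncol(refl)
  ys <- .axis_coords(ny, voxel_yx[1])
  best <- NULL
  for (off in offsets) {
    sel <- matrix(abs(ys - (init_intercept + off)) <= window_um, ny, nx)
    fit <- stats::optim(
      c(init_intercept + off, 0),
      function(p) -.sep_score_fixed(p, refl, voxel_yx, sel),
      method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 600))
    cand <- list(par = fit$par, score = -fit$value)
    if (is.null(best) || cand$score > best$score + 1e-9 ||
        (abs(cand$score - best$score) <= 1e-9 &&
         abs(cand$par[2]) < abs(best$par[2])))
      best <- cand
  }
  best
}

# Sample the mean reflectance in a band at normal offsets from a line and
# locate the opening between the two flanking posts: the reflectance dip
# (medium-filled gap between bright PDMS posts) is interior to the view,
# so its intensity-weighted centroid gives an unbiased sub-pixel estimate
# of the post-pattern x shift.
.match_post_phase <- function(refl, voxel_yx, line, geom, side = -1) {
  ny <- nrow(refl); nx <- ncol(refl)
  xs <- .axis_coords(nx, voxel_yx[2])
  depth <- geom$post_depth_um
  offs <- seq(2, max(4, depth - 2), by = voxel_yx[1])
  tanb <- tan(line["angle_deg"] * pi / 180)
  prof <- rep(0, nx)
  for (o in offs) {
    yline <- line["intercept"] + tanb * xs
    iy <- round((yline + side * o) / voxel_yx[1] + 0.5)
    # keep every sampled row center clear of the blurred boundary ramp
    yc <- (iy - 0.5) * voxel_yx[1]
    bad <- side * (yc - yline) < max(2, voxel_yx[1])
    iy[bad] <- iy[bad] + side
    iy <- pmin(ny, pmax(1L, iy))
    prof <- prof + refl[cbind(iy, seq_len(nx))]
  }
  prof <- prof / length(offs)
  gap_center_nominal <- geom$post_top_um + geom$post_spacing_um / 2
  # intensity-weighted centroid of the reflectance dip; the window covers
  # the whole opening plus the bright post flanks so an off-center window
  # is pulled back toward the true gap center
  halfwin <- geom$post_spacing_um / 2 +
    min(geom$post_top_um, geom$post_spacing_um) / 2
  ctr <- gap_center_nominal
  # cap dip weights at the post/gap contrast so stray dark pixels (e.g.
  # residual boundary leakage) cannot dominate the centroid
  hi <- stats::quantile(prof, 0.9)
  cap <- 1.5 * (hi - stats::median(prof))
  for (it in 1:4) {
    win <- abs(xs - ctr) <= halfwin
    if (!any(win)) break
    w <- pmin(pmax(0, hi - prof), max(cap, 1e-6)) * win
    if (sum(w) <= 0) break
    ctr <- sum(w * xs) / sum(w)
  }
  ctr - gap_center_nominal
}

#' Detect gel/PDMS boundaries
#'
#' Finds the two straight boundary lines delimiting the gel strip by
#' maximizing the histogram-separation score with a multi-start
#' derivative-free (Nelder-Mead) search, starting from a row-profile
#' estimate of the strip. Post polygons are then placed by matching the
#' expected post/gap reflectance pattern along each boundary, yielding
#' post-corner landmarks and the lateral bounds of the growth opening.
#'
#' @param stack an [image_stack()] with a `reflect` channel (collapsed to
#'   2D by z-mean projection), or a 2D reflectance matrix (then supply
#'   `voxel_yx`).
#' @param geom the [device_geometry()] (expected widths and post pattern).
#' @param voxel_yx pixel size `c(y, x)` um when `stack` is a matrix.
#' @return A [gel_region()].
#' @export
detect_gel_boundaries <- function(stack, geom, voxel_yx = NULL) {
  if (inherits(stack, "image_stack")) {
    refl <- .z_project(stack, "reflect")
    voxel_yx <- stack$voxel_size_um[c("y", "x")]
    region_index <- stack$region_index
  } else {
    refl <- stack
    if (is.null(voxel_yx)) voxel_yx <- c(1, 1)
    region_index <- 1L
  }
  if (!.is_bimodal(as.vector(refl)))
    stop("gel/PDMS contrast insufficient: reflectance histogram is not bimodal",
         call. = FALSE)
  strip <- .initial_strip(refl, voxel_yx[1])
  window <- 0.8 * geom$margin_um
  f1 <- .optimize_line(refl, voxel_yx, strip[1], window)
  f2 <- .optimize_line(refl, voxel_yx, strip[2], window)
  line1 <- stats::setNames(f1$par, c("intercept", "angle_deg"))
  line2 <- stats::setNames(f2$par, c("intercept", "angle_deg"))

  shift1 <- .match_post_phase(refl, voxel_yx, line1, geom, side = -1)
  shift2 <- .match_post_phase(refl, voxel_yx, line2, geom, side = +1)
  ext <- .region_extent(geom)
  mk_corners <- function(line, shift) {
    xc <- shift + c(0, geom$post_top_um, ext$x - geom$post_top_um, ext$x)
    cbind(x = xc, y = line["intercept"] + tan(line["angle_deg"] * pi / 180) * xc)
  }
  lm1 <- mk_corners(line1, shift1)
  lm2 <- mk_corners(line2, shift2)
  # gap-center anchor points, one per boundary: their x comes from the
  # sub-pixel post-pattern phase and is insensitive to the line-angle
  # uncertainty, so they carry the rotation signal for registration
  gap_c <- geom$post_top_um + geom$post_spacing_um / 2
  anchor_at <- function(line, shift) {
    x <- gap_c + shift
    c(x, line["intercept"] + tan(line["angle_deg"] * pi / 180) * x)
  }
  anchors <- rbind(anchor_at(line1, shift1), anchor_at(line2, shift2))
  # place each template polygon relative to its detected line: shift in x
  # by the matched phase, and in y by the offset of its boundary face
  polys <- lapply(.post_polygons(geom), function(p) {
    side1 <- mean(p[, 2]) < geom$margin_um + geom$gel_width_um / 2
    line <- if (side1) line1 else line2
    shift <- if (side1) shift1 else shift2
    face_y <- if (side1) geom$margin_um else geom$margin_um + geom$gel_width_um
    xn <- p[, 1] + shift
    cbind(x = xn,
          y = p[, 2] - face_y + line["intercept"] +
            tan(line["angle_deg"] * pi / 180) * xn)
  })
  out <- gel_region(boundary_lines = list(line1 = line1, line2 = line2),
                    post_polygons = polys,
                    landmarks = rbind(lm1, lm2),
                    lateral_bounds = c(shift1 + geom$post_top_um,
                                       shift1 + ext$x - geom$post_top_um),
                    region_index = region_index,
                    expected_width_um = geom$gel_width_um)
  out$anchors <- anchors
  out
}

#' Register two timepoints of one region
#'
#' Least-squares rigid (Kabsch) fit mapping the 48-hr landmarks onto the
#' 0-hr landmarks. The gap-center anchor points (one per boundary line)
#' are used when available -- their sub-pixel phase carries the rotation
#' signal -- falling back to the post-corner landmarks. The returned
#' transform satisfies `apply_rigid(tf, points_48hr) ~ points_0hr`.
#'
#' @param region_0hr,region_48hr [gel_region()] objects of the same
#'   physical region, with matching landmark order.
#' @param rotation_threshold_um a fitted rotation is kept only when the
#'   displacement it implies at the anchor points exceeds this localization
#'   uncertainty; smaller rotations are indistinguishable from anchor noise
#'   and the fit falls back to pure translation.
#' @return A [rigid_transform()] with attribute `residual_um` (RMS landmark
#'   residual). Warns when the residual exceeds 10 um (possible region
#'   mismatch) or the rotation exceeds 10 degrees.
#' @export
register_timepoints <- function(region_0hr, region_48hr,
                                rotation_threshold_um = 1.5) {
  A <- region_48hr$anchors %||% region_48hr$landmarks
  B <- region_0hr$anchors %||% region_0hr$landmarks
  if (is.null(A) || is.null(B) || nrow(A) != nrow(B))
    stop("both regions must carry matching landmarks", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) { sv$v[, 2] <- -sv$v[, 2]; R <- sv$v %*% t(sv$u) }
  angle <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  spread <- max(sqrt(rowSums(sweep(A, 2, ca)^2)))
  if (abs(angle) * pi / 180 * spread < rotation_threshold_um) angle <- 0
  tf <- rigid_transform(translation = cb - ca, rotation_deg = angle,
                        pivot = ca)
  res <- sqrt(mean(rowSums((apply_rigid(tf, A) - B)^2)))
  if (res > 10)
    warning(sprintf("registration residual %.1f um > 10 um: possible region mismatch", res))
  if (abs(angle) >= 10)
    warning(sprintf("recovered rotation %.1f deg exceeds the 10 deg stage-repositioning bound", angle))
  attr(tf, "residual_um") <- res
  tf
}
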