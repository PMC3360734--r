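#' Combined monolayer signal
#'
#' Linear combination of the cytosolic and transmitted-light projections
#' used as the monolayer-detection signal. Because cells attenuate
#' transmitted light, the transmitted component enters inverted by default
#' (as `1 - trans`), so both components peak on the monolayer. The result
#' is renormalized to [0, 1].
#'
#' @param cyto,trans 2D projections of the same shape.
#' @param weights non-negative weights `c(cyto, trans)`, not both zero.
#' @param invert_transmitted use `1 - trans` (default TRUE).
#' @return 2D field in [0, 1].
#' @export
combined_signal <- function(cyto, trans, weights = c(0.7, 0.3),
                            invert_transmitted = TRUE) {
  if (!identical(dim(cyto), dim(trans)))
    stop("cyto and trans projections must share a shape", call. = FALSE)
  if (length(weights) != 2L || any(weights < 0) || sum(weights) == 0)
    stop("'weights' must be two non-negative values, not both zero",
         call. = FALSE)
  tr <- if (invert_transmitted) max(trans) - trans else trans
  f <- weights[1] * cyto + weights[2] * tr
  rng <- range(f)
  if (diff(rng) == 0) return(f * 0)
  (f - rng[1]) / diff(rng)
}

#' Band integral of a candidate monolayer curve
#'
#' The monolayer-fitting objective: the mean of the signal over all pixels
#' within normal distance `halfwidth_um` of the candidate spline
#' (normalizing the integral by the band area removes any long-curve
#' bias). Normal distance uses the first-order slope correction
#' `|y - f(x)| cos(alpha)`, exact for straight curves.
#'
#' @param curve a [monolayer_curve()] (or control-point list).
#' @param signal 2D field (y, x).
#' @param halfwidth_um band half-width (um).
#' @param voxel_yx pixel size `c(y, x)` um.
#' @param clip optional logical matrix (same shape): pixels outside it are
#'   excluded from the band (used to confine the band to the gel strip).
#' @return Mean band signal; attribute `flag = "band_clipped"` if the band
#'   leaves the image.
#' @export
band_integral <- function(curve, signal, halfwidth_um = 6,
                          voxel_yx = c(1, 1), clip = NULL) {
  ny <- nrow(signal); nx <- ncol(signal)
  xs <- .axis_coords(nx, voxel_yx[2]); ys <- .axis_coords(ny, voxel_yx[1])
  fx <- curve_eval(curve, xs)
  eps <- max(1e-3, voxel_yx[2])
  slope <- (curve_eval(curve, xs + eps) - curve_eval(curve, xs - eps)) /
    (2 * eps)
  cosa <- 1 / sqrt(1 + slope^2)
  dn <- abs(outer(ys, fx, `-`)) * rep(cosa, each = ny)
  inband <- dn <= halfwidth_um
  if (!is.null(clip)) inband <- inband & clip
  clipped <- any(fx - halfwidth_um < 0 | fx + halfwidth_um > ny * voxel_yx[1])
  if (!any(inband)) return(structure(0, flag = "band_clipped"))
  out <- mean(signal[inband])
  if (clipped) attr(out, "flag") <- "band_clipped"
  out
}

#' Fit the monolayer curve
#'
#' Searches for the 4-control-point natural cubic spline that maximizes
#' the band integral of the combined signal, by multi-start Nelder-Mead
#' over the 4 normal (r) positions of the control points at fixed, evenly
#' spaced u-knots. Candidates leaving the gel strip are penalized. The
#' default initialization is a straight line at the monolayer-channel edge
#' of the strip; the returned objective never falls below the
#' initialization's.
#'
#' @param signal 2D combined signal (y, x), e.g. from [combined_signal()].
#' @param region a [gel_region()] (defines the strip the curve must stay in).
#' @param voxel_yx pixel size `c(y, x)` um.
#' @param init optional initial [monolayer_curve()].
#' @param band_halfwidth_um band half-width (um).
#' @param n_control number of spline control points.
#' @param start_offsets_um r-offsets (um) from the strip edge used as
#'   multi-start initializations.
#' @return A [monolayer_curve()] with the achieved `score`.
#' @export
fit_monolayer <- function(signal, region, voxel_yx = c(1, 1), init = NULL,
                          band_halfwidth_um = 6, n_control = 4L,
                          start_offsets_um = c(4, 8, 14, 22)) {
  ny <- nrow(signal); nx <- ncol(signal)
  x_max <- nx * voxel_yx[2]
  u_knots <- seq(0, x_max, length.out = n_control)
  l1 <- region$boundary_lines$line1; l2 <- region$boundary_lines$line2
  y1k <- l1["intercept"] + tan(l1["angle_deg"] * pi / 180) * u_knots
  y2k <- l2["intercept"] + tan(l2["angle_deg"] * pi / 180) * u_knots

  # confine the band to the gel strip so bright out-of-gel structure
  # (post attenuation) cannot attract the curve
  xs <- .axis_coords(nx, voxel_yx[2]); ys <- .axis_coords(ny, voxel_yx[1])
  Xi <- matrix(xs, ny, nx, byrow = TRUE)
  Yi <- matrix(ys, ny, nx)
  strip <- Yi >= l1["intercept"] + tan(l1["angle_deg"] * pi / 180) * Xi &
    Yi <= l2["intercept"] + tan(l2["angle_deg"] * pi / 180) * Xi

  objective <- function(r) {
    pen <- sum(pmax(0, y1k - r)) + sum(pmax(0, r - y2k))
    if (pen > 0) return(-pen)  # outside the gel strip
    cv <- monolayer_curve(u_knots, r, band_halfwidth_um)
    as.numeric(band_integral(cv, signal, band_halfwidth_um, voxel_yx,
                             clip = strip))
  }

  starts <- list()
  if (!is.null(init)) starts[[1]] <- curve_eval(init, u_knots)
  for (off in start_offsets_um) starts[[length(starts) + 1L]] <- y1k + off
  init_obj <- objective(starts[[1]])

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, function(p) -objective(p),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 800))
    if (is.null(best) || -fit$value > best$score) {
      best <- list(par = fit$par, score = -fit$value)
    }
  }
  flags <- character()
  if (best$score < init_obj) {  # stagnation guard: keep the best seen
    best <- list(par = starts[[1]], score = init_obj)
    flags <- c(flags, "optimizer_stagnation")
  }
  monolayer_curve(u_knots, best$par, band_halfwidth_um,
                  score = best$score, flags = flags)
}

#' Overlay a monolayer fit on a signal image (QC plot)
#'
#' @param signal 2D field (y, x).
#' @param curve fitted [monolayer_curve()].
#' @param voxel_yx pixel size `c(y, x)` um.
#' @export
plot_monolayer_overlay <- function(signal, curve, voxel_yx = c(1, 1)) {
  ny <- nrow(signal); nx <- ncol(signal)
  xs <- .axis_coords(nx, voxel_yx[2]); ys <- .axis_coords(ny, voxel_yx[1])
  graphics::image(xs, ys, t(signal), col = grDevices::gray.colors(64),
                  xlab = "u (um)", ylab = "y (um)", useRaster = TRUE)
  graphics::lines(xs, curve_eval(curve, xs), col = "red", lwd = 2)
  invisible(NULL)
}
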