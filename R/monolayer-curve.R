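#' Monolayer curve
#'
#' The endothelial monolayer within a growth region, modeled as a natural
#' cubic spline through 4 control points. Control points sit at fixed,
#' evenly spaced positions `control_u` along the monolayer (the region x
#' axis) and move only in the normal direction, so the curve is
#' single-valued in u (fold-free by construction).
#'
#' @param control_u numeric, u positions (um) of the control points.
#' @param control_r numeric, same length: curve position (um, region y
#'   coordinate) at each control point.
#' @param band_halfwidth_um half-width (um) of the signal band used by the
#'   fitting objective.
#' @param score objective value at the optimum (NA for analytic curves).
#' @param flags character vector of QC flags.
#' @return Object of class `monolayer_curve`.
#' @export
monolayer_curve <- function(control_u, control_r, band_halfwidth_um = 6,
                            score = NA_real_, flags = character()) {
  if (length(control_u) != length(control_r) || length(control_u) < 2L)
    stop("need matching control_u / control_r of length >= 2", call. = FALSE)
  if (is.unsorted(control_u, strictly = TRUE))
    stop("'control_u' must be strictly increasing", call. = FALSE)
  structure(list(control_u = as.numeric(control_u),
                 control_r = as.numeric(control_r),
                 band_halfwidth_um = band_halfwidth_um,
                 score = score, flags = flags),
            class = "monolayer_curve")
}

#' @export
print.monolayer_curve <- function(x, ...) {
  cat(sprintf("monolayer_curve: %d control points, r = [%s] um%s\n",
              length(x$control_u),
              paste(sprintf("%.2f", x$control_r), collapse = ", "),
              if (is.finite(x$score)) sprintf(", score %.4f", x$score) else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a monolayer curve
#'
#' Natural cubic spline interpolation of the control points at positions
#' `u` (um).
#'
#' @param curve a [monolayer_curve()].
#' @param u numeric positions along the monolayer (um).
#' @return Curve position (um, region y coordinate) at each `u`.
#' @export
curve_eval <- function(curve, u) {
  .spline_eval(curve$control_u, curve$control_r, u)
}

# Dense (x, y) samples along the curve over [u_min, u_max], with arc length.
.curve_samples <- function(curve, u_range = range(curve$control_u),
                           step = 0.5) {
  u <- seq(u_range[1], u_range[2], by = step)
  y <- curve_eval(curve, u)
  xy <- cbind(x = u, y = y)
  seg <- sqrt(rowSums(diff(xy)^2))
  list(xy = xy, arc = c(0, cumsum(seg)))
}

# Unit tangent/normal at u; the normal points toward increasing y
# (the gel side in region coordinates).
.curve_normal <- function(curve, u, eps = 1e-3) {
  dy <- (curve_eval(curve, u + eps) - curve_eval(curve, u - eps)) / (2 * eps)
  t <- cbind(1, dy) / sqrt(1 + dy^2)
  n <- cbind(-t[, 2], t[, 1])
  if (any(n[, 2] < 0)) n[n[, 2] < 0, ] <- -n[n[, 2] < 0, , drop = FALSE]
  list(tangent = t, normal = n)
}

# Straight monolayer at constant y over the region x extent.
.straight_monolayer <- function(geom, r_offset_um = 8, n_points = 4L) {
  ext <- .region_extent(geom)
  monolayer_curve(seq(0, ext$x, length.out = n_points),
                  rep(geom$margin_um + r_offset_um, n_points))
}
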