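# Internal helpers shared across modules. All physical quantities are in
# micrometers unless a name says otherwise; arrays are dim (y, x, z) with
# pixel centers at (i - 0.5) * voxel_size for 1-based index i.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

# Pixel-center coordinate axes (um) of a (y, x, z) array.
.axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

#' Rigid in-plane transform
#'
#' A 2D rigid-body transform (rotation about a fixed pivot followed by a
#' translation), used to express stage repositioning between imaging days.
#'
#' @param translation numeric length-2, (x, y) translation in micrometers.
#' @param rotation_deg rotation angle in degrees (counter-clockwise).
#' @param pivot numeric length-2 rotation center (x, y) in micrometers.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0), rotation_deg = 0,
                            pivot = c(0, 0)) {
  stopifnot(length(translation) == 2L, length(pivot) == 2L)
  .assert_scalar_num(rotation_deg, "rotation_deg", -360, 360)
  structure(list(translation = as.numeric(translation),
                 rotation_deg = as.numeric(rotation_deg),
                 pivot = as.numeric(pivot)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) points in um.
#' @return n x 2 matrix of transformed points.
#' @export
apply_rigid <- function(tf, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  th <- tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  ctr <- sweep(xy, 2L, tf$pivot)
  out <- ctr %*% t(R)
  sweep(out, 2L, tf$pivot + tf$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: translation (%.3f, %.3f) um, rotation %.4f deg\n",
              x$translation[1], x$translation[2], x$rotation_deg))
  invisible(x)
}

# Natural cubic spline through control points (u_i, r_i), evaluated at u.
.spline_eval <- function(u_knots, r_knots, u) {
  stats::spline(u_knots, r_knots, xout = u, method = "natural")$y
}

# Otsu threshold of a numeric vector (256-bin histogram).
.otsu <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[nbins]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Two-mode summary of an intensity sample: Otsu split, per-class means/sds.
.mode_split <- function(v) {
  thr <- .otsu(v)
  lo <- v[v <= thr]; hi <- v[v > thr]
  if (length(lo) < 2L || length(hi) < 2L)
    return(list(ok = FALSE, thr = thr))
  list(ok = TRUE, thr = thr,
       mu = c(mean(lo), mean(hi)), sd = c(stats::sd(lo), stats::sd(hi)),
       n = c(length(lo), length(hi)))
}

# Bimodality heuristic: the two Otsu classes must be separated by more than
# `k` times the larger intra-class SD.
.is_bimodal <- function(v, k = 2) {
  ms <- .mode_split(v)
  if (!ms$ok) return(FALSE)
  diff(ms$mu) > k * max(ms$sd, 1e-12)
}

# Nearest-point distance from query points to a densely sampled curve.
# `curve_xy`: n x 2 matrix of curve samples (x, y) ordered along the curve;
# `arc`: arc-length coordinate of each sample. Returns list(dist, u, idx)
# where dist is unsigned distance and u the arc-length of the nearest sample.
.polyline_nearest <- function(query_xy, curve_xy, arc = NULL,
                              chunk = 4096L) {
  query_xy <- matrix(as.numeric(query_xy), ncol = 2L)
  m <- nrow(query_xy)
  if (is.null(arc)) {
    seg <- sqrt(rowSums(diff(curve_xy)^2))
    arc <- c(0, cumsum(seg))
  }
  d <- numeric(m); u <- numeric(m); idx <- integer(m)
  cx <- curve_xy[, 1]; cy <- curve_xy[, 2]
  for (start in seq(1L, m, by = chunk)) {
    ii <- start:min(m, start + chunk - 1L)
    dx <- outer(query_xy[ii, 1], cx, `-`)
    dy <- outer(query_xy[ii, 2], cy, `-`)
    dd <- dx * dx + dy * dy
    j <- max.col(-dd, ties.method = "first")
    sel <- cbind(seq_along(ii), j)
    d[ii] <- sqrt(dd[sel])
    u[ii] <- arc[j]
    idx[ii] <- j
  }
  list(dist = d, u = u, idx = idx)
}

# Quadratic (parabolic) sub-sample interpolation of a discrete peak.
.subpixel_peak <- function(score) {
  i <- which.max(score)
  if (i == 1L || i == length(score)) return(i)
  y1 <- score[i - 1L]; y2 <- score[i]; y3 <- score[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < 1e-12) return(i)
  i + 0.5 * (y1 - y3) / den
}
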