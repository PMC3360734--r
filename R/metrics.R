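#' Angiogenic metrics record
#'
#' Scalar invasion metrics for one region at one timepoint: `M` is the
#' signal integral over the integration region V (intensity x um^3), `J`
#' the first moment of the signal about the monolayer (intensity x um^4),
#' and `AR` the dimensionless aspect ratio (mean signal-weighted normal
#' penetration over mean signal-weighted lateral spread). Each is computed
#' for the cytosolic and nuclear channels.
#'
#' @param M_cyto,J_cyto,AR_cyto,M_hoechst,J_hoechst,AR_hoechst metric values.
#' @param timepoint_label,device_id,region_index,condition identifiers.
#' @param flags character QC flags.
#' @param differential logical; differential records may be negative.
#' @return Object of class `angiogenic_metrics`.
#' @export
angiogenic_metrics <- function(M_cyto = 0, J_cyto = 0, AR_cyto = NA_real_,
                               M_hoechst = 0, J_hoechst = 0,
                               AR_hoechst = NA_real_,
                               timepoint_label = NA_character_,
                               device_id = NA_character_,
                               region_index = NA_integer_,
                               condition = NA_character_,
                               flags = character(),
                               differential = FALSE) {
  if (!differential) {
    if (M_cyto < 0 || J_cyto < 0 || M_hoechst < 0 || J_hoechst < 0)
      stop("M and J must be non-negative", call. = FALSE)
    if (M_cyto == 0 && abs(J_cyto) > 1e-9)
      stop("J must be 0 when M is 0", call. = FALSE)
    if (M_hoechst == 0 && abs(J_hoechst) > 1e-9)
      stop("J must be 0 when M is 0", call. = FALSE)
    if ((M_cyto == 0 || M_hoechst == 0) && !("AR_undefined" %in% flags))
      flags <- c(flags, "AR_undefined")
  }
  structure(list(M_cyto = M_cyto, J_cyto = J_cyto, AR_cyto = AR_cyto,
                 M_hoechst = M_hoechst, J_hoechst = J_hoechst,
                 AR_hoechst = AR_hoechst,
                 timepoint_label = timepoint_label, device_id = device_id,
                 region_index = region_index, condition = condition,
                 flags = flags, differential = differential),
            class = "angiogenic_metrics")
}

#' @export
print.angiogenic_metrics <- function(x, ...) {
  cat(sprintf("angiogenic_metrics%s [%s / region %s / %s]\n",
              if (x$differential) " (differential)" else "",
              x$device_id, x$region_index, x$timepoint_label))
  cat(sprintf("  cyto:    M = %.4g, J = %.4g, AR = %.4g\n",
              x$M_cyto, x$J_cyto, x$AR_cyto))
  cat(sprintf("  hoechst: M = %.4g, J = %.4g, AR = %.4g\n",
              x$M_hoechst, x$J_hoechst, x$AR_hoechst))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.angiogenic_metrics <- function(x, ...) {
  data.frame(condition = x$condition, device = x$device_id,
             region = x$region_index, timepoint = x$timepoint_label,
             M_cyto = x$M_cyto, J_cyto = x$J_cyto, AR_cyto = x$AR_cyto,
             M_hoechst = x$M_hoechst, J_hoechst = x$J_hoechst,
             AR_hoechst = x$AR_hoechst,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Integration region past the monolayer
#'
#' Builds the integration domain V: the gel strip between the two detected
#' gel/PDMS boundaries, bounded laterally by the flanking post faces, and
#' offset past the monolayer by `offset_um` (default 10 um) to exclude the
#' high-intensity band around the monolayer itself.
#'
#' @param stack an [image_stack()] (defines the voxel grid).
#' @param region a [gel_region()] from [detect_gel_boundaries()].
#' @param curve a [monolayer_curve()].
#' @param offset_um normal offset past the monolayer (um, >= 0).
#' @return Object of class `region_mask`: a logical volume plus grid info.
#' @export
integration_region <- function(stack, region, curve, offset_um = 10) {
  .assert_scalar_num(offset_um, "offset_um", lower = 0)
  field <- distance_field(stack, curve)
  co <- .stack_coords(stack)
  ny <- length(co$y); nx <- length(co$x); nz <- length(co$z)
  Xi <- matrix(co$x, ny, nx, byrow = TRUE)
  Yi <- matrix(co$y, ny, nx)
  l1 <- region$boundary_lines$line1; l2 <- region$boundary_lines$line2
  y_l1 <- l1["intercept"] + tan(l1["angle_deg"] * pi / 180) * Xi
  y_l2 <- l2["intercept"] + tan(l2["angle_deg"] * pi / 180) * Xi
  in_gel <- Yi >= y_l1 & Yi <= y_l2
  if (!is.null(region$lateral_bounds))
    in_gel <- in_gel & Xi >= region$lateral_bounds[1] &
      Xi <= region$lateral_bounds[2]
  m2d <- in_gel & field$r >= offset_um
  if (!any(m2d))
    stop("integration region is empty (monolayer at far boundary?)",
         call. = FALSE)
  mask <- array(rep(m2d, nz), c(ny, nx, nz))
  structure(list(mask = mask, mask2d = m2d, offset_um = offset_um,
                 voxel_volume = .voxel_volume(stack),
                 field = field),
            class = "region_mask")
}

#' Normal-distance field of a monolayer curve
#'
#' Per-pixel signed normal distance `r` to the monolayer (positive on the
#' gel side) and along-monolayer coordinate `u` (arc length of the nearest
#' curve point). Distances are nearest-point distances to a densely
#' sampled version of the spline (sampling step 0.25 um).
#'
#' @param stack an [image_stack()].
#' @param curve a [monolayer_curve()].
#' @param gel_side +1 if the gel lies at larger y than the curve (default).
#' @return Object of class `distance_field` with 2D matrices `r` and `u`.
#' @export
distance_field <- function(stack, curve, gel_side = 1) {
  co <- .stack_coords(stack)
  ny <- length(co$y); nx <- length(co$x)
  Xi <- matrix(co$x, ny, nx, byrow = TRUE)
  Yi <- matrix(co$y, ny, nx)
  pad <- 0.25 * diff(range(co$x)) + 10
  cs <- .curve_samples(curve, range(co$x) + c(-pad, pad), step = 0.25)
  near <- .polyline_nearest(cbind(as.vector(Xi), as.vector(Yi)),
                            cs$xy, cs$arc)
  yc <- cs$xy[near$idx, 2]
  sgn <- ifelse(as.vector(Yi) >= yc, 1, -1) * sign(gel_side)
  structure(list(r = matrix(sgn * near$dist, ny, nx),
                 u = matrix(near$u, ny, nx)),
            class = "distance_field")
}

#' Total signal integral M
#'
#' `M = sum over V of s(x) * voxel volume`: aggregate invading signal.
#'
#' @param signal 3D channel array (background-removed).
#' @param mask a `region_mask` from [integration_region()].
#' @return Scalar M (intensity x um^3).
#' @export
total_integral <- function(signal, mask) {
  stopifnot(identical(dim(signal), dim(mask$mask)))
  sum(signal[mask$mask]) * mask$voxel_volume
}

#' First moment J about the monolayer
#'
#' `J = sum over V of s(x) * r(x) * voxel volume`: penetration-weighted
#' signal, where r is normal distance to the monolayer.
#'
#' @inheritParams total_integral
#' @param field a `distance_field`; defaults to the one inside `mask`.
#' @return Scalar J (intensity x um^4).
#' @export
first_moment <- function(signal, mask, field = mask$field) {
  stopifnot(identical(dim(signal), dim(mask$mask)))
  nz <- dim(signal)[3]
  r3 <- array(rep(field$r, nz), dim(signal))
  sum(signal[mask$mask] * r3[mask$mask]) * mask$voxel_volume
}

#' Aspect ratio of invasion
#'
#' `AR = (mean signal-weighted normal penetration) /
#'       (mean signal-weighted lateral spread)`, i.e.
#' `(sum s r / M') / (sum s |u - u_bar| / M')` with `u_bar` the
#' signal-weighted mean along-monolayer coordinate. Higher values indicate
#' more directional penetration toward the chemoattractant.
#'
#' @inheritParams first_moment
#' @param max_ar cap returned when the lateral spread is zero.
#' @return Scalar AR (dimensionless); NA with attribute `flag` when the
#'   masked signal is zero.
#' @export
aspect_ratio <- function(signal, mask, field = mask$field, max_ar = 1e6) {
  stopifnot(identical(dim(signal), dim(mask$mask)))
  nz <- dim(signal)[3]
  s <- signal[mask$mask]
  tot <- sum(s)
  if (tot <= 0) return(structure(NA_real_, flag = "AR_undefined"))
  r3 <- array(rep(field$r, nz), dim(signal))[mask$mask]
  u3 <- array(rep(field$u, nz), dim(signal))[mask$mask]
  pen <- sum(s * r3) / tot
  ubar <- sum(s * u3) / tot
  lat <- sum(s * abs(u3 - ubar)) / tot
  if (lat < 1e-9) return(structure(max_ar, flag = "AR_capped"))
  pen / lat
}

#' Compute all angiogenic metrics for one region
#'
#' Composes [integration_region()], [distance_field()], [total_integral()],
#' [first_moment()] and [aspect_ratio()] for the cytosolic and nuclear
#' channels of a preprocessed stack.
#'
#' @param stack preprocessed [image_stack()].
#' @param region detected [gel_region()].
#' @param curve fitted [monolayer_curve()].
#' @param offset_um integration offset (um), default 10.
#' @return An [angiogenic_metrics()] record.
#' @export
compute_metrics <- function(stack, region, curve, offset_um = 10) {
  mask <- integration_region(stack, region, curve, offset_um)
  out <- list()
  flags <- character()
  for (ch in c("cyto", "hoechst")) {
    sig <- stack$channels[[ch]]
    if (is.null(sig)) stop("stack lacks channel: ", ch, call. = FALSE)
    M <- total_integral(sig, mask)
    J <- first_moment(sig, mask)
    AR <- aspect_ratio(sig, mask)
    if (!is.null(attr(AR, "flag")))
      flags <- c(flags, paste0(ch, ":", attr(AR, "flag")))
    out[[ch]] <- list(M = unname(M), J = unname(J), AR = as.numeric(AR))
  }
  angiogenic_metrics(M_cyto = out$cyto$M, J_cyto = out$cyto$J,
                     AR_cyto = out$cyto$AR,
                     M_hoechst = out$hoechst$M,
                     J_hoechst = out$hoechst$J,
                     AR_hoechst = out$hoechst$AR,
                     timepoint_label = stack$timepoint_label,
                     device_id = stack$device_id,
                     region_index = stack$region_index,
                     flags = flags)
}

#' Differential metrics between timepoints
#'
#' Growth-positive differences between the 48-hr and 0-hr records of the
#' same region: `dM = M(48hr) - M(0hr)`, likewise for J and AR.
#'
#' @param m0,m48 [angiogenic_metrics()] records sharing device and region
#'   identifiers (the 48-hr record computed in the registered frame).
#' @return A differential [angiogenic_metrics()] record (timepoint
#'   `"diff"`).
#' @export
differential_metrics <- function(m0, m48) {
  stopifnot(inherits(m0, "angiogenic_metrics"),
            inherits(m48, "angiogenic_metrics"))
  if (!identical(m0$device_id, m48$device_id) ||
      !identical(m0$region_index, m48$region_index))
    stop("device/region identifiers do not match", call. = FALSE)
  angiogenic_metrics(
    M_cyto = m48$M_cyto - m0$M_cyto,
    J_cyto = m48$J_cyto - m0$J_cyto,
    AR_cyto = m48$AR_cyto - m0$AR_cyto,
    M_hoechst = m48$M_hoechst - m0$M_hoechst,
    J_hoechst = m48$J_hoechst - m0$J_hoechst,
    AR_hoechst = m48$AR_hoechst - m0$AR_hoechst,
    timepoint_label = "diff", device_id = m0$device_id,
    region_index = m0$region_index, condition = m0$condition,
    flags = union(m0$flags, m48$flags), differential = TRUE)
}
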