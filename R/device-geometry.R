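#' Microfluidic device geometry
#'
#' Describes the gel-cage device: an array of cell growth regions, each a
#' strip of collagen gel of width `gel_width_um` caged between two rows of
#' trapezoidal PDMS posts whose base angle is supplementary to the
#' collagen/PDMS contact angle, flanked by two media channels. Defaults
#' reproduce the study device: 37 growth regions, 100 um nearest-point post
#' spacing, 60 degree posts, 1.3 mm gel width and an approximately 160 um
#' imaging depth split over 19 optical sections.
#'
#' @param ... named overrides of the default fields, or a single named list.
#'   Fields: `n_regions`, `post_spacing_um`, `post_base_angle_deg`,
#'   `gel_width_um`, `channel_width_um`, `channel_height_um`,
#'   `stack_depth_um`, `n_z_sections`, `voxel_size_um` (length-3, z/y/x),
#'   `post_top_um` (post face width along the gel interface),
#'   `post_depth_um` (post extent away from the gel), `margin_um`
#'   (imaged band beyond each gel boundary).
#' @return An object of class `device_geometry` (a validated named list).
#' @examples
#' device_geometry()                  # the study device
#' device_geometry(n_regions = 1)     # single-region variant
#' @export
device_geometry <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  defaults <- list(
    n_regions          = 37L,
    post_spacing_um    = 100,
    post_base_angle_deg = 60,
    gel_width_um       = 1300,
    channel_width_um   = 500,
    channel_height_um  = 120,
    stack_depth_um     = 160,
    n_z_sections       = 19L,
    voxel_size_um      = c(z = 160 / 19, y = 1.24, x = 1.24),
    post_top_um        = 150,
    post_depth_um      = 40,
    margin_um          = 60
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown device_geometry field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  geom <- utils::modifyList(defaults, overrides)

  geom$n_regions <- as.integer(geom$n_regions)
  geom$n_z_sections <- as.integer(geom$n_z_sections)
  .assert_scalar_num(geom$n_regions, "n_regions", lower = 1)
  .assert_scalar_num(geom$post_spacing_um, "post_spacing_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$post_base_angle_deg, "post_base_angle_deg",
                     lower = 0, upper = 90,
                     strict_lower = TRUE, strict_upper = TRUE)
  .assert_scalar_num(geom$gel_width_um, "gel_width_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$channel_width_um, "channel_width_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$channel_height_um, "channel_height_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$stack_depth_um, "stack_depth_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$n_z_sections, "n_z_sections", lower = 1)
  .assert_scalar_num(geom$post_top_um, "post_top_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$post_depth_um, "post_depth_um", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(geom$margin_um, "margin_um", lower = 0)
  if (length(geom$voxel_size_um) != 3L || any(geom$voxel_size_um <= 0))
    stop("'voxel_size_um' must be three positive lengths (z, y, x)",
         call. = FALSE)
  names(geom$voxel_size_um) <- c("z", "y", "x")
  if (geom$margin_um < geom$post_depth_um)
    geom$margin_um <- geom$post_depth_um  # posts must fit in the imaged band
  structure(geom, class = "device_geometry")
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("device_geometry:\n")
  cat(sprintf("  %d growth regions, post spacing %.0f um, post angle %.0f deg\n",
              x$n_regions, x$post_spacing_um, x$post_base_angle_deg))
  cat(sprintf("  gel width %.0f um, channels %.0f x %.0f um\n",
              x$gel_width_um, x$channel_width_um, x$channel_height_um))
  cat(sprintf("  stack: %.0f um depth over %d z-sections, voxel (%.2f, %.2f, %.2f) um\n",
              x$stack_depth_um, x$n_z_sections, x$voxel_size_um[1],
              x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

# Field-of-view extents (um) of one rendered growth region: x spans the
# opening between the two flanking posts plus the posts themselves; y spans
# the gel width plus the imaged PDMS/channel band on each side.
.region_extent <- function(geom) {
  list(x = 2 * geom$post_top_um + geom$post_spacing_um,
       y = geom$gel_width_um + 2 * geom$margin_um)
}

# Trapezoidal post polygons (list of 4 x 2 (x, y) matrices) for one region
# in region coordinates. Two posts per gel boundary; the post face (top of
# the trapezoid) is flush with the boundary, the base slopes away at the
# post base angle.
.post_polygons <- function(geom) {
  ext <- .region_extent(geom)
  y0 <- geom$margin_um                    # monolayer-side gel boundary
  y1 <- geom$margin_um + geom$gel_width_um
  run <- geom$post_depth_um / tan(geom$post_base_angle_deg * pi / 180)
  centers <- c(geom$post_top_um / 2, ext$x - geom$post_top_um / 2)
  polys <- list()
  for (xc in centers) {
    xt <- xc + c(-0.5, 0.5) * geom$post_top_um
    # boundary at y0: post occupies y in [y0 - depth, y0]
    polys[[length(polys) + 1L]] <- cbind(
      x = c(xt[1], xt[2], xt[2] + run, xt[1] - run),
      y = c(y0, y0, y0 - geom$post_depth_um, y0 - geom$post_depth_um))
    # boundary at y1: mirrored
    polys[[length(polys) + 1L]] <- cbind(
      x = c(xt[1], xt[2], xt[2] + run, xt[1] - run),
      y = c(y1, y1, y1 + geom$post_depth_um, y1 + geom$post_depth_um))
  }
  polys
}

# Post-face corner landmarks (n x 2, um): the points where each post face
# meets the gel boundary. Used as registration landmarks.
.post_corners <- function(geom) {
  polys <- .post_polygons(geom)
  do.call(rbind, lapply(polys, function(p) p[1:2, , drop = FALSE]))
}
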