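#' Multi-channel volumetric image stack
#'
#' The raw observation unit: a 4-channel confocal volume of one cell growth
#' region. Channels are 3D arrays of dimension (y, x, z) sharing one shape;
#' pixel centers sit at `(i - 0.5) * voxel_size_um` along each axis. The
#' canonical channel names are `cyto` (cytosolic stain), `hoechst` (nuclear
#' stain), `reflect` (reflected light) and `trans` (transmitted light).
#'
#' @param channels named list of 3D numeric arrays with identical dims.
#' @param voxel_size_um numeric length-3 voxel size, (z, y, x) in um.
#' @param timepoint_label timepoint tag, conventionally `"0hr"` or `"48hr"`.
#' @param device_id,region_index identifiers carried through to metrics.
#' @param meta free-form metadata list (ground truth, provenance, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um,
                        timepoint_label = "0hr",
                        device_id = "device1", region_index = 1L,
                        meta = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a named list of 3D arrays", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array (y, x, z)", call. = FALSE)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions", call. = FALSE)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be three positive lengths (z, y, x)",
         call. = FALSE)
  names(voxel_size_um) <- c("z", "y", "x")
  structure(list(channels = channels,
                 voxel_size_um = as.numeric(voxel_size_um) |>
                   stats::setNames(c("z", "y", "x")),
                 timepoint_label = timepoint_label,
                 device_id = device_id,
                 region_index = as.integer(region_index),
                 meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "image_stack '%s' region %d @ %s: %d x %d x %d (y,x,z), channels: %s\n",
    x$device_id, x$region_index, x$timepoint_label, d[1], d[2], d[3],
    paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (z,y,x): %.2f x %.2f x %.2f um\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

# Pixel-center coordinates (um) for a stack: list(x, y, z).
.stack_coords <- function(stack) {
  d <- dim(stack$channels[[1]])
  list(y = .axis_coords(d[1], stack$voxel_size_um["y"]),
       x = .axis_coords(d[2], stack$voxel_size_um["x"]),
       z = .axis_coords(d[3], stack$voxel_size_um["z"]))
}

# Mean-projection of one channel over z -> 2D matrix (y, x).
.z_project <- function(stack, channel) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("missing channel: ", channel, call. = FALSE)
  apply(ch, c(1, 2), mean)
}

# Voxel volume in um^3.
.voxel_volume <- function(stack) prod(stack$voxel_size_um)
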