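#' Write a stack to TIFF with a YAML sidecar
#'
#' Stores the stack as a multi-page 32-bit float TIFF (pages ordered
#' channel-major: all z-slices of the first channel, then the next
#' channel) plus a `.yml` sidecar carrying channel names, dimensions,
#' voxel size, identifiers and -- for phantoms -- the ground truth.
#'
#' @param stack an [image_stack()].
#' @param path output path; `.tif` is appended if absent, the sidecar uses
#'   the same stem with `.yml`.
#' @return Invisibly, the TIFF path.
#' @export
write_stack <- function(stack, path) {
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  sidecar <- sub("\\.tiff?$", ".yml", path)
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    for (k in seq_len(dim(arr)[3]))
      pages[[length(pages) + 1L]] <- arr[, , k]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)

  gt <- stack$meta$ground_truth
  meta <- list(
    channels = as.list(names(stack$channels)),
    dim_yxz = as.list(dim(stack$channels[[1]])),
    voxel_size_um = as.list(unname(stack$voxel_size_um)),
    timepoint_label = stack$timepoint_label,
    device_id = stack$device_id,
    region_index = stack$region_index)
  if (!is.null(gt)) {
    mt <- gt$metrics_true
    meta$ground_truth <- list(
      line1 = as.list(unname(gt$boundary_lines$line1)),
      line2 = as.list(unname(gt$boundary_lines$line2)),
      landmarks = apply(gt$landmarks, 1, as.list),
      monolayer_control_points =
        apply(gt$monolayer_control_points, 1, as.list),
      offset_um = gt$offset_um,
      clipped = as.list(gt$clipped),
      metrics_true = list(M_cyto = mt$M_cyto, J_cyto = mt$J_cyto,
                          AR_cyto = mt$AR_cyto, M_hoechst = mt$M_hoechst,
                          J_hoechst = mt$J_hoechst,
                          AR_hoechst = mt$AR_hoechst))
  }
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a stack written by [write_stack()] (or a plain multi-page TIFF)
#'
#' With a sidecar present, channel names, voxel size and identifiers are
#' restored from it. For a plain TIFF, `channels` and `voxel_size_um`
#' must be supplied (pages are assumed channel-major).
#'
#' @param path TIFF path.
#' @param channels channel names (overrides/required without sidecar).
#' @param voxel_size_um voxel size (z, y, x) um (required without
#'   sidecar metadata).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channels = NULL, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- sub("\\.tiff?$", ".yml", path)
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- channels %||% unlist(meta$channels) %||%
    stop("channel mapping unknown: supply 'channels' (expected e.g. cyto, hoechst, reflect, trans)",
         call. = FALSE)
  voxel_size_um <- voxel_size_um %||% unlist(meta$voxel_size_um) %||%
    stop("voxel size unknown: supply 'voxel_size_um' (z, y, x in um)",
         call. = FALSE)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0)
    stop(sprintf("page count %d is not a multiple of the %d named channels",
                 length(pages), n_ch), call. = FALSE)
  nz <- length(pages) %/% n_ch
  d <- dim(pages[[1]])
  chans <- list()
  for (i in seq_len(n_ch)) {
    arr <- array(0, c(d[1], d[2], nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[(i - 1L) * nz + k]]
    chans[[channels[i]]] <- arr
  }
  st <- image_stack(chans, voxel_size_um,
                    timepoint_label = meta$timepoint_label %||% "0hr",
                    device_id = meta$device_id %||% "unknown",
                    region_index = meta$region_index %||% 1L)
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    st$meta$ground_truth <- list(
      boundary_lines = list(
        line1 = stats::setNames(unlist(g$line1), c("intercept", "angle_deg")),
        line2 = stats::setNames(unlist(g$line2), c("intercept", "angle_deg"))),
      landmarks = do.call(rbind, lapply(g$landmarks, unlist)),
      monolayer_control_points =
        do.call(rbind, lapply(g$monolayer_control_points, unlist)),
      offset_um = g$offset_um,
      clipped = unlist(g$clipped),
      metrics_true = do.call(angiogenic_metrics, g$metrics_true))
  }
  st
}
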