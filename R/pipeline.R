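#' Pipeline configuration
#'
#' Every tunable of the end-to-end pipeline with its default.
#'
#' @param geom the expected [device_geometry()].
#' @param median_window odd median filter window (px).
#' @param k_sigma background threshold multiplier.
#' @param weights combined-signal weights `c(cyto, trans)`.
#' @param band_halfwidth_um monolayer band half-width (um).
#' @param offset_um integration offset past the monolayer (um).
#' @param refit_monolayer_48hr refit the monolayer on the 48-hr stack
#'   instead of transporting the 0-hr curve through the registration.
#' @param condition condition label attached to output records.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(geom = device_geometry(), median_window = 3L,
                            k_sigma = 3, weights = c(0.7, 0.3),
                            band_halfwidth_um = 6, offset_um = 10,
                            refit_monolayer_48hr = FALSE,
                            condition = "Control") {
  structure(list(geom = geom, median_window = median_window,
                 k_sigma = k_sigma, weights = weights,
                 band_halfwidth_um = band_halfwidth_um,
                 offset_um = offset_um,
                 refit_monolayer_48hr = refit_monolayer_48hr,
                 condition = condition),
            class = "pipeline_config")
}

# Transport a monolayer curve from the 0-hr frame into the 48-hr frame
# using the registration (which maps 48-hr coords onto 0-hr coords).
.curve_to_48hr_frame <- function(curve, tf) {
  pts0 <- cbind(curve$control_u, curve_eval(curve, curve$control_u))
  pts48 <- .apply_rigid_inv(tf, pts0)
  ord <- order(pts48[, 1])
  monolayer_curve(pts48[ord, 1], pts48[ord, 2], curve$band_halfwidth_um,
                  score = curve$score)
}

# Process one 0-hr / 48-hr stack pair -> list of three metrics records.
.process_pair <- function(s0, s48, config) {
  if (is.character(s0)) s0 <- read_stack(s0)
  if (is.character(s48)) s48 <- read_stack(s48)
  if (!identical(s0$device_id, s48$device_id) ||
      !identical(s0$region_index, s48$region_index))
    stop("stack pair does not share device/region identifiers",
         call. = FALSE)
  vyx0 <- s0$voxel_size_um[c("y", "x")]
  vyx48 <- s48$voxel_size_um[c("y", "x")]

  p0 <- preprocess_stack(s0, config$median_window, config$k_sigma)
  p48 <- preprocess_stack(s48, config$median_window, config$k_sigma)
  r0 <- detect_gel_boundaries(p0, config$geom)
  r48 <- detect_gel_boundaries(p48, config$geom)
  tf <- register_timepoints(r0, r48)

  sig0 <- combined_signal(.z_project(p0, "cyto"), .z_project(p0, "trans"),
                          config$weights)
  curve0 <- fit_monolayer(sig0, r0, vyx0,
                          band_halfwidth_um = config$band_halfwidth_um)
  curve48 <- if (config$refit_monolayer_48hr) {
    sig48 <- combined_signal(.z_project(p48, "cyto"),
                             .z_project(p48, "trans"), config$weights)
    fit_monolayer(sig48, r48, vyx48,
                  band_halfwidth_um = config$band_halfwidth_um)
  } else .curve_to_48hr_frame(curve0, tf)

  m0 <- compute_metrics(p0, r0, curve0, config$offset_um)
  m48 <- compute_metrics(p48, r48, curve48, config$offset_um)
  m0$condition <- m48$condition <- config$condition
  md <- differential_metrics(m0, m48)
  list(m0 = m0, m48 = m48, diff = md, transform = tf)
}

#' Run the full quantification pipeline
#'
#' For each 0-hr/48-hr stack pair: preprocess, detect the gel boundaries
#' at both timepoints, register the timepoints by their post-corner
#' landmarks, fit the monolayer on the 0-hr frame (the reference wall),
#' transport it into the 48-hr frame, compute the angiogenic metrics at
#' both timepoints and their growth-positive differentials. Failures are
#' recorded per region and the pipeline continues (regions are
#' independent). The pipeline is a pure function of (config, inputs).
#'
#' @param pairs list of pairs; each element a list with components `t0`
#'   and `t48`, either [image_stack()] objects or TIFF paths.
#' @param config a [pipeline_config()].
#' @param csv optional path: write the long-format metric table.
#' @return list with `table` (one row per region x timepoint), `records`
#'   (the metric objects), `failures` (per-region error messages) and
#'   `report` (parameter log).
#' @export
run_pipeline <- function(pairs, config = pipeline_config(), csv = NULL) {
  records <- list(); failures <- list(); rows <- list()
  for (i in seq_along(pairs)) {
    res <- tryCatch(.process_pair(pairs[[i]]$t0, pairs[[i]]$t48, config),
                    error = function(e)
                      structure(list(message = conditionMessage(e)),
                                class = "pipeline_failure"))
    if (inherits(res, "pipeline_failure")) {
      failures[[length(failures) + 1L]] <-
        list(pair = i, message = res$message)
      next
    }
    records[[length(records) + 1L]] <- res
    rows[[length(rows) + 1L]] <- rbind(as.data.frame(res$m0),
                                       as.data.frame(res$m48),
                                       as.data.frame(res$diff))
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), device = character(),
               region = integer(), timepoint = character())
  rownames(table) <- NULL
  if (!is.null(csv))
    utils::write.csv(table, csv, row.names = FALSE)
  list(table = table, records = records, failures = failures,
       report = list(config = config, n_pairs = length(pairs),
                     n_failed = length(failures)))
}

#' Flatten metric records into an ensemble table
#'
#' @param metrics list of [angiogenic_metrics()] records.
#' @return Long-format data.frame (one row per record).
#' @export
as_ensemble_records <- function(metrics) {
  do.call(rbind, lapply(metrics, as.data.frame))
}
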