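#' Median-filter a stack
#'
#' Applies a two-dimensional median filter of the given window to every
#' z-slice of every channel, suppressing impulsive noise while preserving
#' edges.
#'
#' @param stack an [image_stack()].
#' @param window odd window width in pixels (>= 1); 1 is the identity.
#' @return The filtered stack.
#' @export
median_filter_stack <- function(stack, window = 3L) {
  if (window %% 2 != 1 || window < 1)
    stop("'window' must be an odd positive integer", call. = FALSE)
  if (window == 1L) return(stack)
  radius <- (window - 1L) / 2L
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    # EBImage's median filter works on [0, 1]; rescale linearly around it
    top <- max(arr, 1e-12)
    for (k in seq_len(dim(arr)[3]))
      arr[, , k] <- EBImage::imageData(
        EBImage::medianFilter(arr[, , k] / top, radius)) * top
    stack$channels[[ch]] <- arr
  }
  stack
}

#' Grayscale normalization
#'
#' Linearly rescales every channel to span [0, 1] by its own minimum and
#' maximum. A constant channel maps to all zeros (with a warning). The
#' applied scale/offset per channel is recorded in `meta$normalization`.
#'
#' @param stack an [image_stack()].
#' @return The normalized stack.
#' @export
normalize_grayscale <- function(stack) {
  norm <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    rng <- range(arr)
    if (diff(rng) == 0) {
      warning(sprintf("channel '%s' is constant; normalized to zeros", ch))
      stack$channels[[ch]] <- array(0, dim(arr))
      norm[[ch]] <- c(min = rng[1], max = rng[1])
    } else {
      stack$channels[[ch]] <- (arr - rng[1]) / diff(rng)
      norm[[ch]] <- c(min = rng[1], max = rng[2])
    }
  }
  stack$meta$normalization <- norm
  stack
}

#' Gaussian background model
#'
#' Robustly fits a Gaussian to the dominant low-intensity mode of a channel
#' histogram (median/MAD initialization, then mean/sd of the trimmed core
#' within 4 sigma), ignoring the bright structure tail. The elimination
#' threshold is `mu + k_sigma * sigma`.
#'
#' @param channel 3D (or 2D) numeric array with at least 1000 voxels.
#' @param k_sigma threshold multiplier (default 3: 99.87% one-sided
#'   background suppression).
#' @return Object of class `background_model`: list(mu, sigma, threshold).
#' @export
estimate_background <- function(channel, k_sigma = 3) {
  v <- as.vector(channel)
  if (length(v) < 1000L)
    stop("need at least 1000 voxels to estimate the background",
         call. = FALSE)
  mu <- stats::median(v)
  sigma <- stats::mad(v)
  if (sigma > 0) {
    core <- v[abs(v - mu) <= 4 * sigma]
    if (length(core) < 0.3 * length(v))
      stop("no clear low-intensity mode; supply a manual threshold",
           call. = FALSE)
    mu <- mean(core)
    sigma <- stats::sd(core)
  }
  structure(list(mu = mu, sigma = sigma,
                 threshold = mu + k_sigma * sigma, k_sigma = k_sigma),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: mu = %.4g, sigma = %.4g, threshold = %.4g (k = %g)\n",
              x$mu, x$sigma, x$threshold, x$k_sigma))
  invisible(x)
}

#' Background elimination
#'
#' Zeroes every voxel at or below the background threshold; voxels above it
#' are kept unchanged (elimination, not subtraction). Applied per channel
#' with a per-channel model; by default only the fluorescence channels are
#' processed.
#'
#' @param stack an [image_stack()].
#' @param models named list of [estimate_background()] models per channel;
#'   missing models are estimated from the stack.
#' @param channels channels to process.
#' @param k_sigma threshold multiplier used when estimating.
#' @return The background-eliminated stack; models are recorded in
#'   `meta$background`.
#' @export
subtract_background <- function(stack, models = NULL,
                                channels = c("cyto", "hoechst"),
                                k_sigma = 3) {
  channels <- intersect(channels, names(stack$channels))
  models <- models %||% list()
  for (ch in channels) {
    m <- models[[ch]] %||% estimate_background(stack$channels[[ch]], k_sigma)
    models[[ch]] <- m
    arr <- stack$channels[[ch]]
    arr[arr <= m$threshold] <- 0
    stack$channels[[ch]] <- arr
  }
  stack$meta$background <- models
  stack
}

#' Standardize a raw stack
#'
#' The full preprocessing chain: 2D median filtering, grayscale
#' normalization, then Gaussian background elimination on the fluorescence
#' channels (declared order: normalization first, elimination on the
#' normalized scale).
#'
#' @param stack raw [image_stack()].
#' @param median_window odd median window (px).
#' @param k_sigma background threshold multiplier.
#' @return Preprocessed stack.
#' @export
preprocess_stack <- function(stack, median_window = 3L, k_sigma = 3) {
  stack <- median_filter_stack(stack, median_window)
  stack <- normalize_grayscale(stack)
  subtract_background(stack, k_sigma = k_sigma)
}
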