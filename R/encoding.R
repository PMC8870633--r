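#' Oriented convolution kernels
#'
#' Builds the four fixed feature-extraction kernels used by the spiking
#' encoder: one transverse (horizontal band), one longitudinal (vertical
#' band), and two cross-diagonal orientations. Within each kernel the band
#' weights are equal and sum to 1 (off-band entries are 0), so a uniform
#' image drives all four orientations identically and the joint min-max
#' rescaling of the feature stack does not favour the wider bands. For
#' even kernel sizes the horizontal/vertical band covers the two centre
#' rows/columns; for odd sizes the single centre row/column.
#'
#' @param size kernel side length, one of 3, 4, 5.
#' @return Named list of four `size x size` matrices:
#'   `transverse`, `longitudinal`, `diagonal`, `antidiagonal`.
#' @examples
#' oriented_kernels(3)$transverse
#' @export
oriented_kernels <- function(size) {
  if (!is.numeric(size) || length(size) != 1L || !size %in% 3:5)
    stop("kernel size must be 3, 4 or 5", call. = FALSE)
  size <- as.integer(size)
  band <- if (size %% 2L == 1L) (size + 1L) %/% 2L else c(size %/% 2L, size %/% 2L + 1L)
  transverse <- matrix(0, size, size)
  transverse[band, ] <- 1 / (length(band) * size)
  diagonal <- diag(1 / size, size)
  antidiagonal <- diagonal[, size:1]
  list(transverse = transverse,
       longitudinal = t(transverse),
       diagonal = diagonal,
       antidiagonal = antidiagonal)
}

#' Valid 2-D cross-correlation
#'
#' Slides the kernel over the image with stride 1 and no padding
#' (cross-correlation: the kernel is not flipped; the oriented kernels are
#' symmetric enough that this is a bookkeeping convention). The output side
#' is `nrow(image) - nrow(kernel) + 1`.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix no larger than `image` in either dimension.
#' @return Numeric matrix of the valid correlation.
#' @examples
#' convolve_valid(matrix(1, 5, 5), oriented_kernels(3)$transverse)
#' @export
convolve_valid <- function(image, kernel) {
  image <- as.matrix(image); kernel <- as.matrix(kernel)
  n <- nrow(image); m <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > n || kc > m)
    stop("kernel larger than image", call. = FALSE)
  out <- matrix(0, n - kr + 1L, m - kc + 1L)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] * image[i:(i + n - kr), j:(j + m - kc)]
    }
  }
  out
}

#' Non-overlapping max pooling
#'
#' Partitions the map into `pool x pool` windows with stride equal to the
#' window side and takes the maximum of each window. Incomplete border
#' rows/columns are dropped, so the output side is `floor(side / pool)` —
#' with 4x4 kernels on 28x28 images this takes the 25x25 feature maps to
#' 12x12, giving the 576-channel input layer.
#'
#' @param map numeric matrix.
#' @param pool window side, integer >= 2.
#' @return Pooled matrix of dimension `floor(dim(map) / pool)`.
#' @examples
#' max_pool(matrix(1:16, 4, 4), 2)
#' @export
max_pool <- function(map, pool) {
  map <- as.matrix(map)
  if (!is.numeric(pool) || length(pool) != 1L || pool < 2)
    stop("pool size must be an integer >= 2", call. = FALSE)
  pool <- as.integer(pool)
  nr <- nrow(map) %/% pool
  nc <- ncol(map) %/% pool
  if (nr < 1L || nc < 1L)
    stop("pool size larger than map", call. = FALSE)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(pool)) {
    for (j in seq_len(pool)) {
      sub <- map[seq.int(i, by = pool, length.out = nr),
                 seq.int(j, by = pool, length.out = nc), drop = FALSE]
      out <- pmax(out, sub)
    }
  }
  out
}

#' Oriented feature stack of an image
#'
#' Runs the four oriented kernels over the image and max-pools each raw
#' map, returning the four pooled feature maps that feed the spike coder.
#'
#' @param image integer/numeric matrix of pixel intensities in \[0, 255\].
#' @param kernel_size kernel side (3, 4 or 5).
#' @param pool_size pooling window side (2, 3 or 4).
#' @return List of 4 pooled feature maps (matrices of equal dimension),
#'   named by orientation.
#' @export
feature_stack <- function(image, kernel_size = 4, pool_size = 2) {
  image <- as.matrix(image)
  if (any(image < 0) || any(image > 255))
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  kernels <- oriented_kernels(kernel_size)
  lapply(kernels, function(k) max_pool(convolve_valid(image, k), pool_size))
}

# The four latency coders. Each maps an intensity V in [0, 255] to a raw
# delay in encoding units on the same [0, 255] scale; higher intensity
# never fires later. The linear coder is delay = 255 - V. The remaining
# three are implemented as 255/2^(V/32), 255/max(V,1) and 255/max(V,1)^2
# so that each spans (0, 255] over V in [1, 255].
delay_coders <- function() {
  list(
    linear      = function(v) 255 - v,
    exponential = function(v) 255 / 2^(v / 32),
    inverse     = function(v) 255 / pmax(v, 1),
    power       = function(v) 255 / pmax(v, 1)^2
  )
}

#' Latency-coding delay of a pixel intensity
#'
#' Maps intensities in \[0, 255\] to raw spike delays in encoding units
#' (also on a 0–255 scale, before rescaling to the simulation window).
#' All four coders are non-increasing in intensity: brighter pixels fire
#' earlier. `linear` is `255 - V`; `exponential` is `255 / 2^(V/32)`;
#' `inverse` is `255 / max(V, 1)`; `power` is `255 / max(V, 1)^2`.
#'
#' @param v numeric vector of intensities in \[0, 255\].
#' @param method one of `"linear"`, `"exponential"`, `"inverse"`, `"power"`.
#' @return Numeric vector of raw delays in \[0, 255\].
#' @examples
#' spike_delay(c(0, 255), "linear")  # 255, 0
#' @export
spike_delay <- function(v, method = "linear") {
  coders <- delay_coders()
  if (!method %in% names(coders))
    stop("unknown encoding method '", method, "'", call. = FALSE)
  if (any(v < 0) || any(v > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  coders[[method]](v)
}

#' Construct a spike train
#'
#' Low-level constructor validating the spike-train invariants: channel
#' indices within `1:n_channels`, event times within `[0, window_ms)`, and
#' events sorted by time (ties by channel).
#'
#' @param channel integer vector of 1-based channel indices.
#' @param time_ms numeric vector of spike times in ms.
#' @param n_channels total number of channels.
#' @param window_ms simulation window length in ms.
#' @return A data frame of class `"spike_train"` with columns `channel`
#'   and `time_ms`, and attributes `n_channels`, `window_ms`.
#' @export
spike_train <- function(channel, time_ms, n_channels, window_ms) {
  channel <- as.integer(channel)
  time_ms <- as.numeric(time_ms)
  stopifnot(length(channel) == length(time_ms),
            n_channels >= 1, window_ms > 0)
  if (length(channel) && (min(channel) < 1L || max(channel) > n_channels))
    stop("channel index out of range", call. = FALSE)
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) >= window_ms))
    stop("spike times must lie in [0, window_ms)", call. = FALSE)
  ord <- order(time_ms, channel)
  out <- data.frame(channel = channel[ord], time_ms = time_ms[ord])
  attr(out, "n_channels") <- as.integer(n_channels)
  attr(out, "window_ms") <- as.numeric(window_ms)
  class(out) <- c("spike_train", "data.frame")
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d events on %d channels, window %g ms\n",
              nrow(x), attr(x, "n_channels"), attr(x, "window_ms")))
  if (nrow(x)) print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Encode pooled feature maps as a spike train
#'
#' Flattens the feature stack into channels (kernel-major, column-major
#' within each map), min-max rescales the values jointly to \[0, 255\],
#' suppresses low-contrast channels, applies the configured latency coder,
#' and linearly rescales the raw delays from encoding units to
#' \[0, window_ms). Channels with rescaled intensity 0 emit no spike, so
#' each channel carries at most one event and a featureless (constant)
#' image produces an empty train.
#'
#' The contrast cut zeroes rescaled intensities below `contrast_cut` of the
#' maximum: oriented-band convolution of stroke images yields a bimodal
#' response (in-band ink vs background), and the weak tail is background
#' texture, not features. Suppressing it keeps the spike trains sparse and
#' event-driven, as latency coding of dark-background digits is meant to
#' be; set `contrast_cut = 0` for the raw behaviour.
#'
#' @param stack list of 4 equal-dimension feature maps ([feature_stack()]).
#' @param method latency coder name (see [spike_delay()]).
#' @param window_ms simulation window in ms.
#' @param contrast_cut fraction of the per-image maximum below which a
#'   channel is silenced (default 0.2).
#' @return A [spike_train()] with `n_channels = 4 * prod(dim(map))`.
#' @export
encode_features <- function(stack, method = "linear", window_ms = 100,
                            contrast_cut = 0.2) {
  stopifnot(is.list(stack), length(stack) == 4L,
            contrast_cut >= 0, contrast_cut < 1)
  dims <- vapply(stack, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("feature maps must share dimensions", call. = FALSE)
  v <- unlist(lapply(stack, as.numeric), use.names = FALSE)
  n_channels <- length(v)
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    v <- rep(0, n_channels)
  }
  v[v < contrast_cut * 255] <- 0
  raw <- spike_delay(v, method)
  t_ms <- raw / 255 * window_ms
  keep <- v > 0 & t_ms < window_ms
  spike_train(which(keep), t_ms[keep], n_channels, window_ms)
}

#' Encode an image as a spike train
#'
#' Full spiking-encoding pipeline: oriented convolution, max pooling and
#' latency coding in one call.
#'
#' @param image 28x28 (or any square) intensity matrix in \[0, 255\].
#' @param encoder encoder section of a configuration, e.g.
#'   `snn_config()$encoder`; a list with `kernel_size`, `pool_size`,
#'   `method`, `window_ms` and `contrast_cut`.
#' @return A [spike_train()].
#' @examples
#' img <- synth_digits(n_per_class = 1, classes = 3, seed = 1)$images[[1]]
#' encode_image(img, snn_config()$encoder)
#' @export
encode_image <- function(image, encoder = snn_config()$encoder) {
  stack <- feature_stack(image, encoder$kernel_size, encoder$pool_size)
  cut <- if (is.null(encoder$contrast_cut)) 0.2 else encoder$contrast_cut
  encode_features(stack, encoder$method, encoder$window_ms,
                  contrast_cut = cut)
}

#' Input channels per cluster for an encoder configuration
#'
#' For kernel side `k` and pool side `p` on a 28x28 image, each oriented map
#' contributes `floor((29 - k) / p)^2` channels; four orientations give the
#' cluster input size (576 for the default k = 4, p = 2).
#'
#' @param kernel_size kernel side.
#' @param pool_size pool side.
#' @param image_side input image side, default 28.
#' @return Integer channel count.
#' @export
n_input_channels <- function(kernel_size = 4, pool_size = 2, image_side = 28) {
  side <- (image_side - kernel_size + 1L) %/% pool_size
  as.integer(4L * side^2)
}
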