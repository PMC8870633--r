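#' Labelled image dataset
#'
#' Light container tying a list of 28x28 intensity matrices to their class
#' labels, with provenance metadata.
#'
#' @param images list of integer matrices with values in \[0, 255\].
#' @param labels integer vector of class ids in `0:9`, same length.
#' @param source `"synthetic"` or `"idx"`.
#' @param meta list of generator parameters or file provenance.
#' @return A list of class `"snn_dataset"`.
#' @export
snn_dataset <- function(images, labels, source = "synthetic", meta = list()) {
  labels <- as.integer(labels)
  stopifnot(length(images) == length(labels))
  if (length(labels) && (min(labels) < 0L || max(labels) > 9L))
    stop("labels must lie in 0:9", call. = FALSE)
  for (img in images) {
    if (!is.matrix(img) || min(img) < 0 || max(img) > 255)
      stop("images must be matrices with intensities in [0, 255]",
           call. = FALSE)
  }
  structure(list(images = images, labels = labels, source = source,
                 meta = meta),
            class = "snn_dataset")
}

#' @export
print.snn_dataset <- function(x, ...) {
  d <- if (length(x$images)) paste(dim(x$images[[1]]), collapse = "x") else "?"
  cat(sprintf("snn dataset: %d images (%s), source: %s\n",
              length(x$images), d, x$source))
  if (length(x$labels)) print(table(label = x$labels))
  invisible(x)
}

#' Read an MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX binary containers used by the MNIST dataset
#' (magic 2051 / 0x00000803 for unsigned-byte image tensors, 2049 /
#' 0x00000801 for label vectors) and checks that the image and label counts
#' match.
#'
#' @param images_path path to the image file.
#' @param labels_path path to the label file.
#' @param n optional cap on the number of images to keep.
#' @return An [snn_dataset()] with `source = "idx"`.
#' @export
read_idx <- function(images_path, labels_path, n = Inf) {
  for (pth in c(images_path, labels_path))
    if (!file.exists(pth)) stop("no such file: ", pth, call. = FALSE)
  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop("bad IDX magic in ", images_path, " (expected 2051, got ", magic,
         ")", call. = FALSE)
  hdr <- readBin(icon, "integer", 3, size = 4, endian = "big")
  n_img <- hdr[1]; nr <- hdr[2]; nc <- hdr[3]
  raw_px <- readBin(icon, "integer", n_img * nr * nc, size = 1,
                    signed = FALSE)
  if (length(raw_px) < n_img * nr * nc)
    stop("truncated IDX image file: ", images_path, call. = FALSE)

  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  if (!identical(lmagic, 2049L))
    stop("bad IDX magic in ", labels_path, " (expected 2049, got ", lmagic,
         ")", call. = FALSE)
  n_lab <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  if (n_lab != n_img)
    stop("IDX count mismatch: ", n_img, " images vs ", n_lab, " labels",
         call. = FALSE)
  labels <- readBin(lcon, "integer", n_lab, size = 1, signed = FALSE)
  if (length(labels) < n_lab)
    stop("truncated IDX label file: ", labels_path, call. = FALSE)

  keep <- seq_len(min(n_img, n))
  # IDX stores row-major: fill by row to recover the image orientation
  images <- lapply(keep, function(i) {
    offset <- (i - 1L) * nr * nc
    matrix(raw_px[offset + seq_len(nr * nc)], nr, nc, byrow = TRUE)
  })
  snn_dataset(images, labels[keep], source = "idx",
              meta = list(images_path = images_path,
                          labels_path = labels_path))
}

#' Write an IDX image/label file pair
#'
#' Inverse of [read_idx()]; mainly useful for round-trip tests and for
#' exporting synthetic data to other tools.
#'
#' @param data an [snn_dataset()].
#' @param images_path,labels_path output paths.
#' @return `data`, invisibly.
#' @export
write_idx <- function(data, images_path, labels_path) {
  stopifnot(inherits(data, "snn_dataset"), length(data$images) >= 1L)
  nr <- nrow(data$images[[1]]); nc <- ncol(data$images[[1]])
  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, length(data$images), nr, nc), icon, size = 4,
           endian = "big")
  for (img in data$images)
    writeBin(as.integer(t(img)), icon, size = 1)
  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, length(data$labels)), lcon, size = 4, endian = "big")
  writeBin(as.integer(data$labels), lcon, size = 1)
  invisible(data)
}

# Draw a straight stroke of the given half-thickness between two grid
# points (rows/cols), intensity 255, onto img.
draw_stroke <- function(img, r1, c1, r2, c2, thick = 1L) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) * 2L + 1L
  rr <- round(seq(r1, r2, length.out = n))
  cc <- round(seq(c1, c2, length.out = n))
  for (k in seq_len(n)) {
    rs <- pmax(1L, pmin(28L, rr[k]:(rr[k] + thick - 1L)))
    cs <- pmax(1L, pmin(28L, cc[k]:(cc[k] + thick - 1L)))
    img[rs, cs] <- 255L
  }
  img
}

# Stroke templates mimicking handwritten digit shapes: each class combines
# horizontal, vertical and diagonal strokes at positions/slopes of its own,
# so no class's active channel set is contained in another's after the
# oriented-kernel encoding (a subset class would be undecodable by a
# monotone nonnegative-weight readout).
digit_template <- function(digit) {
  img <- matrix(0L, 28, 28)
  th <- 2L
  strokes <- switch(as.character(digit),
    "0" = list(c(5, 10, 5, 18), c(23, 10, 23, 18),       # wide ring
               c(5, 9, 23, 9), c(5, 19, 23, 19)),
    "1" = list(c(5, 14, 23, 14), c(8, 11, 5, 14)),       # centre stem + flag
    "2" = list(c(5, 10, 5, 18), c(7, 18, 21, 9),         # top, full diagonal,
               c(22, 9, 22, 19)),                        # base
    "3" = list(c(5, 10, 5, 18), c(13, 12, 13, 18),       # three bars + right
               c(23, 10, 23, 18), c(5, 19, 23, 19)),
    "4" = list(c(5, 9, 13, 9), c(13, 9, 13, 19),         # open top-left
               c(5, 17, 23, 17)),
    "5" = list(c(5, 9, 5, 19), c(5, 9, 13, 9),           # top-left hook,
               c(13, 9, 13, 18), c(13, 19, 22, 19),      # lower-right bowl
               c(23, 9, 23, 18)),
    "6" = list(c(5, 10, 23, 10), c(23, 10, 23, 18),      # tall left spine,
               c(14, 18, 23, 18), c(14, 10, 14, 18)),    # lower loop
    "7" = list(c(5, 9, 5, 19), c(6, 19, 23, 13)),        # top + steep diagonal
    "8" = list(c(5, 11, 5, 17), c(13, 11, 13, 17),       # two stacked loops,
               c(23, 11, 23, 17), c(5, 12, 13, 12),      # waisted columns
               c(5, 17, 13, 17), c(14, 11, 23, 11),
               c(14, 18, 23, 18)),
    "9" = list(c(5, 12, 5, 19), c(5, 12, 13, 12),        # upper loop + tail
               c(13, 12, 13, 19), c(5, 19, 23, 19)),
    stop("digit must be in 0:9", call. = FALSE))
  for (s in strokes) img <- draw_stroke(img, s[1], s[2], s[3], s[4], th)
  img
}

#' Generate a synthetic stroke-digit dataset
#'
#' Renders each requested class as a fixed stroke-template glyph (thick
#' horizontal/vertical strokes at intensity 255 on a dark field, in the
#' style of seven-segment digits), then perturbs each sample with an
#' integer translation jitter and clipped Gaussian pixel noise. The result
#' emulates the gross statistics handwritten-digit encoders rely on —
#' bright oriented strokes on a dark 28x28 field, 10 discriminable classes
#' — while remaining fully deterministic per seed, so the whole pipeline is
#' testable with no download.
#'
#' @param n_per_class samples per class.
#' @param classes which digits to generate (subset of `0:9`).
#' @param noise_sd standard deviation of the additive pixel noise, in
#'   intensity units (clipped back to \[0, 255\]).
#' @param jitter_px maximum absolute translation in pixels, per axis.
#' @param seed RNG seed.
#' @return An [snn_dataset()] with `source = "synthetic"`.
#' @examples
#' d <- synth_digits(n_per_class = 2, seed = 1)
#' table(d$labels)
#' @export
synth_digits <- function(n_per_class = 100, classes = 0:9, noise_sd = 8,
                         jitter_px = 2, seed = 1) {
  stopifnot(n_per_class >= 1, all(classes %in% 0:9), noise_sd >= 0,
            jitter_px >= 0)
  templates <- lapply(classes, digit_template)
  images <- list(); labels <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      for (s in seq_len(n_per_class)) {
        img <- templates[[ci]]
        if (jitter_px > 0) {
          sh <- sample(seq.int(-jitter_px, jitter_px), 2, replace = TRUE)
          img <- shift_image(img, sh[1], sh[2])
        }
        if (noise_sd > 0) {
          img <- img + round(rnorm(length(img), 0, noise_sd))
          img <- pmin(255L, pmax(0L, img))
        }
        images[[length(images) + 1L]] <- matrix(as.integer(img), 28, 28)
        labels <- c(labels, classes[ci])
      }
    }
  })
  snn_dataset(images, labels, source = "synthetic",
              meta = list(n_per_class = n_per_class, classes = classes,
                          noise_sd = noise_sd, jitter_px = jitter_px,
                          seed = seed))
}

# Integer translation with zero fill.
shift_image <- function(img, dr, dc) {
  out <- matrix(0L, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dr
  src_c <- seq_len(ncol(img)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Write a spike train to CSV
#'
#' Diff-able, language-neutral dialect: a comment header carrying the
#' channel count and window, a `channel,time_ms` column header, then one
#' event per line.
#'
#' @param train a [spike_train()].
#' @param path output path.
#' @return `train`, invisibly.
#' @export
write_spike_csv <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# n_channels=%d window_ms=%s",
                     attr(train, "n_channels"),
                     format(attr(train, "window_ms"))), con)
  writeLines("channel,time_ms", con)
  if (nrow(train))
    writeLines(sprintf("%d,%s", train$channel,
                       format(train$time_ms, digits = 15, trim = TRUE)), con)
  invisible(train)
}

#' Read a spike train written by [write_spike_csv()]
#'
#' @param path input path.
#' @return A [spike_train()].
#' @export
read_spike_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# n_channels=", lines[1]))
    stop("not a spike-train CSV: ", path, call. = FALSE)
  n_channels <- as.integer(sub("^# n_channels=(\\d+).*", "\\1", lines[1]))
  window_ms <- as.numeric(sub(".*window_ms=([0-9.eE+-]+).*", "\\1", lines[1]))
  body <- lines[-(1:2)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    channel <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    time_ms <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  } else {
    channel <- integer(0); time_ms <- numeric(0)
  }
  spike_train(channel, time_ms, n_channels, window_ms)
}

#' Save / load a trained ensemble
#'
#' The model container is a directory holding a JSON manifest (encoder and
#' run configuration, seeds, dimensions, package version) plus flat binary
#' arrays for the weights, initial-weight snapshots and alive masks of
#' every cluster.
#'
#' @param ens a trained `"snn_ensemble"`.
#' @param path directory to create/overwrite.
#' @return `save_snn` returns `path` invisibly; `load_snn` returns the
#'   restored `"snn_ensemble"`.
#' @export
save_snn <- function(ens, path) {
  stopifnot(inherits(ens, "snn_ensemble"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "snnclust",
    version = as.character(utils::packageVersion("snnclust")),
    n_clusters = length(ens$clusters),
    n_inputs = ens$clusters[[1]]$n_inputs,
    n_classes = ens$n_classes,
    encoder = ens$encoder,
    seed = ens$seed,
    trained = isTRUE(ens$trained),
    cluster_seeds = vapply(ens$clusters, `[[`, integer(1), "seed"),
    config = unclass(ens$config)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  con <- file(file.path(path, "weights.bin"), "wb")
  for (cl in ens$clusters) writeBin(as.numeric(cl$W), con)
  close(con)
  con <- file(file.path(path, "winit.bin"), "wb")
  for (cl in ens$clusters) writeBin(as.numeric(cl$W_init), con)
  close(con)
  con <- file(file.path(path, "alive.bin"), "wb")
  for (cl in ens$clusters) writeBin(as.integer(cl$alive), con, size = 1)
  close(con)
  invisible(path)
}

#' @rdname save_snn
#' @export
load_snn <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  n_cl <- mf$n_clusters; n_in <- mf$n_inputs; n_de <- mf$n_classes
  block <- n_in * n_de
  wcon <- file(file.path(path, "weights.bin"), "rb")
  W_all <- readBin(wcon, "numeric", n_cl * block); close(wcon)
  icon <- file(file.path(path, "winit.bin"), "rb")
  Wi_all <- readBin(icon, "numeric", n_cl * block); close(icon)
  acon <- file(file.path(path, "alive.bin"), "rb")
  A_all <- readBin(acon, "integer", n_cl * block, size = 1); close(acon)
  clusters <- lapply(seq_len(n_cl), function(t) {
    idx <- (t - 1L) * block + seq_len(block)
    structure(list(n_inputs = as.integer(n_in), n_decode = as.integer(n_de),
                   W = matrix(W_all[idx], n_in, n_de),
                   W_init = matrix(Wi_all[idx], n_in, n_de),
                   alive = matrix(A_all[idx] != 0L, n_in, n_de),
                   seed = as.integer(mf$cluster_seeds[t])),
              class = "snn_cluster")
  })
  cfg <- if (!is.null(mf$config)) do.call(snn_config, mf$config) else NULL
  structure(list(clusters = clusters,
                 encoder = mf$encoder,
                 n_classes = as.integer(n_de),
                 seed = as.integer(mf$seed),
                 trained = isTRUE(mf$trained),
                 outcomes = NULL, config = cfg),
            class = "snn_ensemble")
}
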