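test_that("oriented kernels have the four stated orientations", {
  for (size in 3:5) {
    ks <- oriented_kernels(size)
    expect_named(ks, c("transverse", "longitudinal", "diagonal",
                       "antidiagonal"))
    for (k in ks) expect_equal(dim(k), c(size, size))
    # transverse: positive weights only on the centre row band
    band_rows <- unique(which(ks$transverse > 0, arr.ind = TRUE)[, 1])
    off <- setdiff(seq_len(size), band_rows)
    expect_true(all(ks$transverse[off, ] == 0))
    expect_true(all(ks$transverse[band_rows, ] > 0))
    # longitudinal is the transpose of its orthogonal partner
    expect_identical(ks$longitudinal, t(ks$transverse))
    expect_true(all(diag(ks$diagonal) > 0))
  }
  expect_error(oriented_kernels(6), "3, 4 or 5")
})

test_that("valid convolution has N - k + 1 output and matches a nested-loop oracle", {
  img28 <- matrix(runif(28 * 28, 0, 255), 28, 28)
  expect_equal(dim(convolve_valid(img28, oriented_kernels(4)$transverse)),
               c(25, 25))
  # constant image under a zero-sum kernel -> all zero
  zs <- matrix(c(1, -1), 2, 2)
  expect_true(all(abs(convolve_valid(matrix(7, 6, 6), zs)) < 1e-12))
  # single bright pixel reproduces the kernel weights at aligned offsets
  img <- matrix(0, 8, 8); img[4, 5] <- 1
  k <- matrix(1:9 / 10, 3, 3)
  expect_equal(convolve_valid(img, k), convolve_oracle(img, k))
  # random 8x8 inputs against the brute-force oracle
  set.seed(11)
  for (i in 1:5) {
    img <- matrix(rnorm(64), 8, 8)
    k <- matrix(rnorm(9), 3, 3)
    expect_equal(convolve_valid(img, k), convolve_oracle(img, k),
                 tolerance = 1e-12)
  }
  expect_error(convolve_valid(matrix(0, 3, 3), matrix(0, 4, 4)), "larger")
})

test_that("max pooling drops incomplete borders and matches the window oracle", {
  m25 <- matrix(runif(625), 25, 25)
  expect_equal(dim(max_pool(m25, 2)), c(12, 12))
  expect_equal(max_pool(m25, 2), maxpool_oracle(m25, 2))
  expect_true(all(max_pool(matrix(3, 9, 9), 3) == 3))
  set.seed(12)
  m6 <- matrix(rnorm(36), 6, 6)
  expect_equal(max_pool(m6, 3), maxpool_oracle(m6, 3))
  expect_error(max_pool(matrix(0, 2, 2), 3), "larger")
  expect_error(max_pool(m6, 1), ">= 2")
})

test_that("channel-count arithmetic matches floor((29 - k)/p)^2 per kernel", {
  for (k in 3:5) for (p in 2:4) {
    expect_identical(n_input_channels(k, p),
                     as.integer(4 * ((29 - k) %/% p)^2))
  }
  expect_identical(n_input_channels(4, 2), 576L)
  expect_identical(n_input_channels(3, 2), 676L)
})

test_that("delay coders are monotone and span the stated endpoints", {
  expect_equal(spike_delay(0, "linear"), 255)
  expect_equal(spike_delay(255, "linear"), 0)
  v <- 1:255
  for (m in c("linear", "exponential", "inverse", "power")) {
    d <- spike_delay(v, m)
    expect_true(all(diff(d) <= 0), info = m)  # never later for brighter
    expect_true(all(d >= 0 & d <= 255), info = m)
  }
  expect_error(spike_delay(10, "sigmoid"), "unknown encoding method")
  expect_error(spike_delay(300, "linear"), "\\[0, 255\\]")
})

test_that("encoding yields at most one in-window event per channel, sorted", {
  img <- synth_digits(n_per_class = 1, classes = 5, seed = 3)$images[[1]]
  enc <- snn_config()$encoder
  st <- encode_image(img, enc)
  expect_s3_class(st, "spike_train")
  expect_identical(attr(st, "n_channels"), 576L)
  expect_true(all(st$time_ms >= 0 & st$time_ms < enc$window_ms))
  expect_false(any(duplicated(st$channel)))
  expect_true(!is.unsorted(st$time_ms))
})

test_that("zero intensity emits no spike and constant images are silent", {
  stack <- list(matrix(0, 2, 2), matrix(0, 2, 2),
                matrix(0, 2, 2), matrix(c(0, 100, 200, 255), 2, 2))
  st <- encode_features(stack, "linear", 100, contrast_cut = 0)
  # channel 13 (value 0 after rescaling) must be absent
  expect_false(13L %in% st$channel)
  expect_true(16L %in% st$channel)   # the 255 channel fires earliest
  expect_equal(st$time_ms[st$channel == 16L], 0)
  # strictly higher intensity never fires later
  t100 <- st$time_ms[st$channel == 14L]
  t200 <- st$time_ms[st$channel == 15L]
  expect_lt(t200, t100)
  # featureless image
  flat <- encode_image(matrix(9, 28, 28), snn_config()$encoder)
  expect_identical(nrow(flat), 0L)
})

test_that("contrast cut silences weak channels only", {
  stack <- list(matrix(255, 1, 1), matrix(100, 1, 1),
                matrix(20, 1, 1), matrix(0, 1, 1))
  st <- encode_features(stack, "linear", 100, contrast_cut = 0.2)
  expect_setequal(st$channel, c(1L, 2L))  # 20/255 < 0.2 is cut
  st0 <- encode_features(stack, "linear", 100, contrast_cut = 0)
  expect_setequal(st0$channel, c(1L, 2L, 3L))
})

test_that("spike train constructor enforces its invariants", {
  expect_error(spike_train(5, 10, n_channels = 4, window_ms = 100),
               "out of range")
  expect_error(spike_train(1, 100, n_channels = 4, window_ms = 100),
               "window")
  st <- spike_train(c(3, 1), c(9, 2), 4, 100)
  expect_identical(st$channel, c(1L, 3L))  # re-sorted by time
})
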