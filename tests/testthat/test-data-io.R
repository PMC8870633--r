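test_that("IDX image/label pairs round-trip exactly", {
  d <- synth_digits(n_per_class = 1, classes = c(2, 7), seed = 8)
  ip <- tempfile(); lp <- tempfile()
  write_idx(d, ip, lp)
  back <- read_idx(ip, lp)
  expect_identical(back$labels, d$labels)
  expect_identical(back$images, d$images)
  expect_identical(back$source, "idx")
})

test_that("malformed IDX files are rejected with the offending file named", {
  ip <- tempfile(); lp <- tempfile()
  d <- synth_digits(n_per_class = 1, classes = 0, seed = 1)
  write_idx(d, ip, lp)
  bad <- tempfile()
  con <- file(bad, "wb")
  writeBin(c(1234L, 1L, 28L, 28L), con, size = 4, endian = "big")
  close(con)
  expect_error(read_idx(bad, lp), "magic.*2051")
  expect_error(read_idx(ip, bad), "magic.*2049")
  # count mismatch
  d2 <- synth_digits(n_per_class = 2, classes = 0, seed = 1)
  lp2 <- tempfile()
  write_idx(d2, tempfile(), lp2)
  expect_error(read_idx(ip, lp2), "mismatch")
  expect_error(read_idx(tempfile(), lp), "no such file")
})

test_that("synthetic digits are deterministic, in range, and class-pure without noise", {
  a <- synth_digits(n_per_class = 3, seed = 5)
  b <- synth_digits(n_per_class = 3, seed = 5)
  expect_identical(a$images, b$images)
  expect_false(identical(a$images,
                         synth_digits(n_per_class = 3, seed = 6)$images))
  px <- unlist(a$images)
  expect_true(all(px >= 0 & px <= 255))
  clean <- synth_digits(n_per_class = 2, noise_sd = 0, jitter_px = 0,
                        seed = 1)
  for (c in 0:9) {
    imgs <- clean$images[clean$labels == c]
    expect_identical(imgs[[1]], imgs[[2]])
  }
})

test_that("a nearest-template pixel classifier clears the sanity floor", {
  # translation-searched template matching: the templates plus every
  # translation within the generator's jitter range
  base <- synth_digits(n_per_class = 1, noise_sd = 0, jitter_px = 0,
                       seed = 1)
  shifts <- expand.grid(dr = -2:2, dc = -2:2)
  variants <- list(); vlabels <- integer(0)
  for (k in seq_along(base$images)) {
    for (s in seq_len(nrow(shifts))) {
      img <- base$images[[k]]
      img <- rbind(matrix(0L, 2, 28), img, matrix(0L, 2, 28))
      img <- cbind(matrix(0L, 32, 2), img, matrix(0L, 32, 2))
      variants[[length(variants) + 1L]] <-
        img[(3:30) + shifts$dr[s], (3:30) + shifts$dc[s]]
      vlabels <- c(vlabels, base$labels[k])
    }
  }
  d <- synth_digits(n_per_class = 10, seed = 9)
  pred <- vapply(d$images, function(im) {
    dists <- vapply(variants, function(tp)
      sum((as.numeric(im) - as.numeric(tp))^2), numeric(1))
    vlabels[which.min(dists)]
  }, integer(1))
  expect_gt(100 * mean(pred == d$labels), 95)
})

test_that("no synthetic class is channel-contained in another after encoding", {
  enc <- snn_config()$encoder
  clean <- synth_digits(n_per_class = 1, noise_sd = 0, jitter_px = 0,
                        seed = 1)
  chans <- lapply(clean$images, function(im) encode_image(im, enc)$channel)
  for (a in 1:10) for (b in setdiff(1:10, a)) {
    private <- mean(!chans[[a]] %in% chans[[b]])
    expect_gt(private, 0.05)
  }
})

test_that("configuration files merge over defaults and reject unknown keys", {
  expect_identical(snn_config()$train$clusters, 15L)
  f <- tempfile(fileext = ".yaml")
  writeLines(c("teacher:", "  encourage_ms: 80", "train:", "  clusters: 4"), f)
  cfg <- load_config(f)
  expect_equal(cfg$teacher$encourage_ms, 80)
  expect_identical(cfg$train$clusters, 4L)
  expect_equal(cfg$teacher$punish_ms, 35)  # untouched default

  writeLines("", f)
  expect_equal(load_config(f)$stdp$a_plus, snn_config()$stdp$a_plus)

  fj <- tempfile(fileext = ".json")
  writeLines('{"stdp": {"a_plus": 0.7}}', fj)
  expect_equal(load_config(fj)$stdp$a_plus, 0.7)

  writeLines(c("teachr:", "  encourage_ms: 80"), f)
  expect_error(load_config(f), "teacher")  # nearest-key hint
  writeLines(c("teacher:", "  encorage_ms: 80"), f)
  expect_error(load_config(f), "encourage_ms")
  expect_error(snn_config(teacher = list(encourage_ms = 120)),
               "window")
})

test_that("spike-train CSV files round-trip, including empty trains", {
  st <- spike_train(c(3, 1, 2), c(12.25, 0, 99.5), 10, 100)
  f <- tempfile(fileext = ".csv")
  write_spike_csv(st, f)
  expect_match(readLines(f, n = 1), "n_channels=10 window_ms=100")
  back <- read_spike_csv(f)
  expect_equal(back$time_ms, st$time_ms)
  expect_identical(back$channel, st$channel)
  expect_identical(attr(back, "n_channels"), 10L)

  empty <- spike_train(integer(0), numeric(0), 5, 50)
  write_spike_csv(empty, f)
  expect_identical(nrow(read_spike_csv(f)), 0L)
  expect_error(suppressWarnings(read_spike_csv(tempfile())))
})

test_that("model containers round-trip weights, masks and configuration", {
  cfg <- snn_config(train = list(clusters = 2L, subset_size = 4L,
                                 iterations = 1L, seed = 3L))
  data <- synth_digits(n_per_class = 1, classes = 0:3, seed = 4)
  ens <- train_ensemble(data, cfg)
  ens <- prune(ens, 0.05)
  dir <- file.path(tempdir(), "snn-model")
  save_snn(ens, dir)
  back <- load_snn(dir)
  for (t in 1:2) {
    expect_equal(back$clusters[[t]]$W, ens$clusters[[t]]$W)
    expect_equal(back$clusters[[t]]$W_init, ens$clusters[[t]]$W_init)
    expect_identical(back$clusters[[t]]$alive, ens$clusters[[t]]$alive)
  }
  expect_identical(back$n_classes, ens$n_classes)
  expect_equal(back$encoder$window_ms, ens$encoder$window_ms)
  # the restored model decodes identically
  st <- encode_image(data$images[[1]], ens$encoder)
  expect_identical(decode(back, st, cfg)$votes, decode(ens, st, cfg)$votes)
})
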