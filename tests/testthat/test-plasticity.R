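test_that("stdp_delta matches the explicit double-loop oracle", {
  p <- stdp_params()
  set.seed(21)
  for (i in 1:50) {
    pre <- runif(sample(1:5, 1), 0, 100)
    post <- runif(sample(1:4, 1), 0, 100)
    expect_equal(stdp_delta(pre, post, p), stdp_oracle(pre, post, p),
                 tolerance = 1e-12)
  }
  expect_identical(stdp_delta(numeric(0), 10, p), 0)
  expect_identical(stdp_delta(10, numeric(0), p), 0)
})

test_that("causal pairs potentiate and anti-causal pairs depress", {
  p <- stdp_params()
  expect_gt(stdp_delta(10, 15, p), 0)
  expect_lt(stdp_delta(15, 10, p), 0)
  expect_lt(stdp_delta(10, 10, p), 0)  # simultaneous counts as anti-causal
})

test_that("stdp_delta is antisymmetric under pre/post swap with symmetric constants", {
  p <- stdp_params(a_plus = 0.3, a_minus = 0.3, tau_plus = 15, tau_minus = 15)
  set.seed(22)
  for (i in 1:20) {
    pre <- runif(3, 0, 100); post <- runif(3, 0, 100)
    expect_equal(stdp_delta(pre, post, p), -stdp_delta(post, pre, p),
                 tolerance = 1e-12)
  }
})

test_that("teacher builder implements the bipolar signalling rule", {
  te_cfg <- snn_config()$teacher
  # the worked example: fired set {0,1,7,8}, label 1
  sig <- build_teacher_signals(c(0, 1, 7, 8), 1, te_cfg)
  expect_length(sig, 4)
  enc <- Filter(function(s) s$polarity == "encourage", sig)
  pun <- Filter(function(s) s$polarity == "punish", sig)
  expect_length(enc, 1)
  expect_identical(enc[[1]]$target, 1L)
  expect_equal(enc[[1]]$time, 70)
  expect_setequal(vapply(pun, `[[`, integer(1), "target"), c(0L, 7L, 8L))
  expect_true(all(vapply(pun, `[[`, numeric(1), "time") == 35))
  # fired set already correct -> nothing to signal
  expect_length(build_teacher_signals(1L, 1, te_cfg), 0)
  # silent network still receives the encouraging signal
  sig0 <- build_teacher_signals(integer(0), 4, te_cfg)
  expect_length(sig0, 1)
  expect_identical(sig0[[1]]$polarity, "encourage")
  expect_identical(sig0[[1]]$target, 4L)
  expect_error(build_teacher_signals(c(0, 1), 12, te_cfg), "invalid label")
})

test_that("bipolar update moves weights as the teachers dictate", {
  cfg <- snn_config()
  p <- do.call(stdp_params, cfg$stdp[names(cfg$stdp) != "w_init_max"])
  p_lif <- do.call(lif_params, cfg$lif)
  net <- new_cluster(8, 10, seed = 31)
  st <- spike_train(1:6, c(10, 20, 30, 40, 60, 80), 8, 100)

  # no teachers: identity
  rec0 <- simulate_cluster(net, st, list(), p_lif)
  expect_identical(apply_bipolar_update(net, st, rec0, list(), p)$W, net$W)

  # encourage-only with early inputs: active synapses onto L increase,
  # by exactly the stdp oracle against the forced spike
  L <- 3L
  te <- list(teacher_signal("encourage", L, 70, cfg$teacher$magnitude))
  rec <- simulate_cluster(net, st, te, p_lif)
  up <- apply_bipolar_update(net, st, rec, te, p, record_free = rec0)
  forced <- rec$spike_times[[L + 1]][rec$spike_times[[L + 1]] >= 70]
  for (i in 1:6) {
    expected <- stdp_oracle(st$time_ms[st$channel == i], forced, p)
    expect_equal(up$W[i, L + 1] - net$W[i, L + 1], expected,
                 tolerance = 1e-12)
  }
  expect_identical(up$W[, -(L + 1)], net$W[, -(L + 1)])  # other columns untouched
  expect_identical(up$W[7:8, ], net$W[7:8, ])            # inactive channels untouched

  # punish: column sum never increases; encourage: never decreases
  net_hot <- net; net_hot$W[] <- 150  # single events are suprathreshold
  rec_hot <- simulate_cluster(net_hot, st, list(), p_lif)
  expect_true(length(rec_hot$fired) > 0)
  pu <- list(teacher_signal("punish", rec_hot$fired[1], 35,
                            cfg$teacher$magnitude))
  rec_pu <- simulate_cluster(net_hot, st, pu, p_lif)
  down <- apply_bipolar_update(net_hot, st, rec_pu, pu, p,
                               record_free = rec_hot)
  j <- rec_hot$fired[1] + 1L
  expect_lte(sum(down$W[, j]), sum(net_hot$W[, j]))
  expect_gte(sum(up$W[, L + 1]), sum(net$W[, L + 1]))
})

test_that("updates are clipped to the weight bounds and skip dead synapses", {
  cfg <- snn_config()
  p <- stdp_params(a_plus = 100, a_minus = 100, w_min = 0, w_max = 50)
  p_lif <- do.call(lif_params, cfg$lif)
  net <- new_cluster(4, 10, seed = 32)
  net$alive[2, ] <- FALSE
  frozen <- net$W[2, ]
  st <- spike_train(1:4, c(10, 20, 30, 80), 4, 100)
  rec0 <- simulate_cluster(net, st, list(), p_lif)
  te <- list(teacher_signal("encourage", 0, 70),
             teacher_signal("punish", 1, 35))
  rec <- simulate_cluster(net, st, te, p_lif)
  up <- apply_bipolar_update(net, st, rec, te, p, record_free = rec0)
  expect_true(all(up$W >= p$w_min & up$W <= p$w_max))
  expect_identical(up$W[2, ], frozen)
})

test_that("train_sample converges immediately when the response is already correct", {
  cfg <- snn_config()
  net <- zero_cluster(n_inputs = 2, n_decode = 3)
  net$W[1, 2] <- 300  # neuron 1 fires alone
  st <- spike_train(1, 10, 2, 100)
  res <- train_sample(net, st, 1L, cfg)
  expect_true(res$outcome$converged)
  expect_identical(res$outcome$iterations, 0L)
  expect_identical(res$outcome$final_M, 1L)
  expect_identical(res$net$W, net$W)
})

test_that("hitting the iteration cap is an outcome, not an error", {
  cfg <- snn_config(stdp = list(a_plus = 1e-9, a_minus = 1e-9),
                    train = list(max_inner_iters = 3L))
  net <- zero_cluster(n_inputs = 2, n_decode = 3)
  st <- spike_train(1:2, c(10, 20), 2, 100)
  res <- train_sample(net, st, 0L, cfg)
  expect_false(res$outcome$converged)
  expect_identical(res$outcome$iterations, 3L)
})

test_that("a two-class toy pattern is learned within 20 iterations per sample", {
  cfg <- snn_config()
  fx <- separable_spike_set(n_per_class = 3, n_classes = 2, n_channels = 80,
                            block_size = 30, seed = 41)
  net <- new_cluster(80, 10, seed = 42)
  for (s in fx) {
    res <- train_sample(net, s$train, s$label, cfg)
    net <- res$net
    expect_true(res$outcome$converged)
    expect_lte(res$outcome$iterations, 20)
  }
  ens <- wrap_ensemble(net)
  expect_equal(evaluate_accuracy(ens, fx, cfg)$accuracy, 100)
})

test_that("training is reproducible bit-for-bit and order-deterministic", {
  cfg <- snn_config()
  fx <- separable_spike_set(n_per_class = 2, n_classes = 3, n_channels = 60,
                            block_size = 15, seed = 43)
  net <- new_cluster(60, 10, seed = 44)
  r1 <- train_cluster(net, fx, cfg)
  r2 <- train_cluster(net, fx, cfg)
  expect_identical(r1$net$W, r2$net$W)
  # singleton subset is exactly one train_sample call
  one <- train_cluster(net, fx[1], cfg)
  direct <- train_sample(net, fx[[1]]$train, fx[[1]]$label, cfg)
  expect_identical(one$net$W, direct$net$W)
  expect_error(train_cluster(net, list(), cfg), "empty")
})
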