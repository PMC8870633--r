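#' STDP parameters
#'
#' Pair-based additive spike-timing-dependent plasticity constants, plus the
#' weight bounds and the punish-round scaling used by the bipolar rule.
#'
#' @param a_plus potentiation amplitude per causal pair.
#' @param a_minus depression amplitude per anti-causal pair.
#' @param tau_plus,tau_minus exponential windows, ms.
#' @param w_min,w_max hard weight bounds (weights are clipped after every
#'   update).
#' @param punish_scale multiplier on the anti-STDP depression applied under
#'   a punishing teacher; 0 disables depression, leaving suppression only.
#' @return A list of class `"stdp_params"`.
#' @export
stdp_params <- function(a_plus = 0.5, a_minus = 0.25, tau_plus = 20,
                        tau_minus = 20, w_min = 0, w_max = 50,
                        punish_scale = 1) {
  p <- list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
            tau_minus = tau_minus, w_min = w_min, w_max = w_max,
            punish_scale = punish_scale)
  stopifnot(p$a_plus > 0, p$a_minus > 0, p$tau_plus > 0, p$tau_minus > 0,
            p$w_min < p$w_max, p$punish_scale >= 0)
  class(p) <- "stdp_params"
  p
}

#' Pairwise STDP weight change
#'
#' All-pairs additive STDP: every causal pair (pre spike before post spike)
#' contributes `a_plus * exp(-(t_post - t_pre) / tau_plus)` of potentiation,
#' every anti-causal pair (pre at or after post) contributes
#' `a_minus * exp(-(t_pre - t_post) / tau_minus)` of depression, so the
#' update complies with the causality of the input spike sequence.
#'
#' @param pre_times numeric vector of presynaptic spike times, ms.
#' @param post_times numeric vector of postsynaptic spike times, ms.
#' @param p [stdp_params()].
#' @return Scalar weight change (0 when either list is empty).
#' @examples
#' stdp_delta(10, 15, stdp_params())  # causal: positive
#' stdp_delta(15, 10, stdp_params())  # anti-causal: negative
#' @export
stdp_delta <- function(pre_times, post_times, p = stdp_params()) {
  if (length(pre_times) == 0L || length(post_times) == 0L) return(0)
  d <- outer(post_times, pre_times, "-")  # t_post - t_pre
  causal <- d > 0
  sum(p$a_plus * exp(-d[causal] / p$tau_plus)) -
    sum(p$a_minus * exp(d[!causal] / p$tau_minus))
}

#' Build teacher signals from a firing outcome
#'
#' Implements the signalling step of the bipolar supervised rule: one
#' encouraging signal for the label neuron (emitted whether or not it
#' fired, since the forced spike is the only mechanism that can potentiate
#' a silent label neuron), and one punishing signal for every other neuron
#' that fired. When the fired set is exactly the label neuron no signals
#' are needed and the list is empty.
#'
#' @param M integer vector of fired decode-neuron indices (0-based labels).
#' @param L the sample's class label in `0:(n_classes - 1)`.
#' @param teacher teacher section of a configuration
#'   (`snn_config()$teacher`): `encourage_ms`, `punish_ms`, `magnitude`.
#' @param n_classes number of decode neurons.
#' @return List of [teacher_signal()]s.
#' @examples
#' sig <- build_teacher_signals(c(0, 1, 7, 8), 1, snn_config()$teacher)
#' vapply(sig, `[[`, integer(1), "target")
#' @export
build_teacher_signals <- function(M, L, teacher = snn_config()$teacher,
                                  n_classes = 10) {
  stopifnot(length(L) == 1L)
  if (L < 0 || L >= n_classes || L != round(L))
    stop("invalid label ", L, call. = FALSE)
  M <- as.integer(M)
  if (setequal(M, L)) return(list())
  signals <- list(teacher_signal("encourage", L, teacher$encourage_ms,
                                 teacher$magnitude))
  for (x in sort(setdiff(M, L))) {
    signals[[length(signals) + 1L]] <-
      teacher_signal("punish", x, teacher$punish_ms, teacher$magnitude)
  }
  signals
}

#' Apply one bipolar supervised weight update
#'
#' For each encouraging teacher, the synapses onto its target are updated
#' by `+stdp_delta` computed against the target's spikes in the teacher-run
#' record (which include the teacher-forced spike, so causally earlier
#' inputs potentiate). For each punishing teacher, the synapses onto its
#' target are depressed by `punish_scale * |stdp_delta|` computed against
#' that neuron's natural (teacher-free) spikes — the very firing that put it
#' in the fired set — so the activity that drove the wrong neuron is
#' unlearned even though the hyperpolarizing pulse silences it during the
#' teacher run itself. All weights are clipped to `[w_min, w_max]`; dead
#' (pruned) synapses are never touched.
#'
#' @param net a cluster ([new_cluster()]).
#' @param train the input [spike_train()].
#' @param record the `"firing_record"` produced by simulating `net` on
#'   `train` under `teachers`.
#' @param teachers list of [teacher_signal()]s used for that simulation.
#' @param p [stdp_params()].
#' @param record_free the teacher-free `"firing_record"` from which the
#'   fired set was built; punished targets are depressed against its
#'   spikes. Defaults to `record`.
#' @return The updated cluster.
#' @export
apply_bipolar_update <- function(net, train, record, teachers,
                                 p = stdp_params(), record_free = record) {
  if (attr(train, "n_channels") != net$n_inputs ||
      record$n_decode != net$n_decode ||
      record_free$n_decode != net$n_decode)
    stop("shape mismatch between cluster, train and record", call. = FALSE)
  if (length(teachers) == 0L) return(net)
  for (te in teachers) {
    j <- te$target + 1L
    # encourage: credit is assigned against the teacher-forced spike(s)
    # only; punish: against the natural (teacher-free) spikes that put the
    # neuron in the fired set.
    post <- if (te$polarity == "punish") record_free$spike_times[[j]]
            else record$spike_times[[j]][record$spike_times[[j]] >= te$time]
    if (length(post) == 0L) next
    # each channel contributes the summed pair terms of its (few) events
    contrib <- outer(train$time_ms, post, function(tp, to) {
      d <- to - tp
      ifelse(d > 0, p$a_plus * exp(-d / p$tau_plus),
             -p$a_minus * exp(d / p$tau_minus))
    })
    dw_by_channel <- rowsum(rowSums(contrib), train$channel)
    ch <- as.integer(rownames(dw_by_channel))
    dw <- dw_by_channel[, 1]
    if (te$polarity == "punish") dw <- -p$punish_scale * abs(dw)
    live <- net$alive[ch, j]
    net$W[ch, j] <- pmin(p$w_max, pmax(p$w_min, net$W[ch, j] + dw * live))
  }
  net
}

#' Train a cluster on one labelled spike train
#'
#' The inner loop of bipolar supervised learning: simulate teacher-free,
#' and while the fired set is not exactly the label neuron, build teacher
#' signals from it, re-simulate under the teachers, apply the bipolar
#' update, and re-check with a teacher-free verification pass. The loop is
#' capped; hitting the cap is an outcome (`converged = FALSE`), not an
#' error.
#'
#' @param net a cluster.
#' @param train the encoded sample.
#' @param L its class label (0-based).
#' @param cfg a full [snn_config()].
#' @return List with `net` (updated cluster) and `outcome`, a
#'   `"train_outcome"` with `converged`, `iterations` and `final_M` (the
#'   teacher-free fired set after the last update).
#' @export
train_sample <- function(net, train, L, cfg = snn_config()) {
  p_lif <- do.call(lif_params, cfg$lif)
  p_stdp <- do.call(stdp_params, cfg$stdp[names(cfg$stdp) != "w_init_max"])
  rec <- simulate_cluster(net, train, list(), p_lif)
  M <- rec$fired
  iters <- 0L
  while (!setequal(M, L) && iters < cfg$train$max_inner_iters) {
    teachers <- build_teacher_signals(M, L, cfg$teacher, net$n_decode)
    rec_t <- simulate_cluster(net, train, teachers, p_lif)
    net <- apply_bipolar_update(net, train, rec_t, teachers, p_stdp,
                                record_free = rec)
    iters <- iters + 1L
    rec <- simulate_cluster(net, train, list(), p_lif)
    M <- rec$fired
  }
  outcome <- structure(list(converged = setequal(M, L), iterations = iters,
                            final_M = M),
                       class = "train_outcome")
  list(net = net, outcome = outcome)
}

#' Train a cluster on a subset of labelled spike trains
#'
#' One pass over the subset in the given (sampled) order, applying
#' [train_sample()] to each element. Deterministic for a fixed subset
#' order.
#'
#' @param net a cluster.
#' @param subset list of `list(train = <spike_train>, label = <0-based>)`.
#' @param cfg a full [snn_config()].
#' @return List with `net` and `outcomes` (one `"train_outcome"` per
#'   sample).
#' @export
train_cluster <- function(net, subset, cfg = snn_config()) {
  if (length(subset) == 0L) stop("empty training subset", call. = FALSE)
  outcomes <- vector("list", length(subset))
  for (i in seq_along(subset)) {
    res <- train_sample(net, subset[[i]]$train, subset[[i]]$label, cfg)
    net <- res$net
    outcomes[[i]] <- res$outcome
  }
  list(net = net, outcomes = outcomes)
}
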