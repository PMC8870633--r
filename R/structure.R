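#' Construct a single untrained cluster
#'
#' A cluster is a fully connected bipartite net: `n_inputs` encoded channels
#' feeding `n_decode` decode-layer neurons (one per class). Weights are
#' drawn uniformly on `[0, w_init_max]`; the construction-time snapshot
#' `W_init` is kept for structural learning and is never refreshed, and the
#' `alive` mask starts all true.
#'
#' @param n_inputs input channel count.
#' @param n_decode decode neuron count (number of classes).
#' @param seed RNG seed for the weight draw.
#' @param w_init_max upper bound of the uniform initial weights.
#' @return A list of class `"snn_cluster"` with `n_inputs`, `n_decode`,
#'   `W`, `W_init` and `alive` (all matrices `n_inputs x n_decode`).
#' @export
new_cluster <- function(n_inputs, n_decode = 10, seed = 1, w_init_max = 5) {
  stopifnot(n_inputs >= 1, n_decode >= 1, w_init_max > 0)
  W <- with_seed(seed, matrix(runif(n_inputs * n_decode, 0, w_init_max),
                              n_inputs, n_decode))
  structure(list(n_inputs = as.integer(n_inputs),
                 n_decode = as.integer(n_decode),
                 W = W, W_init = W,
                 alive = matrix(TRUE, n_inputs, n_decode),
                 seed = as.integer(seed)),
            class = "snn_cluster")
}

#' @export
print.snn_cluster <- function(x, ...) {
  cat(sprintf("spiking cluster: %d input channels -> %d decode neurons (%d/%d synapses alive)\n",
              x$n_inputs, x$n_decode, sum(x$alive), length(x$alive)))
  invisible(x)
}

#' Build an untrained cluster-grouped network
#'
#' Constructs `clusters` structurally identical clusters whose input size is
#' determined by the encoder configuration: four oriented feature maps of
#' side `floor((29 - kernel_size) / pool_size)` on 28x28 images. With the
#' default 4x4 kernel and 2x2 pooling each cluster has 576 input channels
#' and 10 decode neurons (586 neurons), and a 15-cluster network carries
#' 86,400 trainable synapses. Per-cluster weight draws use sub-seeds
#' derived from `seed`, so construction and training are independent of
#' cluster execution order.
#'
#' @param encoder encoder section of a configuration (see [snn_config()]).
#' @param clusters number of clusters `T`.
#' @param n_classes decode neurons per cluster.
#' @param seed global seed from which per-cluster seeds are derived.
#' @param w_init_max upper bound of the uniform initial weights.
#' @param image_side input image side, default 28.
#' @return An object of class `"snn_ensemble"`: list with `clusters` (list
#'   of `"snn_cluster"`), `encoder`, `n_classes`, `seed` and `trained`.
#' @examples
#' ens <- build_network(snn_config()$encoder, clusters = 15)
#' count_synapses(ens)
#' @export
build_network <- function(encoder = snn_config()$encoder, clusters = 15,
                          n_classes = 10, seed = 1, w_init_max = 5,
                          image_side = 28) {
  stopifnot(clusters >= 1, n_classes >= 1)
  n_in <- n_input_channels(encoder$kernel_size, encoder$pool_size, image_side)
  seeds <- derive_seeds(seed, clusters)
  nets <- lapply(seq_len(clusters), function(t)
    new_cluster(n_in, n_classes, seed = seeds[t], w_init_max = w_init_max))
  structure(list(clusters = nets, encoder = encoder,
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 trained = FALSE, outcomes = NULL, config = NULL),
            class = "snn_ensemble")
}

#' Prune synapses whose weight barely changed
#'
#' Structural learning by use-and-disuse: a synapse whose trained weight
#' moved less than `w_change` from its construction-time value,
#' `|W - W_init| < w_change` (strict), was not involved in learning and is
#' eliminated. Pruning only clears `alive` flags — weights are untouched
#' and already-dead synapses stay dead — so it is idempotent and monotone
#' in the threshold. A threshold of 0 prunes nothing.
#'
#' @param net an `"snn_cluster"` or `"snn_ensemble"`.
#' @param w_change non-negative threshold in weight units.
#' @return The object with its `alive` mask(s) updated.
#' @export
prune <- function(net, w_change) UseMethod("prune")

#' @export
prune.snn_cluster <- function(net, w_change) {
  if (!is.numeric(w_change) || length(w_change) != 1L || w_change < 0)
    stop("pruning threshold must be a single non-negative number",
         call. = FALSE)
  net$alive <- net$alive & (abs(net$W - net$W_init) >= w_change)
  net
}

#' @export
prune.snn_ensemble <- function(net, w_change) {
  net$clusters <- lapply(net$clusters, prune, w_change = w_change)
  net
}

#' Count live synapses
#'
#' @param ens an `"snn_ensemble"` or single `"snn_cluster"`.
#' @return List with `alive`, `total` and `proportion` (alive/total).
#' @export
count_synapses <- function(ens) {
  masks <- if (inherits(ens, "snn_cluster")) list(ens$alive)
           else lapply(ens$clusters, `[[`, "alive")
  alive <- sum(vapply(masks, sum, numeric(1)))
  total <- sum(vapply(masks, length, numeric(1)))
  list(alive = alive, total = total, proportion = alive / total)
}

#' Pruning threshold sweep
#'
#' Applies each threshold to a fresh copy of the trained ensemble, scores
#' it on the evaluation set, and reports accuracy alongside the surviving
#' synapse count — the standard report for choosing a structural-learning
#' threshold.
#'
#' @param ens a trained `"snn_ensemble"`.
#' @param thresholds numeric vector of pruning thresholds.
#' @param test a dataset ([snn_dataset()]) to score against.
#' @param cfg full configuration (LIF parameters for evaluation).
#' @return Data frame with columns `threshold`, `accuracy` (percent),
#'   `proportion` (percent of synapses alive) and `alive`, sorted by
#'   threshold.
#' @export
prune_sweep <- function(ens, thresholds, test, cfg = snn_config()) {
  if (length(thresholds) == 0L) stop("empty threshold list", call. = FALSE)
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    pruned <- prune(ens, th)
    counts <- count_synapses(pruned)
    acc <- evaluate_accuracy(pruned, test, cfg)
    data.frame(threshold = th, accuracy = acc$accuracy,
               proportion = 100 * counts$proportion, alive = counts$alive)
  })
  do.call(rbind, rows)
}
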