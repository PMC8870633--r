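#' Bootstrap training subsets
#'
#' Draws one subset per cluster, each of `n_sub` samples with replacement
#' from the encoded training set. Draws use per-cluster derived sub-seeds,
#' so subset `t` is the same whatever order clusters are processed in.
#'
#' @param n_samples size of the training set being resampled.
#' @param clusters number of subsets `T`.
#' @param n_sub samples per subset.
#' @param seed global seed.
#' @return List of `clusters` integer index vectors of length `n_sub`.
#' @export
bootstrap_subsets <- function(n_samples, clusters, n_sub, seed = 1) {
  if (n_samples < 1L) stop("cannot bootstrap an empty training set",
                           call. = FALSE)
  stopifnot(clusters >= 1, n_sub >= 1)
  seeds <- derive_seeds(seed, clusters)
  lapply(seq_len(clusters), function(t)
    with_seed(seeds[t], sample.int(n_samples, n_sub, replace = TRUE)))
}

#' Train a cluster-grouped ensemble
#'
#' The full co-learning procedure: encode the training images once, build
#' the network, draw one bootstrap subset per cluster, train each cluster
#' on its subset for `iterations` passes with the bipolar supervised rule,
#' and (if a pruning threshold is configured) apply structural learning to
#' each cluster after its training. Clusters are trained independently with
#' derived sub-seeds, so results do not depend on the order in which they
#' are processed.
#'
#' Most users should call [snn_fit()] instead, which wraps this in the
#' standard modelling interface.
#'
#' @param data an [snn_dataset()] of labelled images.
#' @param cfg a full [snn_config()].
#' @return A trained `"snn_ensemble"`.
#' @export
train_ensemble <- function(data, cfg = snn_config()) {
  stopifnot(inherits(data, "snn_dataset"))
  if (length(data$images) == 0L) stop("empty training set", call. = FALSE)
  tr <- cfg$train
  trains <- lapply(data$images, encode_image, encoder = cfg$encoder)
  ens <- build_network(cfg$encoder, clusters = tr$clusters,
                       n_classes = 10, seed = tr$seed,
                       w_init_max = cfg$stdp$w_init_max)
  idx <- bootstrap_subsets(length(trains), tr$clusters, tr$subset_size,
                           seed = tr$seed)
  outcomes <- vector("list", tr$clusters)
  for (t in seq_len(tr$clusters)) {
    subset <- lapply(idx[[t]], function(i)
      list(train = trains[[i]], label = data$labels[i]))
    net <- ens$clusters[[t]]
    for (pass in seq_len(tr$iterations)) {
      res <- train_cluster(net, subset, cfg)
      net <- res$net
    }
    if (!is.null(tr$prune_threshold)) net <- prune(net, tr$prune_threshold)
    ens$clusters[[t]] <- net
    outcomes[[t]] <- res$outcomes
  }
  ens$trained <- TRUE
  ens$outcomes <- outcomes
  ens$config <- cfg
  ens
}

#' Decode one image with a trained ensemble
#'
#' Teacher-free readout: the image is encoded and every cluster simulated
#' without any teacher signal; the second decode layer is a deterministic
#' accumulator in which output neuron `j` sums the spike counts of every
#' cluster's decode neuron `j`. The prediction is the argmax of the vote
#' vector; ties are broken by the earliest first-spike time across
#' clusters, then by the lowest label index. If no neuron fires anywhere
#' the prediction falls back to label 0 and is flagged `no_spike`.
#'
#' @param ens a trained `"snn_ensemble"`.
#' @param image a 28x28 intensity matrix, or a pre-encoded [spike_train()].
#' @param cfg configuration supplying the LIF parameters; defaults to the
#'   one stored in the ensemble.
#' @return A list of class `"snn_prediction"`: `label`, `votes` (named
#'   per-class spike counts), `first_spike` (earliest per-class spike time
#'   across clusters), `no_spike`, and `per_cluster` spike-count matrix.
#' @export
decode <- function(ens, image, cfg = NULL) {
  stopifnot(inherits(ens, "snn_ensemble"))
  if (length(ens$clusters) == 0L) stop("empty ensemble", call. = FALSE)
  if (is.null(cfg)) cfg <- if (!is.null(ens$config)) ens$config else snn_config()
  p_lif <- do.call(lif_params, cfg$lif)
  train <- if (inherits(image, "spike_train")) image
           else encode_image(image, ens$encoder)
  n_cls <- ens$n_classes
  counts <- matrix(0L, length(ens$clusters), n_cls)
  first <- rep(Inf, n_cls)
  for (t in seq_along(ens$clusters)) {
    rec <- simulate_cluster(ens$clusters[[t]], train, list(), p_lif)
    counts[t, ] <- lengths(rec$spike_times)
    first <- pmin(first, ifelse(is.na(rec$first_spike), Inf, rec$first_spike))
  }
  votes <- as.integer(colSums(counts))
  names(votes) <- 0:(n_cls - 1L)
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    earliest <- min(first[top])
    top <- top[first[top] == earliest]  # all Inf when nothing fired
  }
  label <- min(top) - 1L
  structure(list(label = label, votes = votes,
                 first_spike = ifelse(is.finite(first), first, NA_real_),
                 no_spike = all(votes == 0), per_cluster = counts),
            class = "snn_prediction")
}

#' @export
print.snn_prediction <- function(x, ...) {
  cat(sprintf("predicted label: %d%s\n", x$label,
              if (x$no_spike) " (no neuron fired; tie fallback)" else ""))
  cat("votes:", paste(names(x$votes), x$votes, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Evaluate classification accuracy
#'
#' Scores a trained ensemble on a labelled dataset by teacher-free
#' decoding. Accuracy is the exact fraction of correct predictions,
#' reported as a percentage rounded to two decimals.
#'
#' @param ens a trained `"snn_ensemble"`.
#' @param test an [snn_dataset()], or a list of
#'   `list(train = <spike_train>, label =)` pairs for pre-encoded data.
#' @param cfg configuration (LIF parameters); defaults to the ensemble's.
#' @return List with `accuracy` (percent, 2 dp), `correct`, `n` and the
#'   `confusion` table (true x predicted).
#' @export
evaluate_accuracy <- function(ens, test, cfg = NULL) {
  if (inherits(test, "snn_dataset")) {
    inputs <- test$images
    labels <- test$labels
  } else {
    if (length(test) == 0L) stop("empty test set", call. = FALSE)
    inputs <- lapply(test, `[[`, "train")
    labels <- vapply(test, `[[`, numeric(1), "label")
  }
  if (length(inputs) == 0L) stop("empty test set", call. = FALSE)
  preds <- vapply(inputs, function(x) decode(ens, x, cfg)$label, integer(1))
  correct <- sum(preds == labels)
  n <- length(labels)
  lv <- 0:(ens$n_classes - 1L)
  list(accuracy = round(100 * correct / n, 2), correct = correct, n = n,
       confusion = table(true = factor(labels, lv),
                         predicted = factor(preds, lv)))
}
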