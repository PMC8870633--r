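#' Fit a cluster-grouped spiking neural network
#'
#' The main modelling entry point. Encodes the training images as latency
#' spike trains, builds `clusters` homogeneous LIF clusters, trains each on
#' its own bootstrap subset with the bipolar supervised STDP rule, and
#' optionally applies structural learning (weight-change pruning). Returns
#' a fitted ensemble with the usual modelling methods ([print][print.snn_ensemble],
#' [summary][summary.snn_ensemble], [coef][coef.snn_ensemble],
#' [predict][predict.snn_ensemble], [plot][plot.snn_ensemble]).
#'
#' @param data an [snn_dataset()] of labelled 28x28 images (from
#'   [synth_digits()] or [read_idx()]).
#' @param config a full [snn_config()]; individual training arguments below
#'   override its `train` section.
#' @param clusters number of clusters `T` (default 15).
#' @param subset_size bootstrap samples per cluster (default 1000).
#' @param iterations training passes per cluster (default 3).
#' @param seed global seed.
#' @param prune_threshold optional structural-learning threshold; `NULL`
#'   disables pruning.
#' @return A trained object of class `"snn_ensemble"`.
#' @examples
#' \donttest{
#' train <- synth_digits(n_per_class = 20, seed = 1)
#' fit <- snn_fit(train, clusters = 2, subset_size = 30, iterations = 1)
#' predict(fit, synth_digits(n_per_class = 2, seed = 2))
#' }
#' @export
snn_fit <- function(data, config = snn_config(), clusters = NULL,
                    subset_size = NULL, iterations = NULL, seed = NULL,
                    prune_threshold = NULL) {
  over <- list(clusters = clusters, subset_size = subset_size,
               iterations = iterations, seed = seed,
               prune_threshold = prune_threshold)
  over <- over[!vapply(over, is.null, logical(1))]
  ints <- intersect(names(over),
                    c("clusters", "subset_size", "iterations", "seed"))
  over[ints] <- lapply(over[ints], as.integer)
  if (length(over)) config$train <- merge_config(config$train, over,
                                                 path = "train.")
  validate_config(config)
  ens <- train_ensemble(data, config)
  ens$call <- match.call()
  ens
}

#' @export
print.snn_ensemble <- function(x, ...) {
  counts <- count_synapses(x)
  cat("Cluster-grouped spiking neural network",
      if (isTRUE(x$trained)) "(trained)" else "(untrained)", "\n")
  cat(sprintf("  clusters: %d, each %d input channels + %d decode neurons (%d neurons/cluster)\n",
              length(x$clusters), x$clusters[[1]]$n_inputs, x$n_classes,
              x$clusters[[1]]$n_inputs + x$n_classes))
  cat(sprintf("  synapses: %d alive of %d (%.2f%%)\n",
              counts$alive, counts$total, 100 * counts$proportion))
  if (!is.null(x$encoder))
    cat(sprintf("  encoder: %dx%d kernels, %dx%d pooling, %s coding, %g ms window\n",
                x$encoder$kernel_size, x$encoder$kernel_size,
                x$encoder$pool_size, x$encoder$pool_size,
                x$encoder$method, x$encoder$window_ms))
  invisible(x)
}

#' @export
summary.snn_ensemble <- function(object, ...) {
  counts <- count_synapses(object)
  conv <- if (!is.null(object$outcomes)) {
    vapply(object$outcomes, function(oc)
      mean(vapply(oc, `[[`, logical(1), "converged")), numeric(1))
  } else NULL
  wchange <- vapply(object$clusters, function(cl)
    mean(abs(cl$W - cl$W_init)), numeric(1))
  out <- list(clusters = length(object$clusters),
              n_inputs = object$clusters[[1]]$n_inputs,
              n_classes = object$n_classes,
              synapses = counts,
              convergence_rate = conv,
              mean_weight_change = wchange,
              trained = isTRUE(object$trained))
  class(out) <- "summary.snn_ensemble"
  out
}

#' @export
print.summary.snn_ensemble <- function(x, ...) {
  cat(sprintf("snn ensemble: %d clusters x (%d -> %d), %s\n",
              x$clusters, x$n_inputs, x$n_classes,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("synapses alive: %d / %d (%.2f%%)\n", x$synapses$alive,
              x$synapses$total, 100 * x$synapses$proportion))
  if (!is.null(x$convergence_rate))
    cat("per-cluster sample convergence (last pass):",
        paste(sprintf("%.0f%%", 100 * x$convergence_rate), collapse = " "),
        "\n")
  cat("mean |weight change| per cluster:",
      paste(sprintf("%.2f", x$mean_weight_change), collapse = " "), "\n")
  invisible(x)
}

#' Extract synaptic weight matrices
#'
#' @param object a fitted `"snn_ensemble"`.
#' @param masked if `TRUE` (default) dead synapses are reported as 0.
#' @param ... unused.
#' @return List of `n_inputs x n_classes` weight matrices, one per cluster.
#' @export
coef.snn_ensemble <- function(object, masked = TRUE, ...) {
  lapply(object$clusters, function(cl) if (masked) cl$W * cl$alive else cl$W)
}

#' Predict class labels for new images
#'
#' @param object a trained `"snn_ensemble"`.
#' @param newdata an [snn_dataset()], a single image matrix, or a
#'   [spike_train()].
#' @param type `"class"` for an integer label vector, `"votes"` for the
#'   per-class spike-count matrix, `"prediction"` for the full
#'   `"snn_prediction"` objects.
#' @param ... unused.
#' @return Per `type`; labels are integers in `0:9`.
#' @export
predict.snn_ensemble <- function(object, newdata,
                                 type = c("class", "votes", "prediction"),
                                 ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained))
    warning("predicting from an untrained ensemble")
  inputs <- if (inherits(newdata, "snn_dataset")) newdata$images
            else if (is.matrix(newdata) || inherits(newdata, "spike_train"))
              list(newdata)
            else newdata
  preds <- lapply(inputs, function(x) decode(object, x))
  switch(type,
         class = vapply(preds, `[[`, integer(1), "label"),
         votes = do.call(rbind, lapply(preds, `[[`, "votes")),
         prediction = preds)
}

#' Plot a fitted spiking ensemble
#'
#' Two base-graphics panels: the distribution of absolute weight changes
#' (|W - W_init|) across all live synapses — the quantity structural
#' learning thresholds — and the per-cluster percentage of live synapses.
#'
#' @param x a fitted `"snn_ensemble"`.
#' @param ... passed to [hist()].
#' @return `x`, invisibly.
#' @export
plot.snn_ensemble <- function(x, ...) {
  old <- par(mfrow = c(1, 2))
  on.exit(par(old))
  dw <- unlist(lapply(x$clusters, function(cl) abs(cl$W - cl$W_init)[cl$alive]))
  hist(dw, main = "Weight change |W - W_init|", xlab = "weight units", ...)
  alive_pct <- vapply(x$clusters, function(cl)
    100 * sum(cl$alive) / length(cl$alive), numeric(1))
  barplot(alive_pct, names.arg = seq_along(alive_pct),
          main = "Live synapses per cluster", xlab = "cluster",
          ylab = "% alive", ylim = c(0, 100))
  invisible(x)
}
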