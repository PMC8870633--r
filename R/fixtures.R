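#' Class-disjoint separable spike-train fixture
#'
#' Constructs a labelled set of spike trains in which each class occupies
#' its own disjoint block of input channels, so classes are perfectly
#' separable by construction. Spike times fall in a mid-window band (by
#' default 40–65 ms) where the causal STDP window of a 70 ms encouraging
#' teacher gives appreciable potentiation. This is the canonical
#' test bed for the learning rule: a correctly implemented bipolar
#' supervised learner must reach 100% teacher-free training accuracy on it.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes.
#' @param n_channels total channel count (default 576, the default encoder
#'   geometry).
#' @param block_size active channels per class (must satisfy
#'   `block_size <= n_channels / n_classes`).
#' @param active_frac fraction of the class block active in each sample.
#' @param time_range spike-time band in ms.
#' @param window_ms simulation window.
#' @param seed RNG seed.
#' @return List of `list(train = <spike_train>, label = <0-based class>)`.
#' @examples
#' fx <- separable_spike_set(n_per_class = 1, n_classes = 2)
#' fx[[1]]$label
#' @export
separable_spike_set <- function(n_per_class = 3, n_classes = 10,
                                n_channels = 576, block_size = 40,
                                active_frac = 0.8,
                                time_range = c(40, 65), window_ms = 100,
                                seed = 1) {
  stride <- n_channels %/% n_classes
  stopifnot(block_size <= stride, active_frac > 0, active_frac <= 1,
            time_range[1] >= 0, time_range[2] < window_ms)
  n_active <- max(1L, round(block_size * active_frac))
  with_seed(seed, {
    out <- list()
    for (cls in 0:(n_classes - 1L)) {
      block <- cls * stride + seq_len(block_size)
      for (s in seq_len(n_per_class)) {
        ch <- sort(sample(block, n_active))
        tm <- runif(n_active, time_range[1], time_range[2])
        out[[length(out) + 1L]] <-
          list(train = spike_train(ch, tm, n_channels, window_ms),
               label = cls)
      }
    }
    out
  })
}
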