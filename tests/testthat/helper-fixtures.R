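# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so individual files stay fast.

# Wrap a single cluster as a minimal ensemble so decode()/evaluate() work
# on hand-built clusters.
wrap_ensemble <- function(..., encoder = snn_config()$encoder) {
  clusters <- list(...)
  structure(list(clusters = clusters, encoder = encoder,
                 n_classes = clusters[[1]]$n_decode, seed = 0L,
                 trained = TRUE, outcomes = NULL, config = NULL),
            class = "snn_ensemble")
}

# A cluster with all-zero weights (silent unless taught).
zero_cluster <- function(n_inputs = 20, n_decode = 10) {
  net <- new_cluster(n_inputs, n_decode, seed = 1)
  net$W[] <- 0
  net$W_init[] <- 0
  net
}

# Nested-loop reference for valid cross-correlation.
convolve_oracle <- function(image, kernel) {
  n <- nrow(image); k <- nrow(kernel)
  out <- matrix(0, n - k + 1, ncol(image) - ncol(kernel) + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      acc <- 0
      for (a in seq_len(k)) for (b in seq_len(ncol(kernel)))
        acc <- acc + image[i + a - 1, j + b - 1] * kernel[a, b]
      out[i, j] <- acc
    }
  }
  out
}

# Exhaustive per-window maximum reference for pooling.
maxpool_oracle <- function(map, pool) {
  nr <- nrow(map) %/% pool; nc <- ncol(map) %/% pool
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- max(map[(i - 1) * pool + seq_len(pool),
                         (j - 1) * pool + seq_len(pool)])
  out
}

# Explicit all-pairs STDP reference.
stdp_oracle <- function(pre, post, p) {
  acc <- 0
  for (tp in pre) for (to in post) {
    acc <- acc + if (tp < to) p$a_plus * exp(-(to - tp) / p$tau_plus)
                 else -p$a_minus * exp(-(tp - to) / p$tau_minus)
  }
  acc
}
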