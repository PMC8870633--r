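#' Default run configuration
#'
#' Returns the full nested configuration used throughout the package, with
#' any supplied overrides merged in. Every tunable of the pipeline lives
#' here so that a single object documents a run completely.
#'
#' Sections and defaults:
#' \describe{
#'   \item{encoder}{`kernel_size = 4`, `pool_size = 2`, `method = "linear"`,
#'     `window_ms = 100`, `contrast_cut = 0.2` (feature values below this
#'     fraction of the per-image maximum emit no spike — see
#'     [encode_features()]). The 4x4 kernel / 2x2 pool combination gives
#'     4 * 12^2 = 576 input channels per cluster. The simulation window must
#'     extend past the latest teacher signal.}
#'   \item{lif}{`tau_m = 10` ms membrane time constant, `v_rest = -65` mV,
#'     `v_thresh = -50` mV, `v_reset = -70` mV, `t_ref = 2` ms refractory
#'     period, `psc_tau = 2` ms synaptic current decay, `dt = 0.1` ms
#'     integration step.}
#'   \item{stdp}{`a_plus = 0.5`, `a_minus = 0.25` pair amplitudes,
#'     `tau_plus = tau_minus = 20` ms, weight bounds `w_min = 0`,
#'     `w_max = 50`, `punish_scale = 1` (multiplier on the anti-STDP
#'     depression under a punishing teacher), `w_init_max = 5` (initial
#'     weights are uniform on \[0, w_init_max\]).}
#'   \item{teacher}{`encourage_ms = 70`, `punish_ms = 35` injection times,
#'     `magnitude = 3000` current units (suprathreshold in one step).}
#'   \item{train}{`clusters = 15`, `subset_size = 1000` bootstrap samples
#'     per cluster, `iterations = 3` passes per cluster, `max_inner_iters =
#'     50` teacher rounds per sample, `seed = 1`, `prune_threshold = NULL`
#'     (no structural learning unless set).}
#' }
#'
#' @param ... named nested lists overriding sections, e.g.
#'   `snn_config(encoder = list(method = "power"), train = list(clusters = 3))`.
#'   Unknown section or key names are an error.
#' @return A nested list of class `"snn_config"`.
#' @examples
#' cfg <- snn_config(train = list(clusters = 3, subset_size = 50))
#' cfg$train$clusters
#' @export
snn_config <- function(...) {
  defaults <- list(
    encoder = list(kernel_size = 4L, pool_size = 2L, method = "linear",
                   window_ms = 100, contrast_cut = 0.2),
    lif = list(tau_m = 10, v_rest = -65, v_thresh = -50, v_reset = -70,
               t_ref = 2, psc_tau = 2, dt = 0.1),
    stdp = list(a_plus = 0.5, a_minus = 0.25, tau_plus = 20, tau_minus = 20,
                w_min = 0, w_max = 50, punish_scale = 1, w_init_max = 5),
    teacher = list(encourage_ms = 70, punish_ms = 35, magnitude = 3000),
    train = list(clusters = 15L, subset_size = 1000L, iterations = 3L,
                 max_inner_iters = 50L, seed = 1L, prune_threshold = NULL)
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  validate_config(cfg)
  class(cfg) <- "snn_config"
  cfg
}

# Recursive merge of `over` into `base`, rejecting keys absent from `base`
# (with a nearest-name hint). NULL defaults (train.prune_threshold) are
# representable, so key membership is checked by name, not by value.
merge_config <- function(base, over, path = "") {
  if (length(over) == 0L) return(base)
  nms <- names(over)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  valid <- names(base)
  for (key in nms) {
    if (!key %in% valid) {
      hint <- valid[which.min(utils::adist(key, valid))]
      stop(sprintf("unknown configuration key '%s%s'; did you mean '%s%s'?",
                   path, key, path, hint), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(over[[key]]))
        stop(sprintf("configuration section '%s%s' must be a list", path, key),
             call. = FALSE)
      base[[key]] <- merge_config(base[[key]], over[[key]],
                                  path = paste0(path, key, "."))
    } else {
      base[key] <- over[key]  # [<- keeps explicit NULL assignments
    }
  }
  base
}

validate_config <- function(cfg) {
  enc <- cfg$encoder
  stopifnot(enc$kernel_size %in% 3:5, enc$pool_size %in% 2:4,
            enc$window_ms > 0)
  if (!enc$method %in% names(delay_coders()))
    stop("unknown encoding method '", enc$method, "'", call. = FALSE)
  lif <- cfg$lif
  stopifnot(lif$tau_m > 0, lif$dt > 0, lif$psc_tau > 0, lif$t_ref >= 0,
            lif$v_reset <= lif$v_rest, lif$v_rest < lif$v_thresh)
  st <- cfg$stdp
  stopifnot(st$a_plus > 0, st$a_minus > 0, st$tau_plus > 0, st$tau_minus > 0,
            st$w_min < st$w_max, st$punish_scale >= 0, st$w_init_max > 0)
  te <- cfg$teacher
  stopifnot(te$encourage_ms >= 0, te$punish_ms >= 0, te$magnitude > 0)
  if (max(te$encourage_ms, te$punish_ms) >= enc$window_ms)
    stop("simulation window must extend past the latest teacher signal",
         call. = FALSE)
  tr <- cfg$train
  stopifnot(tr$clusters >= 1, tr$subset_size >= 1, tr$iterations >= 1,
            tr$max_inner_iters >= 1)
  if (!is.null(tr$prune_threshold)) stopifnot(tr$prune_threshold >= 0)
  invisible(cfg)
}

#' Load a run configuration from a YAML or JSON file
#'
#' Reads the file and merges it over the documented defaults of
#' [snn_config()]. Unknown keys are rejected with a nearest-key hint, so a
#' misspelled override fails loudly rather than being silently ignored. An
#' empty file yields the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file of (possibly
#'   partial) configuration sections.
#' @return A `"snn_config"` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("teacher:\n  encourage_ms: 80", f)
#' load_config(f)$teacher$encourage_ms
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(over)) over <- list()
  do.call(snn_config, over)
}

#' @export
print.snn_config <- function(x, ...) {
  cat("snnclust run configuration\n")
  for (sec in names(x)) {
    vals <- vapply(x[[sec]], function(v)
      if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
      character(1))
    cat(sprintf("  %-8s %s\n", sec,
                paste(names(vals), vals, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

# Evaluate f with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seeds so per-cluster RNG streams do not depend on
# execution order.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
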