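# Stochastic generator of network specifications: a Markov chain over layer
# types plus clipped, rounded normal priors on layer hyperparameters.  Used to
# produce the corpus that trains the genotype codec and the pool of candidate
# ancestors.

#' Layer-type transition model (Markov chain)
#'
#' States are the hidden-layer types plus a terminal state `end`.  A chain is
#' drawn by sampling the first layer from `initial` and then following
#' `transition` until `end` is reached.
#'
#' Only the convolutional row's probabilities are fixed by convention
#' (conv -> pool 0.7, conv -> conv 0.2, conv -> dense 0.1); every other row,
#' and the initial distribution, is shipped configuration.
#'
#' @param transition numeric matrix, rows = c("conv","pool","dense"), columns
#'   = c("conv","pool","dense","end"); each row sums to 1.
#' @param initial numeric vector over c("conv","pool","dense") summing to 1.
#' @return object of class `serann_transition_model`.
#' @export
transition_model <- function(transition = default_transition_matrix(),
                             initial = c(conv = 0.6, pool = 0.1, dense = 0.3)) {
  states <- c("conv", "pool", "dense")
  stopifnot(is.matrix(transition),
            identical(rownames(transition), states),
            identical(colnames(transition), c(states, "end")))
  if (any(transition < 0) || any(initial < 0))
    stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("every transition row must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9)
    stop("the initial distribution must sum to 1")
  # terminal state must be reachable from every state (graph closure)
  reach <- transition[, "end"] > 0
  for (i in 1:3) {
    reach <- reach | (transition[, states, drop = FALSE] %*% reach > 0)[, 1]
  }
  if (!all(reach)) stop("terminal state unreachable from some layer state")
  structure(list(states = states, transition = transition, initial = initial),
            class = "serann_transition_model")
}

#' @rdname transition_model
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    conv  = c(0.20, 0.70, 0.10, 0.00),
    pool  = c(0.35, 0.00, 0.45, 0.20),
    dense = c(0.00, 0.00, 0.55, 0.45)
  )
  colnames(m) <- c("conv", "pool", "dense", "end")
  m
}

#' Clipped, rounded normal prior on a layer hyperparameter
#'
#' @param mean,sd normal location and scale (sd > 0).
#' @param lo,hi clip bounds, `lo <= mean <= hi`.
#' @param digits rounding grid: 0 rounds to integers (half away from zero),
#'   4 rounds to the 1e-4 grid used for the loss weight.
#' @return object of class `serann_prior`.
#' @export
hyperparam_prior <- function(mean, sd, lo, hi, digits = 0L) {
  stopifnot(sd > 0, lo <= mean, mean <= hi)
  structure(list(mean = mean, sd = sd, lo = lo, hi = hi, digits = digits),
            class = "serann_prior")
}

#' Default hyperparameter priors
#'
#' Fully-connected width ~ N(64, 15) clipped to `[8, 128]`; convolutional
#' filter count and the loss weight alpha are shipped configuration.
#'
#' @return named list of `serann_prior` objects
#'   (`dense_units`, `conv_filters`, `alpha`).
#' @export
default_priors <- function() {
  list(
    dense_units  = hyperparam_prior(64, 15, 8, 128),
    conv_filters = hyperparam_prior(12, 4, 4, 24),
    alpha        = hyperparam_prior(0.10, 0.02, 0.05, 0.15, digits = 4L)
  )
}

#' Draw one value from a clipped, rounded normal prior
#'
#' @param prior a [hyperparam_prior()].
#' @return a scalar inside `[lo, hi]`, integral on the prior's rounding grid.
#' @export
sample_hyperparameter <- function(prior) {
  x <- clamp(stats::rnorm(1L, prior$mean, prior$sd), prior$lo, prior$hi)
  scale <- 10^prior$digits
  x <- round_half_away(x * scale) / scale
  clamp(x, prior$lo, prior$hi)
}

#' Draw a hidden-layer type chain from the transition model
#'
#' The raw Markov chain, before any validity or budget filtering; exposed so
#' the chain-length distribution can be compared against direct path
#' enumeration.
#'
#' @param model a [transition_model()].
#' @param max_len hard stop on the chain length (a practical guard; the
#'   default far exceeds typical absorption times).
#' @return character vector of layer types (possibly length 0 is impossible:
#'   the first layer is always drawn from `initial`).
#' @export
sample_layer_chain <- function(model, max_len = 64L) {
  states <- model$states
  chain <- sample(states, 1L, prob = model$initial)
  repeat {
    if (length(chain) >= max_len) break
    nxt <- sample(c(states, "end"), 1L,
                  prob = model$transition[chain[length(chain)], ])
    if (nxt == "end") break
    chain <- c(chain, nxt)
  }
  chain
}

#' Sample one valid network specification
#'
#' Draws a hidden-layer chain from the Markov chain, attaches hyperparameters
#' from the priors and the scaffold markers, and accepts the spec only if it
#' tokenizes within the token budget and builds successfully.  Rejected draws
#' are resampled up to `retry` times.
#'
#' @param model a [transition_model()].
#' @param priors named list as in [default_priors()].
#' @param scaffold a [default_scaffold()].
#' @param vocab a [serann_vocab()].
#' @param d token budget for [tokenize()].
#' @param token_cap maximum content length (defaults to the conventional 350).
#' @param retry resample budget for invalid or over-budget chains.
#' @return a `serann_netspec` that passes [build_network()].
#' @export
sample_architecture <- function(model = transition_model(),
                                priors = default_priors(),
                                scaffold = default_scaffold(),
                                vocab = default_vocab(),
                                d = 352L, token_cap = 350L, retry = 100L) {
  for (attempt in seq_len(retry)) {
    chain <- sample_layer_chain(model)
    layers <- lapply(chain, function(type) {
      switch(type,
        conv  = list(type = "conv",
                     filters = sample_hyperparameter(priors$conv_filters)),
        pool  = list(type = "pool"),
        dense = list(type = "dense",
                     units = sample_hyperparameter(priors$dense_units))
      )
    })
    spec <- structure(
      list(layers = layers, alpha = sample_hyperparameter(priors$alpha)),
      class = "serann_netspec")
    spec$text <- format_netspec(spec)
    toks <- tryCatch(tokenize(spec$text, vocab, d), error = function(e) NULL)
    if (is.null(toks) || toks$content_length > token_cap) next
    if (!build_network(spec, scaffold)$valid) next
    return(spec)
  }
  stop("sample_architecture: retry budget exhausted (", retry, " attempts)",
       call. = FALSE)
}

#' Generate a corpus of specification strings
#'
#' @param n number of specifications (>= 1).
#' @param seed optional integer seed; a fixed seed makes the corpus
#'   byte-reproducible.
#' @inheritParams sample_architecture
#' @return character vector of length `n`; every element parses and builds.
#' @export
generate_corpus <- function(n, model = transition_model(),
                            priors = default_priors(),
                            scaffold = default_scaffold(),
                            vocab = default_vocab(),
                            d = 352L, token_cap = 350L, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    sample_architecture(model, priors, scaffold, vocab, d, token_cap)$text
  }, character(1))
}

#' Write / read a line-delimited specification archive
#'
#' One specification per line, UTF-8 text.
#'
#' @param specs character vector of specification strings.
#' @param path file path.
#' @export
write_spec_archive <- function(specs, path) {
  writeLines(specs, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_spec_archive
#' @export
read_spec_archive <- function(path) readLines(path)
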