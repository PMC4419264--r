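# Synthetic session generator with known ground truth.
#
# Emulates the structure of the precomputed competition sessions: a
# 4-minute recording of 15 s task blocks at 16 feature vectors per
# second, 96 strictly positive band-power features, three task codes.
# Band powers are lognormal (heavy-tailed, positive — a reasonable
# surrogate for Welch band-power marginals); class information enters a
# small designated feature subset as class-specific multiplicative mean
# shifts, mimicking ERD/ERS-style power modulation. Everything else is
# class-independent noise.

#' Specification for a synthetic session set
#'
#' @param n_classes Number of task classes (default 3).
#' @param n_features Feature arity (default 96).
#' @param informative Integer indices of class-discriminant features.
#' @param effect_size Separation between adjacent class means of an
#'   informative feature, in within-class (log-domain) SD units.
#' @param block_seconds Task-block length in seconds (default 15).
#' @param vectors_per_second Cadence (default 16).
#' @param session_minutes Session length in minutes (default 4).
#' @param sigma_log Within-class SD of log band power (default 0.4).
#' @param labels Task codes to use (default `c(2, 3, 7)`, the
#'   competition scheme: 2 = LEFT, 3 = RIGHT, 7 = WORD).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, n_features = 96L,
                           informative = integer(0), effect_size = 2,
                           block_seconds = 15L, vectors_per_second = 16L,
                           session_minutes = 4, sigma_log = 0.4,
                           labels = c(2L, 3L, 7L), seed = 1L) {
  informative <- as.integer(informative)
  if (length(informative) &&
      (any(informative < 1L) || any(informative > n_features)))
    stop("informative indices must lie in 1..n_features")
  if (effect_size < 0) stop("effect_size must be >= 0")
  stopifnot(n_classes >= 2, n_features >= 1, block_seconds >= 1,
            vectors_per_second >= 1, session_minutes > 0, sigma_log > 0,
            length(labels) == n_classes)
  structure(list(n_classes = as.integer(n_classes),
                 n_features = as.integer(n_features),
                 informative = informative,
                 effect_size = effect_size,
                 block_seconds = as.integer(block_seconds),
                 vectors_per_second = as.integer(vectors_per_second),
                 session_minutes = session_minutes,
                 sigma_log = sigma_log,
                 labels = as.integer(labels),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ground-truth informative feature set of a spec
#'
#' @param spec A [synthetic_spec()].
#' @return Integer vector of informative feature indices.
#' @export
known_answer <- function(spec) spec$informative

#' Generate synthetic labeled feature sessions
#'
#' Each session is a sequence of `block_seconds`-long constant-label
#' blocks (240 vectors per block at the defaults); the class order of
#' the blocks is a seeded random permutation repeated cyclically, so
#' class priors are balanced within every block cycle. Features are
#' lognormal; each informative feature is modulated by exactly one
#' designated class (a log-mean offset of `effect_size * sigma_log`
#' for that class, baseline for the rest), mirroring task-specific
#' ERD/ERS power modulation; the designated class rotates across the
#' informative features so every class is covered when there are at
#' least `n_classes` of them.
#'
#' @param spec A [synthetic_spec()].
#' @param n_sessions Number of sessions to generate (default 4: three
#'   learning sessions plus one test session).
#' @return List of [feature_session()]s with ids `"synth1"`, ...
#' @export
generate_sessions <- function(spec, n_sessions = 4L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_sessions >= 1)
  C <- spec$n_classes
  m <- spec$n_features
  blk <- spec$block_seconds * spec$vectors_per_second
  n_blocks <- max(1L, floor(spec$session_minutes * 60 / spec$block_seconds))
  # per-feature baseline log-mean, shared across classes and sessions
  set.seed(spec$seed)
  base_mu <- rnorm(m, mean = 0, sd = 0.2)
  delta <- matrix(0, C, m)
  for (k in seq_along(spec$informative)) {
    j <- spec$informative[k]
    ck <- (k - 1L) %% C + 1L  # designated class rotates across features
    delta[ck, j] <- spec$effect_size * spec$sigma_log
  }
  lapply(seq_len(n_sessions), function(s) {
    set.seed(spec$seed + 1000L * s)
    order_cycle <- unlist(lapply(seq_len(ceiling(n_blocks / C)),
                                 function(i) sample.int(C)))
    block_classes <- order_cycle[seq_len(n_blocks)]
    y <- rep(spec$labels[block_classes], each = blk)
    n <- length(y)
    cls <- rep(block_classes, each = blk)
    mu <- matrix(base_mu, n, m, byrow = TRUE) + delta[cls, , drop = FALSE]
    X <- exp(mu + matrix(rnorm(n * m, sd = spec$sigma_log), n, m))
    feature_session(X, y, spec$vectors_per_second,
                    session_id = paste0("synth", s))
  })
}
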