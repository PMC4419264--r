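# Supervised fuzzy-rule classifier.
#
# A deliberately static stand-in for the dynamic fuzzy-ART family: rules
# are per-feature trapezoids (a core interval with full membership and a
# linear decay of width gamma_f outside it, in normalized units) combined
# by min-conjunction; learning is a single sequential pass in which each
# sample either expands the best-matching same-class rule that passes the
# vigilance test or seeds a new point-core rule. The criterion layer
# (per-class fuzzy sets compared pairwise) is unaffected by this
# simplification; the classifier itself makes no claim to reproduce the
# differential activation dynamics of the original architecture.

.norm_from_session <- function(features) {
  list(min = apply(features, 2, min), max = apply(features, 2, max))
}

.norm_apply <- function(x, norm) {
  rng <- norm$max - norm$min
  const <- rng <= 0
  rng[const] <- 1
  z <- sweep(sweep(x, 2, norm$min, "-"), 2, rng, "/")
  z[z < 0] <- 0
  z[z > 1] <- 1
  if (any(const)) z[, const] <- 0.5  # constant feature: uninformative midpoint
  z
}

#' Fit a fuzzy-rule model by one-pass sequential learning
#'
#' Features are min/max normalized to `[0, 1]` from the learning session.
#' Each sample in presentation order either expands the core of the
#' best-matching rule of its own class whose conjunctive activation is at
#' least the vigilance `rho_v`, or creates a new rule with a point core
#' at the sample. Learning is fully deterministic given the session
#' order and parameters.
#'
#' @param session A [feature_session()] with at least one sample per class.
#' @param rho_v Vigilance in `[0, 1]`: how closely a sample must match a
#'   rule before the rule may absorb it. `rho_v = 1` yields one rule per
#'   distinct training sample.
#' @param gamma_f Fuzziness width: linear decay distance (in normalized
#'   feature units) from the core edge to zero membership.
#' @param seed Unused (learning has no random component); accepted for
#'   interface uniformity.
#' @return An object of class `fuzzy_model`.
#' @export
fit_fuzzy_model <- function(session, rho_v = 0.75, gamma_f = 0.1,
                            seed = NULL) {
  stopifnot(rho_v >= 0, rho_v <= 1, gamma_f >= 0)
  labs <- session$label_set
  if (any(tabulate(match(session$labels, labs), length(labs)) == 0))
    stop("every class must have at least one sample")
  norm <- .norm_from_session(session$features)
  Z <- .norm_apply(session$features, norm)
  y0 <- match(session$labels, labs) - 1L
  fit <- cpp_fit_rules(Z, y0, rho_v, gamma_f)
  structure(list(core_lo = fit$core_lo,
                 core_hi = fit$core_hi,
                 rule_class = fit$class + 1L,   # index into label_set
                 label_set = labs,
                 rho_v = rho_v, gamma_f = gamma_f,
                 norm = norm,
                 success = rep(0L, nrow(fit$core_lo)),
                 error = rep(0L, nrow(fit$core_lo)),
                 provenance = list(learn = session$session_id,
                                   prune = NULL)),
            class = "fuzzy_model")
}

#' @export
print.fuzzy_model <- function(x, ...) {
  cat(sprintf("<fuzzy_model: %d rules over %d features, %d classes, rho_v=%g, gamma_f=%g>\n",
              nrow(x$core_lo), ncol(x$core_lo), length(x$label_set),
              x$rho_v, x$gamma_f))
  invisible(x)
}

# Winner rule index for a matrix of raw samples. cpp_winners applies
# the same max-activation / lowest-index rule as a max.col scan over
# cpp_activations, without materializing the n x R activation matrix.
.model_winners <- function(model, X) {
  Z <- .norm_apply(X, model$norm)
  list(winner = cpp_winners(Z, model$core_lo, model$core_hi, model$gamma_f))
}

#' Predict the class of a single feature vector
#'
#' The winning rule is the one with maximal conjunctive (min over
#' per-feature memberships) activation; ties break toward the lowest
#' rule index.
#'
#' @param model A [fit_fuzzy_model()] result.
#' @param x Numeric feature vector of the model's arity.
#' @return The predicted class label.
#' @export
predict_sample <- function(model, x) {
  if (length(x) != ncol(model$core_lo))
    stop("feature arity mismatch: expected ", ncol(model$core_lo),
         ", got ", length(x))
  w <- .model_winners(model, matrix(x, nrow = 1))
  model$label_set[model$rule_class[w$winner]]
}

#' Predict classes for every row of a session
#'
#' @param model A `fuzzy_model`.
#' @param session A [feature_session()] (labels ignored).
#' @return Integer vector of predicted labels, one per window.
#' @export
predict_session <- function(model, session) {
  if (ncol(session$features) != ncol(model$core_lo))
    stop("feature arity mismatch")
  w <- .model_winners(model, session$features)
  model$label_set[model$rule_class[w$winner]]
}

#' Prune rules with more errors than successes
#'
#' Every sample of the prune session is classified by its winning rule;
#' that rule's success counter (correct class) or error counter (wrong
#' class) is incremented. Rules that lose are untouched. Afterwards each
#' rule with strictly more errors than successes is discarded. If that
#' would leave a class with no rules, the best-performing rule of the
#' class (largest success - error, ties to the lowest index) is retained
#' so the model can still represent every class.
#'
#' @param model A fitted `fuzzy_model`.
#' @param session Labeled [feature_session()]; an empty session leaves
#'   the model unchanged.
#' @return The pruned `fuzzy_model` with updated counters and provenance.
#' @export
prune_rules <- function(model, session) {
  if (nrow(session$features) == 0) return(model)
  if (ncol(session$features) != ncol(model$core_lo))
    stop("feature arity mismatch")
  w <- .model_winners(model, session$features)
  pred_ok <- model$label_set[model$rule_class[w$winner]] == session$labels
  nr <- nrow(model$core_lo)
  succ <- model$success + tabulate(w$winner[pred_ok], nr)
  err <- model$error + tabulate(w$winner[!pred_ok], nr)
  keep <- err <= succ
  # guard: never empty a class
  for (ci in unique(model$rule_class)) {
    in_class <- model$rule_class == ci
    if (!any(keep & in_class)) {
      perf <- ifelse(in_class, succ - err, -Inf)
      keep[which.max(perf)] <- TRUE
    }
  }
  model$core_lo <- model$core_lo[keep, , drop = FALSE]
  model$core_hi <- model$core_hi[keep, , drop = FALSE]
  model$rule_class <- model$rule_class[keep]
  model$success <- succ[keep]
  model$error <- err[keep]
  model$provenance$prune <- session$session_id
  model
}

#' Build the six models from three learning sessions
#'
#' One model per ordered (learn, prune) pair of distinct sessions:
#' (1,2), (1,3), (2,1), (2,3), (3,1), (3,2). Each model's normalization
#' derives only from its learning session.
#'
#' @param sessions List of exactly 3 [feature_session()]s with distinct
#'   `session_id`s.
#' @param rho_v,gamma_f Classifier parameters, see [fit_fuzzy_model()].
#' @return List of 6 `fuzzy_model`s, named `"i.j"` by (learn, prune)
#'   session position.
#' @export
build_models <- function(sessions, rho_v = 0.75, gamma_f = 0.1) {
  if (length(sessions) != 3)
    stop("exactly 3 sessions are required, got ", length(sessions))
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate session ids: ",
                               paste(ids, collapse = ", "))
  pairs <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  models <- lapply(pairs, function(p) {
    m <- fit_fuzzy_model(sessions[[p[1]]], rho_v, gamma_f)
    prune_rules(m, sessions[[p[2]]])
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = ".")
  models
}

#' Majority vote over six models and one half-second window
#'
#' Each of the 6 models predicts each of the 8 consecutive feature
#' vectors of a 0.5 s decision window (at 16 vectors/s), yielding
#' 48 votes; the most frequent prediction wins. A tie goes to the
#' previous decision when available, otherwise to the lowest class
#' label.
#'
#' @param models List of 6 `fuzzy_model`s sharing a label set.
#' @param window Numeric matrix of 8 rows (feature vectors).
#' @param prev Previous decision label, or `NULL`.
#' @return The voted class label, with attribute `"votes"` (named counts
#'   over the 48 predictions).
#' @export
vote_predict <- function(models, window, prev = NULL) {
  if (length(models) != 6)
    stop("exactly 6 models are required, got ", length(models))
  window <- as.matrix(window)
  if (nrow(window) != 8)
    stop("a decision window must hold exactly 8 feature vectors, got ",
         nrow(window))
  votes <- unlist(lapply(models, function(m) {
    w <- .model_winners(m, window)
    m$label_set[m$rule_class[w$winner]]
  }), use.names = FALSE)
  labs <- sort(unique(unlist(lapply(models, `[[`, "label_set"))))
  counts <- vapply(labs, function(l) sum(votes == l), integer(1))
  names(counts) <- labs
  top <- labs[counts == max(counts)]
  decision <- if (length(top) == 1L) top
  else if (!is.null(prev)) prev
  else min(top)
  structure(decision, votes = counts)
}

#' Classify a session in half-second voted windows
#'
#' Splits the session into consecutive non-overlapping decision windows
#' of `vectors_per_second / 2` vectors, applies [vote_predict()] to each
#' (carrying the previous decision for tie-breaks), and scores against
#' the modal true label of each window.
#'
#' @param models List of 6 `fuzzy_model`s.
#' @param session Labeled [feature_session()].
#' @return List with `accuracy` (percent), `predicted` and `truth`
#'   (per-window labels).
#' @export
classify_session <- function(models, session) {
  wlen <- max(1L, session$vectors_per_second %/% 2L)
  n <- nrow(session$features)
  nwin <- n %/% wlen
  if (nwin == 0) stop("session shorter than one decision window")
  pred <- integer(nwin)
  truth <- integer(nwin)
  prev <- NULL
  for (k in seq_len(nwin)) {
    rows <- ((k - 1L) * wlen + 1L):(k * wlen)
    d <- vote_predict(models, session$features[rows, , drop = FALSE], prev)
    pred[k] <- as.integer(d)
    prev <- pred[k]
    tl <- session$labels[rows]
    tab <- table(tl)
    truth[k] <- as.integer(names(tab)[which.max(tab)])
  }
  list(accuracy = 100 * mean(pred == truth), predicted = pred, truth = truth)
}

#' Collapse a model to one prototype rule per class
#'
#' The "intermediate" model summarizes a rule set as exactly one
#' trapezoid per class, whose core endpoints are the feature-wise
#' arithmetic means of that class's rule cores. Its per-class,
#' per-feature fuzzy sets are what the fuzzy discriminant criterion
#' compares.
#'
#' @param model A `fuzzy_model` with at least one rule per class.
#' @return An object of class `intermediate_model` with fields
#'   `proto_lo`, `proto_hi` (class-by-feature matrices), `label_set`,
#'   `gamma_f`.
#' @export
intermediate_model <- function(model) {
  C <- length(model$label_set)
  m <- ncol(model$core_lo)
  proto_lo <- matrix(NA_real_, C, m)
  proto_hi <- matrix(NA_real_, C, m)
  for (ci in seq_len(C)) {
    rows <- model$rule_class == ci
    if (!any(rows))
      stop("class ", model$label_set[ci], " has no rules")
    proto_lo[ci, ] <- colMeans(model$core_lo[rows, , drop = FALSE])
    proto_hi[ci, ] <- colMeans(model$core_hi[rows, , drop = FALSE])
  }
  structure(list(proto_lo = proto_lo, proto_hi = proto_hi,
                 label_set = model$label_set, gamma_f = model$gamma_f),
            class = "intermediate_model")
}
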