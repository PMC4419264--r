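# Stage 2 (score, order, candidate selection) and stage 3 (prefix order
# selection; GMDH greedy forward selection under the regularity
# criterion), plus the cross-user unified model.

#' Score one criterion run
#'
#' Features are ranked most-discriminant-first according to the
#' criterion's direction (`"low"`: ascending values; `"high"`:
#' descending), ties broken by the lower feature index, unrankable
#' (flagged `NA`) features last. The ten best positions receive scores
#' 10, 9, ..., 1; all other features score 0, so a full run distributes
#' exactly 55 points.
#'
#' @param criterion A `criterion_vector` (from [product_criterion()],
#'   [entropy_criterion()] or [fuzzy_feature_scores()]).
#' @param top_k Number of scored positions (default 10).
#' @return Integer score vector, one entry per feature.
#' @export
score_run <- function(criterion, top_k = 10L) {
  v <- criterion$values
  key <- if (identical(criterion$direction, "high")) -v else v
  ord <- order(key, seq_along(key), na.last = TRUE)
  n_rankable <- sum(!is.na(v))
  k <- min(top_k, n_rankable)
  scores <- integer(length(v))
  if (k > 0) scores[ord[seq_len(k)]] <- seq(top_k, by = -1L, length.out = k)
  scores
}

#' Accumulate scores over runs
#'
#' Elementwise sum of per-run score vectors: three runs (one per
#' learning session) for the statistics route, six runs (one per
#' learn/prune permutation) for the fuzzy route.
#'
#' @param score_runs List of integer score vectors of equal length.
#' @return An object of class `score_table` with fields `scores` and
#'   `runs`.
#' @export
accumulate_scores <- function(score_runs) {
  stopifnot(length(score_runs) >= 1)
  lens <- lengths(score_runs)
  if (length(unique(lens)) != 1) stop("score runs differ in feature arity")
  structure(list(scores = Reduce(`+`, score_runs),
                 runs = length(score_runs)),
            class = "score_table")
}

#' Select candidate features by cumulative score fraction
#'
#' Features are sorted by descending accumulated score (ties to the
#' lower index); `K` is the smallest `k` whose cumulative score fraction
#' strictly exceeds `rho`. The default `rho = 0.85` discards the long
#' tail of features with minimal scores.
#'
#' @param tbl A [accumulate_scores()] table.
#' @param rho Cumulative-score threshold, a fraction in `(0, 1)`.
#' @return List with `K` and `candidates` (the first `K` features in
#'   score order).
#' @export
select_candidates <- function(tbl, rho = 0.85) {
  if (rho >= 1) stop("rho must be < 1")
  if (rho <= 0) stop("rho must be > 0")
  total <- sum(tbl$scores)
  if (total <= 0) stop("score table is empty")
  ord <- order(-tbl$scores, seq_along(tbl$scores))
  frac <- cumsum(tbl$scores[ord]) / total
  K <- which(frac > rho)[1]
  list(K = as.integer(K), candidates = as.integer(ord[seq_len(K)]))
}

#' Regularity criterion of a feature subset
#'
#' Mean voted test accuracy over the six ordered (learn, prune, test)
#' permutations of the three learning sessions: for each permutation
#' the classifier is fitted on the learn session restricted to the
#' subset, pruned on the prune session, and scored by half-second
#' majority voting on the test session. A single learn+prune model
#' votes alone in this protocol, so each 0.5 s window aggregates 8
#' votes; full six-model voting is used at final validation time via
#' [build_models()] and [classify_session()].
#'
#' @param features Nonempty integer vector of 1-based feature indices.
#' @param sessions List of 3 labeled [feature_session()]s.
#' @param rho_v,gamma_f Classifier parameters.
#' @return Percent success rate in `[0, 100]`, with attribute
#'   `"per_permutation"`.
#' @export
evaluate_subset <- function(features, sessions, rho_v = 0.75,
                            gamma_f = 0.1) {
  if (length(features) == 0) stop("empty feature subset")
  if (length(sessions) != 3) stop("exactly 3 sessions are required")
  sub <- lapply(sessions, subset_features, features = features)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  accs <- vapply(perms, function(p) {
    m <- fit_fuzzy_model(sub[[p[1]]], rho_v, gamma_f)
    m <- prune_rules(m, sub[[p[2]]])
    .vote_accuracy_single(m, sub[[p[3]]])
  }, numeric(1))
  names(accs) <- vapply(perms, paste, character(1), collapse = "")
  structure(mean(accs), per_permutation = accs)
}

# Half-second voted accuracy of a single model on one session: the 8
# per-vector predictions of each non-overlapping decision window are
# majority-voted (ties to previous decision, then lowest label).
.vote_accuracy_single <- function(model, session) {
  wlen <- max(1L, session$vectors_per_second %/% 2L)
  pred <- predict_session(model, session)
  nwin <- length(pred) %/% wlen
  if (nwin == 0) stop("session shorter than one decision window")
  used <- seq_len(nwin * wlen)
  labs <- model$label_set
  pm <- matrix(pred[used], nrow = wlen)
  counts <- vapply(labs, function(l) colSums(pm == l), numeric(nwin))
  counts <- matrix(counts, nrow = nwin)  # windows x labels
  # modal true label per window, ties to the lowest label
  tlabs <- session$label_set
  tm <- matrix(session$labels[used], nrow = wlen)
  tcounts <- matrix(vapply(tlabs, function(l) colSums(tm == l),
                           numeric(nwin)), nrow = nwin)
  truth <- tlabs[max.col(tcounts, ties.method = "first")]
  maxc <- counts[cbind(seq_len(nwin), max.col(counts, ties.method = "first"))]
  decision <- labs[max.col(counts, ties.method = "first")]  # = lowest on ties
  tied <- rowSums(counts == maxc) > 1L
  if (any(tied)) {
    prev <- NA_integer_
    for (k in seq_len(nwin)) {
      if (tied[k] && !is.na(prev)) decision[k] <- prev
      prev <- decision[k]
    }
  }
  100 * mean(decision == truth)
}

#' Prefix order selection
#'
#' Evaluates the score-ordered prefixes `(x1), (x1, x2), ...,
#' (x1..xK)` of the candidate list with an evaluation function and
#' returns the best-performing prefix (ties to the shorter one).
#'
#' @param candidates Ordered candidate features (from
#'   [select_candidates()]).
#' @param sessions List of 3 sessions, passed to `evaluator`.
#' @param rho_v,gamma_f Classifier parameters.
#' @param evaluator Function `(features, sessions, rho_v, gamma_f) ->
#'   percent`; defaults to [evaluate_subset()]. Overridable for testing.
#' @param scores Accumulated scores of the candidates (carried into the
#'   result for reporting).
#' @param rho Candidate threshold used (reporting only).
#' @return A [selection_result()] whose `trace` holds the accuracy of
#'   every prefix in order.
#' @export
order_selection <- function(candidates, sessions, rho_v = 0.75,
                            gamma_f = 0.1, evaluator = evaluate_subset,
                            scores = rep(NA_real_, length(candidates)),
                            rho = NA_real_) {
  stopifnot(length(candidates) >= 1)
  trace <- vapply(seq_along(candidates), function(k) {
    as.numeric(evaluator(candidates[seq_len(k)], sessions, rho_v, gamma_f))
  }, numeric(1))
  best <- which.max(trace)  # first maximum = shortest prefix on ties
  selection_result(method = "order",
                   candidates = candidates, scores = scores,
                   selected = candidates[seq_len(best)],
                   trace = trace, K = length(candidates), rho = rho)
}

#' GMDH greedy forward selection under the regularity criterion
#'
#' Starts from the best single-feature model, then repeatedly evaluates
#' every one-feature extension drawn from the remaining candidates and
#' accepts the best extension if and only if its criterion value
#' strictly exceeds the incumbent's; otherwise the search stops. The
#' accepted-step trace is strictly increasing by construction and an
#' accepted feature is never swapped out.
#'
#' @inheritParams order_selection
#' @return A [selection_result()] whose `trace` holds the criterion
#'   value of each accepted step.
#' @export
gmdh_selection <- function(candidates, sessions, rho_v = 0.75,
                           gamma_f = 0.1, evaluator = evaluate_subset,
                           scores = rep(NA_real_, length(candidates)),
                           rho = NA_real_) {
  stopifnot(length(candidates) >= 1)
  eval1 <- function(f) as.numeric(evaluator(f, sessions, rho_v, gamma_f))
  vals <- vapply(as.list(candidates), eval1, numeric(1))
  best <- which.max(vals)
  selected <- candidates[best]
  remaining <- candidates[-best]
  trace <- vals[best]
  repeat {
    if (!length(remaining)) break
    ext <- vapply(remaining,
                  function(f) eval1(c(selected, f)), numeric(1))
    b <- which.max(ext)
    if (ext[b] > trace[length(trace)]) {
      selected <- c(selected, remaining[b])
      remaining <- remaining[-b]
      trace <- c(trace, ext[b])
    } else break
  }
  selection_result(method = "gmdh",
                   candidates = candidates, scores = scores,
                   selected = selected, trace = trace,
                   K = length(candidates), rho = rho)
}

#' Unified cross-user feature subset
#'
#' Per user, intersects the selected sets across that user's selection
#' methods (the features every method agrees on); the per-user
#' intersections are then unioned across users. A user whose methods
#' share no feature contributes nothing (with a warning).
#'
#' @param per_user_results Named list; each element is a list of
#'   [selection_result()]s (or plain integer vectors) for one user, one
#'   per selection method (a single method contributes its set as-is).
#' @return Sorted integer vector of unified features.
#' @export
unified_model <- function(per_user_results) {
  stopifnot(length(per_user_results) >= 1)
  as_set <- function(r) if (inherits(r, "selection_result")) r$selected
  else as.integer(r)
  out <- integer(0)
  for (u in names(per_user_results)) {
    sets <- lapply(per_user_results[[u]], as_set)
    if (!length(sets)) stop("user ", u, " has no method results")
    common <- Reduce(intersect, sets)
    if (!length(common))
      warning("user ", u, " has no feature common to all methods")
    out <- union(out, common)
  }
  sort(as.integer(out))
}

#' Full three-stage selection pipeline
#'
#' Stage 1 computes per-feature discriminant character — statistics
#' route: one [product_criterion()] (or [entropy_criterion()]) per
#' learning session (3 runs); fuzzy route: one [fuzzy_feature_scores()]
#' per (learn, prune) permutation of the sessions (6 runs). Stage 2
#' scores each run ([score_run()]), accumulates, and selects candidates
#' by the cumulative-score threshold `rho`. Stage 3 runs the requested
#' wrapper over the candidates.
#'
#' @param sessions List of 3 labeled [feature_session()]s.
#' @param criterion `"statistic"` or `"fuzzy"`.
#' @param wrapper `"order"` or `"gmdh"`.
#' @param rho Candidate cumulative-score threshold.
#' @param rho_v,gamma_f Classifier parameters.
#' @param statistic_form `"product"` or `"entropy"` (statistics route).
#' @param fuzzy_aggregate `"min"` or `"mean"` (fuzzy route).
#' @return A [selection_result()] with `method` of the form
#'   `"<criterion>+<wrapper>"`.
#' @export
select_features <- function(sessions, criterion = c("statistic", "fuzzy"),
                            wrapper = c("gmdh", "order"), rho = 0.85,
                            rho_v = 0.75, gamma_f = 0.1,
                            statistic_form = c("product", "entropy"),
                            fuzzy_aggregate = c("min", "mean")) {
  criterion <- match.arg(criterion)
  wrapper <- match.arg(wrapper)
  statistic_form <- match.arg(statistic_form)
  fuzzy_aggregate <- match.arg(fuzzy_aggregate)
  if (length(sessions) != 3) stop("exactly 3 sessions are required")
  runs <- if (criterion == "statistic") {
    lapply(sessions, function(s) {
      tbl <- normalized_variance(s)
      cv <- if (statistic_form == "product") product_criterion(tbl)
      else entropy_criterion(tbl)
      score_run(cv)
    })
  } else {
    pairs <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    lapply(pairs, function(p) {
      m <- fit_fuzzy_model(sessions[[p[1]]], rho_v, gamma_f)
      m <- prune_rules(m, sessions[[p[2]]])
      score_run(fuzzy_feature_scores(intermediate_model(m),
                                     aggregate = fuzzy_aggregate))
    })
  }
  tbl <- accumulate_scores(runs)
  cand <- select_candidates(tbl, rho)
  wrap_fun <- if (wrapper == "gmdh") gmdh_selection else order_selection
  res <- wrap_fun(cand$candidates, sessions, rho_v, gamma_f,
                  scores = tbl$scores[cand$candidates], rho = rho)
  res$method <- paste0(criterion, "+", wrapper)
  res
}
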