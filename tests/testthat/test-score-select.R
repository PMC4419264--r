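cv <- function(values, direction = "low")
  structure(list(values = values, direction = direction, method = "mock"),
            class = "criterion_vector")

test_that("score_run assigns 10..1 to the ten most discriminant features", {
  scores <- score_run(cv(1:96))
  expect_identical(scores[1:10], 10:1)
  expect_true(all(scores[11:96] == 0L))
  expect_identical(sum(scores), 55L)
  # direction "high" reverses the ranking
  expect_identical(score_run(cv(1:96, "high"))[96:87], 10:1)
  # ties break toward the lower feature index; verify against a stable sort
  set.seed(8)
  v <- sample(c(0.1, 0.2, 0.3), 30, replace = TRUE)
  s <- score_run(cv(v))
  ord <- order(v, seq_along(v))
  expect_identical(s[ord[1:10]], 10:1)
  # unrankable (NA) features are never scored
  vna <- c(NA, 1:11)
  expect_identical(score_run(cv(vna))[1], 0L)
  # fewer than 10 rankable features: score as many as exist
  expect_identical(score_run(cv(c(3, 1, 2))), c(8L, 10L, 9L))
})

test_that("accumulate_scores sums runs and conserves 55 per run", {
  r <- score_run(cv(1:20))
  tbl <- accumulate_scores(list(r, r, r))
  expect_identical(tbl$scores, 3L * r)
  expect_identical(tbl$runs, 3L)
  expect_identical(sum(tbl$scores), 55L * 3L)
  set.seed(12)
  runs <- replicate(6, score_run(cv(runif(40))), simplify = FALSE)
  acc <- accumulate_scores(runs)
  expect_equal(acc$scores, Reduce(`+`, runs))
  expect_identical(sum(acc$scores), 55L * 6L)
  expect_error(accumulate_scores(list(1:5, 1:6)), "arity")
})

test_that("select_candidates applies the strict cumulative threshold", {
  # all mass on one feature
  tbl <- structure(list(scores = c(0, 12, 0, 0), runs = 1L),
                   class = "score_table")
  expect_identical(select_candidates(tbl, 0.99),
                   list(K = 1L, candidates = 2L))
  # hand-computed case: one run scoring (10, 9, ..., 1); cumulative
  # fractions 10/55, 19/55, ...; the first strictly above 0.85 is k = 7
  tbl55 <- structure(list(scores = c(10:1, rep(0, 10)), runs = 1L),
                     class = "score_table")
  sel <- select_candidates(tbl55, 0.85)
  expect_identical(sel$K, 7L)
  expect_identical(sel$candidates, 1:7)
  # K is non-decreasing in rho
  set.seed(4)
  for (i in 1:10) {
    tblr <- structure(list(scores = rpois(30, 3), runs = 1L),
                      class = "score_table")
    Ks <- vapply(seq(0.05, 0.95, by = 0.1),
                 function(r) select_candidates(tblr, r)$K, integer(1))
    expect_true(all(diff(Ks) >= 0))
  }
  expect_error(select_candidates(tbl55, 1), "rho")
})

test_that("order_selection returns the best prefix, shortest on ties", {
  peak2 <- function(features, sessions, rho_v, gamma_f)
    c(50, 80, 70, 60, 80)[length(features)]
  res <- order_selection(c(38L, 2L, 31L, 7L, 14L), sessions = NULL,
                         evaluator = peak2)
  expect_identical(res$selected, c(38L, 2L))  # ties at 80 -> shorter prefix
  expect_equal(res$trace, c(50, 80, 70, 60, 80))
  # K = 1 degenerate case
  res1 <- order_selection(5L, NULL, evaluator = function(f, ...) 42)
  expect_identical(res1$selected, 5L)
  # exhaustive prefix scan oracle on random deterministic evaluators
  set.seed(77)
  for (i in 1:10) {
    vals <- runif(8, 0, 100)
    ev <- function(features, ...) vals[length(features)]
    res <- order_selection(1:8, NULL, evaluator = ev)
    expect_identical(length(res$selected), which.max(vals))
    expect_equal(res$trace[length(res$selected)], max(vals))
  }
})

test_that("gmdh_selection runs the documented greedy search", {
  # deterministic evaluator f(S) = |S ∩ {a,b}| * 10 - |S| with a=4, b=7:
  # singles: f({4})=f({7})=9, others -1; best single is 4 (lowest index
  # among maxima); extensions: f({4,7})=18 accepted; any third feature
  # drops to 17 -> stop
  ev <- function(features, ...)
    length(intersect(features, c(4L, 7L))) * 10 - length(features)
  res <- gmdh_selection(c(1L, 4L, 7L, 9L), NULL, evaluator = ev)
  expect_identical(sort(res$selected), c(4L, 7L))
  expect_equal(res$trace, c(9, 18))
  # evaluator maximal on singletons: one feature returned
  res1 <- gmdh_selection(1:5, NULL,
                         evaluator = function(f, ...) 90 - 10 * length(f))
  expect_length(res1$selected, 1)
  # accepted trace strictly increases on random evaluators
  set.seed(55)
  for (i in 1:10) {
    tabvals <- new.env()
    ev <- function(features, ...) {
      key <- paste(sort(features), collapse = ",")
      if (is.null(tabvals[[key]])) tabvals[[key]] <- runif(1, 0, 100)
      tabvals[[key]]
    }
    res <- gmdh_selection(1:6, NULL, evaluator = ev)
    expect_true(all(diff(res$trace) > 0))
    expect_equal(res$trace[length(res$trace)], ev(res$selected))
  }
})

test_that("evaluate_subset is deterministic and near chance on shuffled labels", {
  ss <- balanced_sessions(3, 3, informative = 1:4, n_features = 8)
  rc1 <- evaluate_subset(1:4, ss)
  rc2 <- evaluate_subset(1:4, ss)
  expect_identical(rc1, rc2)
  expect_length(attr(rc1, "per_permutation"), 6)
  expect_error(evaluate_subset(integer(0), ss), "empty")
  rcs <- vapply(1:5, function(seed) {
    ss <- balanced_sessions(seed, 3, n_features = 10)
    set.seed(seed)
    ss <- lapply(ss, function(s) { s$labels <- sample(s$labels); s })
    as.numeric(evaluate_subset(1:5, ss))
  }, numeric(1))
  expect_lt(abs(mean(rcs) - 100 / 3), 5)
})

test_that("unified_model intersects per user then unions across users", {
  sel <- jsonlite::read_json(system.file("extdata",
                                         "bci3v_reported_selections.json",
                                         package = "eegfsel"),
                             simplifyVector = TRUE)
  uf <- unified_model(sel$users)
  expect_identical(uf, c(2L, 3L, 4L, 26L, 38L))
  # per-user intersections behind the union
  expect_identical(sort(Reduce(intersect, sel$users$user1)), c(2L, 38L))
  expect_identical(sort(Reduce(intersect, sel$users$user2)), c(2L, 26L))
  expect_identical(sort(Reduce(intersect, sel$users$user3)), c(3L, 4L))
  # single user, single method: that method's set
  expect_identical(unified_model(list(u = list(c(9L, 5L)))), c(5L, 9L))
  # empty intersection contributes nothing, with a warning
  expect_warning(
    out <- unified_model(list(a = list(1:2, 3:4), b = list(c(7L, 8L), 8L))),
    "no feature common")
  expect_identical(out, 8L)
  # brute-force membership enumeration oracle on random inputs
  set.seed(61)
  for (i in 1:10) {
    users <- lapply(1:3, function(u)
      lapply(1:3, function(m) sort(sample(1:15, sample(3:6, 1)))))
    names(users) <- paste0("u", 1:3)
    got <- suppressWarnings(unified_model(users))
    ref <- integer(0)
    for (f in 1:15) for (u in users) {
      if (all(vapply(u, function(s) f %in% s, logical(1))))
        ref <- union(ref, f)
    }
    expect_identical(got, sort(as.integer(ref)))
  }
})
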