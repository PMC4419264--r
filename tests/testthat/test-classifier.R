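test_that("fit memorizes singletons and is deterministic", {
  X <- rbind(c(0.1, 0.9), c(0.9, 0.1), c(0.5, 0.5))
  s <- make_session(X, c(2L, 3L, 7L))
  m <- fit_fuzzy_model(s)
  for (i in 1:3)
    expect_identical(predict_sample(m, X[i, ]), s$labels[i])
  m2 <- fit_fuzzy_model(s)
  expect_identical(m[c("core_lo", "core_hi", "rule_class")],
                   m2[c("core_lo", "core_hi", "rule_class")])
  expect_error(predict_sample(m, c(0.1, 0.2, 0.3)), "arity")
})

test_that("maximal vigilance creates one rule per distinct sample and 100% training accuracy", {
  set.seed(5)
  X <- matrix(runif(40), 20, 2)
  X <- rbind(X, X[1:3, ])  # duplicates must be absorbed, not duplicated
  y <- rep(c(2L, 3L), length.out = nrow(X))
  y[21:23] <- y[1:3]       # duplicates carry their original class
  s <- make_session(X, y)
  m <- fit_fuzzy_model(s, rho_v = 1)
  expect_identical(nrow(m$core_lo), 20L)
  expect_identical(unname(predict_session(m, s)), y)
})

test_that("well-separated clusters are recovered on held-out data across 20 seeds", {
  accs <- vapply(1:20, function(seed) {
    ss <- balanced_sessions(seed, 2, informative = 1:3, effect = 4,
                            n_features = 3)
    m <- fit_fuzzy_model(ss[[1]])
    100 * mean(predict_session(m, ss[[2]]) == ss[[2]]$labels)
  }, numeric(1))
  expect_true(all(accs >= 95))
})

test_that("pruning removes exactly the rules with more errors than successes, winner-only", {
  # feature domain [0,1]; four hand-placed rules, gamma small enough that
  # each probe point activates only its intended rule
  m <- make_model(core_lo = cbind(c(0.0, 0.8, 0.40, 0.60)),
                  core_hi = cbind(c(0.2, 1.0, 0.50, 0.62)),
                  rule_class = c(1L, 2L, 1L, 2L),
                  label_set = c(2L, 3L), gamma_f = 0.02)
  X <- cbind(c(rep(0.10, 3), rep(0.12, 5),   # rule 1: 3 success, 5 error
               rep(0.90, 5), rep(0.92, 3),   # rule 2: 5 success, 3 error
               rep(0.45, 2), rep(0.46, 2)))  # rule 3: 2 success, 2 error
  y <- c(rep(2L, 3), rep(3L, 5), rep(3L, 5), rep(2L, 3),
         rep(2L, 2), rep(3L, 2))
  pm <- prune_rules(m, make_session(X, y))
  # (3,5) removed; (5,3) kept; (2,2) kept; never-winning rule 4 kept
  expect_equal(pm$core_lo[, 1], c(0.8, 0.40, 0.60))
  expect_equal(pm$success, c(5L, 2L, 0L))
  expect_equal(pm$error, c(3L, 2L, 0L))
  # empty prune session leaves the model unchanged
  expect_identical(prune_rules(m, make_session(matrix(0, 0, 1), integer(0))),
                   m)
  # rule count never increases
  expect_lte(nrow(pm$core_lo), nrow(m$core_lo))
})

test_that("pruning never empties a class", {
  m <- make_model(core_lo = cbind(c(0.0, 0.8)), core_hi = cbind(c(0.2, 1.0)),
                  rule_class = c(1L, 2L), label_set = c(2L, 3L),
                  gamma_f = 0.02)
  # every class-1 sample is an error for rule 1, but rule 1 is its class's
  # only representative and must survive
  X <- cbind(c(rep(0.1, 4), rep(0.9, 4)))
  y <- c(rep(3L, 4), rep(3L, 4))
  pm <- prune_rules(m, make_session(X, y))
  expect_setequal(unique(pm$rule_class), c(1L, 2L))
})

test_that("build_models yields the six (learn, prune) permutations with learn-only normalization", {
  ss <- balanced_sessions(2, 3, informative = 1:2, n_features = 4)
  models <- build_models(ss)
  expect_length(models, 6)
  prov <- t(vapply(models, function(m)
    c(m$provenance$learn, m$provenance$prune), character(2)))
  expect_setequal(paste(prov[, 1], prov[, 2]),
                  c("synth1 synth2", "synth1 synth3", "synth2 synth1",
                    "synth2 synth3", "synth3 synth1", "synth3 synth2"))
  for (m in models) {
    learn_idx <- match(m$provenance$learn, c("synth1", "synth2", "synth3"))
    expect_equal(m$norm$min, apply(ss[[learn_idx]]$features, 2, min))
    expect_equal(m$norm$max, apply(ss[[learn_idx]]$features, 2, max))
  }
  expect_error(build_models(ss[1:2]), "3 sessions")
  expect_error(build_models(list(ss[[1]], ss[[1]], ss[[2]])), "duplicate")
})

test_that("predict agrees with an exhaustive activation scan on random inputs", {
  set.seed(21)
  ss <- balanced_sessions(7, 1, informative = 1:2, n_features = 5)
  m <- fit_fuzzy_model(ss[[1]])
  X <- matrix(runif(40 * 5, 0, max(ss[[1]]$features)), 40, 5)
  got <- predict_session(m, make_session(X, rep(2L, 40)))
  # independent oracle: normalize, score every rule by min-membership,
  # take the max with lowest-index ties
  rng <- m$norm$max - m$norm$min
  for (t in seq_len(nrow(X))) {
    z <- pmin(pmax((X[t, ] - m$norm$min) / rng, 0), 1)
    act <- vapply(seq_len(nrow(m$core_lo)), function(r) {
      min(oracle_mu(z, m$core_lo[r, ], m$core_hi[r, ], m$gamma_f))
    }, numeric(1))
    expect_identical(got[t], m$label_set[m$rule_class[which.max(act)]])
  }
})

test_that("vote_predict aggregates 48 votes with the documented tie rules", {
  # six single-rule models engineered to produce fixed votes
  mk <- function(lab) make_model(cbind(0), cbind(1), 1L, lab, gamma_f = 0)
  w <- matrix(0.5, 8, 1)
  # 5 models vote LEFT(2), 1 votes RIGHT(3): 40 vs 8
  models <- c(replicate(5, mk(2L), simplify = FALSE), list(mk(3L)))
  d <- vote_predict(models, w)
  expect_identical(as.integer(d), 2L)
  expect_identical(sum(attr(d, "votes")), 48L)
  # 24/24 tie: previous decision wins; without one, lowest label
  models <- c(replicate(3, mk(3L), simplify = FALSE),
              replicate(3, mk(7L), simplify = FALSE))
  expect_identical(as.integer(vote_predict(models, w, prev = 3L)), 3L)
  expect_identical(as.integer(vote_predict(models, w, prev = 7L)), 7L)
  expect_identical(as.integer(vote_predict(models, w)), 3L)
  expect_error(vote_predict(models, w[1:4, , drop = FALSE]), "8 feature vectors")
  expect_error(vote_predict(models[1:5], w), "6 models")
})

test_that("vote outcome is invariant under permutation of the votes", {
  ss <- balanced_sessions(13, 3, informative = 1:3, n_features = 6)
  models <- build_models(ss)
  w <- ss[[1]]$features[1:8, ]
  base <- as.integer(vote_predict(models, w))
  set.seed(99)
  for (i in 1:5) {
    perm_models <- models[sample(6)]
    perm_rows <- w[sample(8), ]
    expect_identical(as.integer(vote_predict(perm_models, perm_rows)), base)
  }
})

test_that("intermediate model averages rule cores feature-wise", {
  m <- make_model(core_lo = rbind(c(0.0, 0.3), c(0.2, 0.5), c(0.6, 0.1)),
                  core_hi = rbind(c(0.1, 0.4), c(0.3, 0.6), c(0.9, 0.2)),
                  rule_class = c(1L, 1L, 2L), label_set = c(2L, 3L))
  im <- intermediate_model(m)
  expect_equal(im$proto_lo[1, ], c(0.1, 0.4))   # mean of the two class-2 rules
  expect_equal(im$proto_hi[1, ], c(0.2, 0.5))
  expect_equal(im$proto_lo[2, ], c(0.6, 0.1))   # single rule: identity
  expect_equal(im$proto_hi[2, ], c(0.9, 0.2))

  # loop-based reference on a random rule set
  set.seed(31)
  R <- 9
  lo <- matrix(runif(R * 4, 0, 0.5), R, 4)
  hi <- lo + matrix(runif(R * 4, 0, 0.5), R, 4)
  cls <- sample(1:3, R, replace = TRUE)
  cls[1:3] <- 1:3  # every class represented
  mr <- make_model(lo, hi, cls, c(2L, 3L, 7L))
  imr <- intermediate_model(mr)
  for (ci in 1:3) for (j in 1:4) {
    expect_equal(imr$proto_lo[ci, j], mean(lo[cls == ci, j]))
    expect_equal(imr$proto_hi[ci, j], mean(hi[cls == ci, j]))
  }
  expect_error(intermediate_model(
    make_model(cbind(0), cbind(1), 1L, c(2L, 3L))), "no rules")
})

test_that("end-to-end learn/prune/vote recovers strong synthetic structure", {
  hits <- 0L
  for (seed in 1:20) {
    ss <- balanced_sessions(seed, 4, informative = 1:4, effect = 3,
                            n_features = 4, minutes = 1)
    models <- build_models(ss[1:3])
    acc <- classify_session(models, ss[[4]])$accuracy
    if (acc >= 90) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
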