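# Shared builders for tiny in-code fixtures.

# A hand-built fuzzy model over [0, 1] features with an identity
# normalization, for tests that need exact control over the rule set.
make_model <- function(core_lo, core_hi, rule_class, label_set,
                       gamma_f = 0.1, rho_v = 0.75) {
  core_lo <- as.matrix(core_lo)
  core_hi <- as.matrix(core_hi)
  structure(list(core_lo = core_lo, core_hi = core_hi,
                 rule_class = as.integer(rule_class),
                 label_set = as.integer(label_set),
                 rho_v = rho_v, gamma_f = gamma_f,
                 norm = list(min = rep(0, ncol(core_lo)),
                             max = rep(1, ncol(core_lo))),
                 success = rep(0L, nrow(core_lo)),
                 error = rep(0L, nrow(core_lo)),
                 provenance = list(learn = "manual", prune = NULL)),
            class = "fuzzy_model")
}

# Small labeled session from explicit rows.
make_session <- function(X, labels, id = "s", vps = 16L) {
  feature_session(as.matrix(X), labels, vps, id)
}

# Balanced synthetic world: 0.75 min = exactly one 15 s block per class.
balanced_sessions <- function(seed, n_sessions = 3, informative = integer(0),
                              effect = 2, n_features = 96, minutes = 0.75) {
  spec <- synthetic_spec(informative = informative, effect_size = effect,
                         n_features = n_features, session_minutes = minutes,
                         seed = seed)
  generate_sessions(spec, n_sessions)
}

# Independent trapezoid membership for oracles (plain R, no package code).
oracle_mu <- function(x, lo, hi, gamma) {
  d <- pmax(lo - x, x - hi, 0)
  if (gamma <= 0) as.numeric(d <= 0) else pmax(0, 1 - d / gamma)
}
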