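# Stage-1 discriminant character.
#
# Statistical route: per-feature normalized within-class variances
# gamma_tilde[i, j] = P_i * var_ij / lambda_j (population variances, so
# the law-of-total-variance bound sum_i gamma_tilde[i, j] <= 1 is exact,
# with equality iff the class means of feature j coincide). Two scalar
# criteria condense the table: an entropy form sum gamma * log(gamma)
# and a product form prod gamma, whose maximum (1/C)^C is attained
# exactly by features carrying no mean separation.
#
# Fuzzy route: per-class trapezoidal fuzzy sets from an intermediate
# model are compared pairwise by the fuzzy Jaccard ratio
# integral(min) / integral(max); values near 0 mark discriminant
# features, near 1 non-discriminant ones.

#' Normalized within-class variance table
#'
#' For each class i and feature j computes
#' `gamma_tilde[i, j] = P_i * gamma[i, j] / lambda[j]` where
#' `gamma[i, j]` is the population variance of feature j within class i,
#' `P_i` the empirical class frequency, and `lambda[j]` the population
#' variance of feature j over all samples. Features with zero total
#' variance are flagged and excluded from ranking.
#'
#' @param session A labeled [feature_session()] with at least two samples.
#' @return An object of class `normalized_variance_table` with fields
#'   `gamma_tilde` (classes x features), `priors`, `class_var`,
#'   `total_var`, `constant` (logical flag per feature), `label_set`.
#' @export
normalized_variance <- function(session) {
  X <- session$features
  if (nrow(X) < 2) stop("need at least 2 samples")
  labs <- session$label_set
  C <- length(labs)
  m <- ncol(X)
  n <- nrow(X)
  popvar <- function(M) {
    if (nrow(M) == 0) return(rep(NA_real_, ncol(M)))
    mu <- colMeans(M)
    colMeans(sweep(M, 2, mu)^2)
  }
  lambda <- popvar(X)
  const <- lambda <= .Machine$double.eps * 100
  gv <- matrix(NA_real_, C, m)
  priors <- numeric(C)
  for (ci in seq_len(C)) {
    rows <- session$labels == labs[ci]
    priors[ci] <- mean(rows)
    gv[ci, ] <- popvar(X[rows, , drop = FALSE])
  }
  gt <- sweep(gv * priors, 2, ifelse(const, NA_real_, lambda), "/")
  structure(list(gamma_tilde = gt, priors = priors, class_var = gv,
                 total_var = lambda, constant = const, label_set = labs),
            class = "normalized_variance_table")
}

.criterion_vector <- function(values, direction, method) {
  structure(list(values = as.numeric(values), direction = direction,
                 method = method),
            class = "criterion_vector")
}

#' Entropy discriminant criterion
#'
#' `J(x_j) = sum_i gamma_tilde[i, j] * log(gamma_tilde[i, j])` (natural
#' log; `0 * log 0 = 0`). J ranges in `[-log C, 0]`: a feature whose
#' within-class variances exhaust the total variance in equal shares
#' (no mean separation) attains the minimum `-log C`, while strongly
#' discriminant features (small within-class shares) push J toward 0.
#' High values therefore mark discriminant features; rankings are
#' invariant to the logarithm base.
#'
#' @param tbl A [normalized_variance()] table.
#' @return A `criterion_vector` with `direction = "high"`.
#' @export
entropy_criterion <- function(tbl) {
  g <- tbl$gamma_tilde
  term <- ifelse(is.na(g) | g > 0, g * log(g), 0)
  term[!is.na(g) & g == 0] <- 0
  .criterion_vector(colSums(term), direction = "high", method = "entropy")
}

#' Product discriminant criterion
#'
#' `J(x_j) = prod_i gamma_tilde[i, j]`, bounded above by `(1/C)^C`,
#' which is attained exactly when all class shares are equal and sum to
#' one — i.e. by features adding no discriminant information. Low
#' values mark discriminant features.
#'
#' @param tbl A [normalized_variance()] table.
#' @return A `criterion_vector` with `direction = "low"`.
#' @export
product_criterion <- function(tbl) {
  .criterion_vector(apply(tbl$gamma_tilde, 2, prod),
                    direction = "low", method = "product")
}

# Trapezoid membership on a grid: core [lo, hi], linear decay gamma.
.trap_mu <- function(grid, lo, hi, gamma) {
  d <- pmax(lo - grid, grid - hi, 0)
  if (gamma <= 0) as.numeric(d <= 0) else pmax(0, 1 - d / gamma)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Fuzzy Jaccard similarity of two trapezoidal sets
#'
#' `F = integral(min(mu_A, mu_B)) / integral(max(mu_A, mu_B))`,
#' integrated by the trapezoid rule on a uniform grid spanning both
#' supports. `F = 1` for identical sets, `0` for disjoint supports, and
#' (by convention) `1` when both sets are empty.
#'
#' @param A,B Lists with elements `lo`, `hi`, `gamma` describing a
#'   trapezoid: full membership on `[lo, hi]`, linear decay to zero over
#'   width `gamma`.
#' @param grid_n Number of integration points (default 1001).
#' @return Similarity in `[0, 1]`.
#' @export
fuzzy_pair_similarity <- function(A, B, grid_n = 1001) {
  g0 <- min(A$lo - A$gamma, B$lo - B$gamma)
  g1 <- max(A$hi + A$gamma, B$hi + B$gamma)
  if (g1 <= g0) return(1)  # both sets degenerate to the same point
  grid <- seq(g0, g1, length.out = grid_n)
  ma <- .trap_mu(grid, A$lo, A$hi, A$gamma)
  mb <- .trap_mu(grid, B$lo, B$hi, B$gamma)
  den <- .trapz(grid, pmax(ma, mb))
  if (den <= 0) return(1)  # both sets empty
  .trapz(grid, pmin(ma, mb)) / den
}

#' Per-feature fuzzy discriminant scores from an intermediate model
#'
#' For every feature, [fuzzy_pair_similarity()] is evaluated for each of
#' the `C(C-1)/2` class pairs of prototype fuzzy sets and aggregated
#' (default `min`: a feature that cleanly separates any pair of classes
#' is useful). Values near 0 mark discriminant features.
#'
#' @param im An [intermediate_model()].
#' @param aggregate `"min"` or `"mean"` over class pairs.
#' @param grid_n Integration grid size per pair.
#' @return A `criterion_vector` with `direction = "low"`.
#' @export
fuzzy_feature_scores <- function(im, aggregate = c("min", "mean"),
                                 grid_n = 1001) {
  aggregate <- match.arg(aggregate)
  C <- length(im$label_set)
  m <- ncol(im$proto_lo)
  agg <- if (aggregate == "min") min else mean
  vals <- numeric(m)
  pairs <- utils::combn(C, 2)
  for (j in seq_len(m)) {
    fs <- apply(pairs, 2, function(p) {
      fuzzy_pair_similarity(
        list(lo = im$proto_lo[p[1], j], hi = im$proto_hi[p[1], j],
             gamma = im$gamma_f),
        list(lo = im$proto_lo[p[2], j], hi = im$proto_hi[p[2], j],
             gamma = im$gamma_f),
        grid_n)
    })
    vals[j] <- agg(fs)
  }
  .criterion_vector(vals, direction = "low", method = "fuzzy")
}
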