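# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: the Watson density is normalized by 1-D
# quadrature, the graph metrics are brute-force enumerations.

# Watson density on the sphere, prop. to exp(k (n.mu)^2), normalized by
# adaptive 1-D quadrature. Equals the Bingham density at kappa1 == kappa2
# == k up to the shared exp(-k) factor folding into the normalizer.
watson_density <- function(n, mu, k) {
  z <- 4 * pi * stats::integrate(function(t) exp(k * t^2), 0, 1,
                                 rel.tol = 1e-12)$value
  if (!is.matrix(n)) n <- matrix(n, 1)
  exp(k * as.vector(n %*% mu)^2) / z
}

# All-pairs shortest paths by Floyd-Warshall on lengths 1/w.
brute_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_efficiency <- function(W) {
  n <- nrow(W)
  d <- brute_distances(W)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

# Onnela clustering by explicit triple enumeration.
brute_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wh <- W / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (Wh[i, j] * Wh[j, h] * Wh[h, i])^(1 / 3)
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0)
  out
}

# Exhaustive-search optimum of Newman modularity over every partition.
brute_modularity_opt <- function(W, gamma = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    q <- mwconn:::modularity_q(W, p, gamma)
    if (q > best) best <- q
  }
  best
}

# Random symmetric nonnegative test graph with zero diagonal.
random_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- stats::runif(sum(ut)) * (stats::runif(sum(ut)) < p_edge)
  W[ut] <- vals
  W + t(W)
}

# Random Bingham-NODDI parameter draw over the identifiable box.
random_bnoddi <- function(seed) {
  set.seed(seed)
  odi <- stats::runif(1, 0.04, 0.7)
  bf <- stats::runif(1, 0, 0.95)
  bnoddi_params(stats::runif(1, 0, 0.5), stats::runif(1, 0.15, 0.95),
                acos(stats::runif(1, -1, 1)), stats::runif(1, -pi, pi),
                stats::runif(1, 0, pi),
                kappa1 = kappa_from_odi(odi),
                kappa2 = kappa_from_odi(odi) * bf)
}

angle_deg <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi

expect_symmetric_zero_diag <- function(W) {
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
}
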