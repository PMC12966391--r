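# Weighted graph metrics, following the Brain Connectivity Toolbox
# definitions: density, mean nodal strength, weighted global efficiency
# (lengths 1/w), Onnela weighted clustering, Louvain modularity.

as_conn_matrix <- function(W, require_nonneg = TRUE) {
  if (inherits(W, "weighted_connectome")) W <- W$matrix
  W <- unname(as.matrix(W))
  if (nrow(W) != ncol(W)) stopf("connectome matrix must be square")
  if (max(abs(W - t(W))) > 1e-10 * max(1, max(abs(W))))
    stopf("connectome matrix must be symmetric")
  if (require_nonneg && any(W < 0)) stopf("negative edge weight(s)")
  diag(W) <- 0
  W
}

#' Connection density
#'
#' Fraction of possible undirected edges that are present:
#' `2K / (N (N - 1))` with K the number of nonzero upper-triangle entries.
#' Independent of the edge weights, so identical across all weightings of
#' the same tractogram.
#'
#' @param W a `weighted_connectome` or symmetric nonnegative matrix with
#'   zero diagonal.
#' @return density in \[0, 1\].
#' @export
connectome_density <- function(W) {
  W <- as_conn_matrix(W)
  n <- nrow(W)
  if (n < 2) return(0)
  2 * sum(W[upper.tri(W)] != 0) / (n * (n - 1))
}

#' Mean nodal strength
#'
#' Node strength is the sum of a node's edge weights (weighted degree);
#' the summary value is its mean over all nodes.
#'
#' @inheritParams connectome_density
#' @return mean strength (weight units).
#' @export
mean_strength <- function(W) {
  W <- as_conn_matrix(W)
  mean(rowSums(W))
}

#' Weighted global efficiency
#'
#' Edge lengths are reciprocal weights (L = 1/w); d_ij is the shortest
#' weighted path length between nodes i and j, and efficiency is the mean of
#' 1/d_ij over ordered pairs, with disconnected pairs contributing 0.
#'
#' @inheritParams connectome_density
#' @return global efficiency (>= 0; 1 for the unit-weight complete graph).
#' @export
global_efficiency_weighted <- function(W) {
  W <- as_conn_matrix(W)
  n <- nrow(W)
  if (n < 2) return(0)
  L <- ifelse(W > 0, 1 / W, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean weighted clustering coefficient (Onnela)
#'
#' Per node, the geometric mean of triangle weights normalized by the
#' largest weight in the network:
#' `C_i = sum_jk (w_ij' w_jk' w_ki')^(1/3) / (k_i (k_i - 1))` with
#' `w' = w / max(w)` and k_i the nodal degree; nodes with degree < 2
#' contribute 0. Returns the mean over all nodes.
#'
#' @inheritParams connectome_density
#' @return mean clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient_weighted <- function(W) {
  W <- as_conn_matrix(W)
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  cr <- (W / mx)^(1 / 3)
  num <- diag(cr %*% cr %*% cr)          # 2 x triangle intensity per node
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

# Greedy single-node refinement of a partition: repeatedly apply the best
# Q-improving move of any node to a neighbouring or fresh singleton
# community (the Louvain phase-1 sweep on the unaggregated graph) until no
# move improves Q. Deterministic.
refine_partition <- function(W, memb, gamma = 1) {
  n <- nrow(W)
  m2 <- sum(W)
  if (m2 == 0) return(rep(1L, n))
  k <- rowSums(W)
  memb <- as.integer(factor(memb))
  for (pass in seq_len(100)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      cands <- unique(c(memb[W[i, ] > 0], max(memb) + 1L))
      cands <- setdiff(cands, memb[i])
      if (!length(cands)) next
      K <- vapply(split(k, memb), sum, 0)
      Kc <- K[[as.character(memb[i])]]
      Si <- vapply(cands, function(d) sum(W[i, memb == d]), 0)
      Sc <- sum(W[i, memb == memb[i]])
      Kd <- vapply(cands, function(d) {
        kd <- K[as.character(d)]
        if (is.na(kd)) 0 else kd
      }, 0)
      dq <- (2 / m2) * (Si - Sc) -
        (2 * gamma * k[i] / m2^2) * (Kd - (Kc - k[i]))
      j <- which.max(dq)
      if (dq[j] > 1e-13) {
        memb[i] <- cands[j]
        memb <- as.integer(factor(memb))
        improved <- TRUE
      }
    }
    # merge step: apply the best community merge if it raises Q
    u <- sort(unique(memb))
    if (length(u) > 1) {
      K <- vapply(u, function(c) sum(k[memb == c]), 0)
      best_dq <- 0
      best_pair <- NULL
      for (ci in seq_along(u)) for (cj in seq_len(ci - 1)) {
        Wcd <- sum(W[memb == u[ci], memb == u[cj]])
        dq <- 2 * (Wcd / m2 - gamma * K[ci] * K[cj] / m2^2)
        if (dq > best_dq + 1e-13) {
          best_dq <- dq
          best_pair <- c(u[ci], u[cj])
        }
      }
      if (!is.null(best_pair)) {
        memb[memb == best_pair[1]] <- best_pair[2]
        memb <- as.integer(factor(memb))
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

# Newman modularity of a partition at resolution gamma.
modularity_q <- function(W, membership, gamma = 1) {
  m2 <- sum(W)                            # 2m
  if (m2 == 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - gamma * outer(k, k) / m2) * same) / m2
}

#' Louvain community detection with modularity
#'
#' Runs seeded Louvain community detection `n_runs` times under random node
#' reorderings, polishes each run with a deterministic greedy single-node
#' refinement sweep, and returns the partition with the highest modularity
#' `Q = (1/2m) sum_ij (w_ij - gamma k_i k_j / 2m) delta(c_i, c_j)`.
#' Modularity is known to be sensitive to small edge-weight perturbations,
#' so the per-run Q values are returned alongside the best partition to make
#' that run-to-run spread visible. Deterministic for a fixed seed.
#'
#' @inheritParams connectome_density
#' @param gamma resolution parameter (> 0, default 1).
#' @param seed integer seed for the node-order shuffling.
#' @param n_runs number of restarts.
#' @return list with `membership` (integer community labels), `Q` (best
#'   modularity) and `q_runs` (Q of every run).
#' @export
modularity_louvain <- function(W, gamma = 1, seed = 0, n_runs = 10) {
  W <- as_conn_matrix(W)
  if (gamma <= 0) stopf("gamma must be positive")
  n <- nrow(W)
  if (sum(W) == 0)
    return(list(membership = rep(1L, n), Q = 0, q_runs = rep(0, n_runs)))
  g0 <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  best <- NULL
  q_runs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    inits <- with_local_seed(seed + r - 1, {
      perm <- sample.int(n)
      gp <- igraph::permute(g0, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                    resolution = gamma)
      # seeded random partitions as independent starting points
      c(list(igraph::membership(cl)[perm]),
        lapply(2:4, function(kinit)
          sample.int(min(kinit, n), n, replace = TRUE)))
    })
    q <- -Inf
    memb <- NULL
    for (ini in inits) {
      mm <- refine_partition(W, ini, gamma)
      qq <- modularity_q(W, mm, gamma)
      if (qq > q) { q <- qq; memb <- mm }
    }
    q_runs[r] <- q
    if (is.null(best) || q > best$Q + 1e-15)
      best <- list(membership = as.integer(memb), Q = q)
  }
  # a partition never beats the trivial one on a graph with no structure
  if (best$Q <= 0) best <- list(membership = rep(1L, n), Q = 0)
  c(best, list(q_runs = q_runs))
}

#' All network metrics of one connectome
#'
#' Computes the five reported network metrics -- density, weighted global
#' efficiency, Louvain modularity, mean Onnela clustering coefficient and
#' mean nodal strength -- for one weighted connectome.
#'
#' @inheritParams modularity_louvain
#' @return one-row data.frame with columns density, efficiency, modularity,
#'   clustering, strength.
#' @export
metric_set <- function(W, gamma = 1, seed = 0, n_runs = 10) {
  data.frame(density = connectome_density(W),
             efficiency = global_efficiency_weighted(W),
             modularity = modularity_louvain(W, gamma, seed, n_runs)$Q,
             clustering = clustering_coefficient_weighted(W),
             strength = mean_strength(W))
}
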