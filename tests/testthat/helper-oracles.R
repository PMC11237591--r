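# Independent oracles used across the suite. Everything here is written
# against the definitions, not against the package's implementation paths.

# Constant-rate birth-death log-likelihood of an ultrametric tree, closed
# form: along a branch running from age t0 (tipward) to t1, the data
# variable scales by psi(t1)/psi(t0) with
# psi(t) = e^{rt} r^2 / (lambda e^{rt} - mu)^2, and every internal node
# (including the root) contributes a factor lambda. No conditioning.
oracle_bd_loglik <- function(tree, lambda, mu) {
  r <- lambda - mu
  stopifnot(r > 0)
  nd <- ape::node.depth.edgelength(tree)
  age <- max(nd) - nd
  tre <- ape::reorder.phylo(tree, "postorder")
  psi <- function(t) exp(r * t) * r^2 / (lambda * exp(r * t) - mu)^2
  bs <- 0
  for (k in seq_len(nrow(tre$edge))) {
    t0 <- age[tre$edge[k, 2]]
    bs <- bs + log(psi(t0 + tre$edge.length[k]) / psi(t0))
  }
  bs + ape::Nnode(tree) * log(lambda)
}

# Two-state symmetric Markov (Mk2) character log-likelihood by pruning with
# the analytic transition probabilities. root = "equal" (1/2, 1/2 weights)
# or "weighted" (weights proportional to the conditional likelihoods).
oracle_mk2_loglik <- function(tree, states, q, root = "equal") {
  tre <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  L <- matrix(0, n + tree$Nnode, 2)
  st <- ifelse(states[tree$tip.label] == "generalist", 1, 2)
  L[cbind(seq_len(n), st)] <- 1
  seen <- integer(n + tree$Nnode)
  comp <- 0
  for (k in seq_len(nrow(tre$edge))) {
    par <- tre$edge[k, 1]; ch <- tre$edge[k, 2]; t <- tre$edge.length[k]
    same <- (1 + exp(-2 * q * t)) / 2
    diff <- (1 - exp(-2 * q * t)) / 2
    v <- c(same * L[ch, 1] + diff * L[ch, 2],
           diff * L[ch, 1] + same * L[ch, 2])
    if (seen[par] == 0) L[par, ] <- v else {
      L[par, ] <- L[par, ] * v
      s <- sum(L[par, ]); L[par, ] <- L[par, ] / s; comp <- comp + log(s)
    }
    seen[par] <- seen[par] + 1
  }
  cl <- L[tre$edge[nrow(tre$edge), 1], ]
  if (root == "equal") log(0.5 * sum(cl)) + comp
  else log(sum(cl^2) / sum(cl)) + comp
}

# Equal-rate BiSSE factorisation oracle: BD tree likelihood times Mk2
# character likelihood under matching root conventions.
oracle_bd_mk2 <- function(tree, states, lambda, mu, q, root = "equal") {
  oracle_bd_loglik(tree, lambda, mu) +
    oracle_mk2_loglik(tree, states, q, root)
}

# Global efficiency by brute force from an adjacency matrix (BFS distances).
oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  tot <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] > 0)) {
          if (dist[u] == Inf) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
        }
      }
      frontier <- nxt
    }
    tot <- tot + sum(1 / dist[-s][is.finite(dist[-s])])
  }
  tot / (n * (n - 1))
}

oracle_vulnerability <- function(adj) {
  e0 <- oracle_global_efficiency(adj)
  max(vapply(seq_len(nrow(adj)), function(i) {
    (e0 - oracle_global_efficiency(adj[-i, -i, drop = FALSE])) / e0
  }, numeric(1)))
}

# Newman modularity of a given partition, straight from the definition
# Q = sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m.
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)                      # = 2m for a symmetric 0/1 matrix
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# Zi and Pi straight from the definitions, given adjacency and membership.
oracle_zi_pi <- function(adj, membership) {
  n <- nrow(adj)
  k_own <- vapply(seq_len(n), function(i) {
    sum(adj[i, membership == membership[i]])
  }, numeric(1))
  zi <- vapply(seq_len(n), function(i) {
    mem <- which(membership == membership[i])
    mu <- mean(k_own[mem]); s <- stats::sd(k_own[mem])
    if (is.na(s) || s == 0) 0 else (k_own[i] - mu) / s
  }, numeric(1))
  pi <- vapply(seq_len(n), function(i) {
    ki <- sum(adj[i, ])
    km <- tapply(adj[i, ], membership, sum)
    1 - sum((km / ki)^2)
  }, numeric(1))
  list(zi = zi, pi = pi)
}

# Exact expected attack-tolerance AUC by enumerating all removal orders
# (feasible for n <= 6).
oracle_robustness_exact <- function(adj) {
  n <- nrow(adj)
  orders <- gtools_permutations(n)
  mean(apply(orders, 1, function(ord) {
    alive <- rep(TRUE, n)
    ys <- numeric(n + 1)
    degm <- adj
    ys[1] <- sum(rowSums(degm) > 0) / n
    for (k in seq_len(n)) {
      v <- ord[k]
      alive[v] <- FALSE
      degm[v, ] <- 0; degm[, v] <- 0
      ys[k + 1] <- sum(alive & rowSums(degm) > 0) / n
    }
    sum((ys[-1] + ys[-(n + 1)]) / 2) / n
  }))
}

# all permutations of 1..n as rows (n small)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      row[row >= k] <- row[row >= k] + 1L
      out[r, ] <- c(k, row)
      r <- r + 1
    }
  }
  out
}

# small utility: adjacency matrix of an igraph graph
graph_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# a deterministic toy community table
toy_table <- function() {
  counts <- matrix(
    c(5L, 0L, 3L, 2L,
      0L, 7L, 1L, 0L,
      2L, 2L, 2L, 2L,
      1L, 0L, 0L, 9L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("zotu", 1:4), paste0("s", 1:4)))
  community_table(counts, tibble::tibble(
    sample = paste0("s", 1:4),
    habitat = c("soil", "water", "soil", "water"),
    park = c("p1", "p1", "p2", "p2"), x = c(0, 0, 1, 1), y = 0))
}
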