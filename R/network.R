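#' Build a co-occurrence network from correlations and p-values
#'
#' Keeps edges with `|R| >= r_min` and `p < alpha` (defaults 0.6 / 0.05);
#' nodes left without any edge are dropped. Edge sign is recorded as an
#' attribute; all structural analyses run on the unsigned simple graph.
#'
#' @param correlations,pvalues Conformable symmetric matrices with taxon
#'   dimnames (from [sparcc()] and [edge_pvalues()]).
#' @param annotations Optional tibble with columns `taxon` and any of
#'   `domain`, `niche_class`; copied onto vertices.
#' @param r_min Minimum absolute correlation.
#' @param alpha Maximum p-value (exclusive).
#' @return An `igraph` graph with edge attributes `r`, `p`, `sign`, `weight`
#'   (= `|r|`) and vertex attributes from `annotations`.
#' @export
threshold_network <- function(correlations, pvalues, annotations = NULL,
                              r_min = 0.6, alpha = 0.05) {
  correlations <- as.matrix(correlations); pvalues <- as.matrix(pvalues)
  if (!all(dim(correlations) == dim(pvalues))) {
    abort("Correlation and p-value matrices must be conformable.")
  }
  taxa <- rownames(correlations) %||% paste0("t", seq_len(nrow(correlations)))
  keep <- abs(correlations) >= r_min & pvalues < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    r = correlations[idx], p = pvalues[idx],
    sign = ifelse(correlations[idx] >= 0, "positive", "negative"),
    weight = abs(correlations[idx])
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations)
    pos <- match(igraph::V(g)$name, ann$taxon)
    for (col in setdiff(names(ann), "taxon")) {
      g <- igraph::set_vertex_attr(g, col, value = ann[[col]][pos])
    }
  }
  g
}

#' Greedy modularity optimisation
#'
#' Agglomerative (fast greedy) modularity maximisation on the unsigned,
#' unweighted graph.
#'
#' @param network An `igraph` graph with at least one edge.
#' @return List with `membership` (named integer vector) and `modularity`.
#' @export
greedy_modules <- function(network) {
  if (igraph::ecount(network) == 0) abort("Graph has no edges.")
  cl <- igraph::cluster_fast_greedy(network, weights = NA)
  # cut the merge sequence at the modularity maximum; on ties prefer the
  # most merged state (fewest communities) for a deterministic result
  qs <- cl$modularity
  steps <- max(which(qs >= max(qs) - 1e-12)) - 1L
  mem <- igraph::cut_at(cl, steps = steps)
  names(mem) <- igraph::V(network)$name
  list(membership = mem,
       modularity = igraph::modularity(network, mem))
}

#' Topological properties of a network
#'
#' Node/link counts, positive-edge fraction, average local clustering
#' coefficient (isolated or degree-1 nodes contribute 0), average shortest
#' path distance over connected pairs, greedy modularity, and the R-squared
#' of a least-squares power-law fit of `log(degree frequency)` on
#' `log(degree)`.
#'
#' @param network An `igraph` graph with at least 3 nodes.
#' @return One-row tibble (`n_nodes`, `n_links`, `positive_fraction`,
#'   `avg_cc`, `gd`, `modularity`, `powerlaw_r2`).
#' @export
topo_props <- function(network) {
  if (igraph::vcount(network) < 3) abort("Need at least 3 nodes.")
  deg <- igraph::degree(network)
  avg_cc <- mean(igraph::transitivity(network, type = "local",
                                      isolates = "zero"))
  gd <- igraph::mean_distance(network, directed = FALSE, unconnected = TRUE)
  mod <- if (igraph::ecount(network) > 0) {
    greedy_modules(network)$modularity
  } else NA_real_
  sgn <- igraph::edge_attr(network, "sign")
  pos_frac <- if (is.null(sgn)) NA_real_ else mean(sgn == "positive")
  tab <- table(deg[deg > 0])
  pl_r2 <- if (length(tab) >= 2) {
    fit <- stats::lm(log(as.numeric(tab)) ~ log(as.numeric(names(tab))))
    summary(fit)$r.squared
  } else NA_real_
  tibble(n_nodes = igraph::vcount(network),
         n_links = igraph::ecount(network),
         positive_fraction = pos_frac,
         avg_cc = avg_cc, gd = gd, modularity = mod, powerlaw_r2 = pl_r2)
}

#' Degree-preserving rewired null networks
#'
#' Generates `n_random` degree-preserving randomisations (double-edge swaps,
#' at least `10 * ecount` swap attempts each) and compares the empirical
#' average clustering coefficient and modularity against the null
#' distribution.
#'
#' @param network An `igraph` graph with at least 2 edges.
#' @param n_random Number of rewired replicates.
#' @param seed RNG seed.
#' @return List with `replicates` (tibble of per-replicate `avg_cc`,
#'   `modularity`) and `summary` (tibble: statistic, observed, null mean/sd,
#'   z-score).
#' @export
rewire_null <- function(network, n_random = 100, seed = 1) {
  if (igraph::ecount(network) < 2) abort("Need at least 2 edges to rewire.")
  obs_cc <- mean(igraph::transitivity(network, type = "local",
                                      isolates = "zero"))
  obs_mod <- greedy_modules(network)$modularity
  reps <- with_stream(seed, "rewire", {
    purrr::map(seq_len(n_random), function(b) {
      rg <- igraph::rewire(network, igraph::keeping_degseq(
        niter = 10 * igraph::ecount(network)))
      tibble(replicate = b,
             avg_cc = mean(igraph::transitivity(rg, type = "local",
                                                isolates = "zero")),
             modularity = greedy_modules(rg)$modularity)
    }) |> bind_rows()
  })
  z <- function(obs, nu) {
    s <- stats::sd(nu)
    if (s == 0) return(ifelse(obs == mean(nu), 0, Inf * sign(obs - mean(nu))))
    (obs - mean(nu)) / s
  }
  list(replicates = reps,
       summary = tibble(
         statistic = c("avg_cc", "modularity"),
         observed = c(obs_cc, obs_mod),
         null_mean = c(mean(reps$avg_cc), mean(reps$modularity)),
         null_sd = c(stats::sd(reps$avg_cc), stats::sd(reps$modularity)),
         z = c(z(obs_cc, reps$avg_cc), z(obs_mod, reps$modularity))))
}

#' Write a network as GraphML
#'
#' GraphML export (node annotations and edge attributes included) for use in
#' external viewers such as Gephi or Cytoscape.
#'
#' @param network An `igraph` graph.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
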