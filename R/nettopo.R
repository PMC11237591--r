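#' Within- and among-module connectivity (Zi-Pi) of network nodes
#'
#' `zi` standardises a node's number of links into its own module against
#' the members of that module (`(k_own - mean_own) / sd_own`; 0 when the
#' module's sd is 0); `pi = 1 - sum_m (k_im / k_i)^2` measures how evenly a
#' node's links spread among modules.
#'
#' @param network An `igraph` graph without isolated nodes.
#' @param membership Optional module membership (named integer vector);
#'   computed with [greedy_modules()] when missing.
#' @return Tibble: `taxon`, `module`, `degree`, `zi`, `pi`, `role` (from
#'   [classify_role()]), plus any `niche_class` / `domain` vertex attributes.
#' @export
zi_pi <- function(network, membership = NULL) {
  deg <- igraph::degree(network)
  if (any(deg == 0)) abort("Isolated nodes present; drop them first.")
  membership <- membership %||% greedy_modules(network)$membership
  vnames <- igraph::V(network)$name
  mem <- membership[vnames]
  if (anyNA(mem)) abort("Membership must cover all nodes.")
  adj <- igraph::as_adj_list(network)
  k_own <- vapply(seq_along(vnames), function(i) {
    sum(mem[igraph::V(network)$name[as.integer(adj[[i]])]] == mem[i])
  }, numeric(1))
  # per-module mean/sd of within-module degree
  mu <- tapply(k_own, mem, mean)
  sdv <- tapply(k_own, mem, stats::sd)
  sdv[is.na(sdv) | sdv == 0] <- NA
  zi <- as.numeric(ifelse(is.na(sdv[as.character(mem)]), 0,
                          (k_own - mu[as.character(mem)]) /
                            sdv[as.character(mem)]))
  pi <- vapply(seq_along(vnames), function(i) {
    km <- table(mem[igraph::V(network)$name[as.integer(adj[[i]])]])
    1 - sum((as.numeric(km) / deg[i])^2)
  }, numeric(1))
  out <- tibble(taxon = vnames, module = as.integer(mem),
                degree = as.integer(unname(deg)), zi = zi, pi = pi,
                role = classify_role(zi, pi))
  for (attr in intersect(c("niche_class", "domain"),
                         igraph::vertex_attr_names(network))) {
    out[[attr]] <- igraph::vertex_attr(network, attr)
  }
  out
}

#' Topological role of a node from (Zi, Pi)
#'
#' Network hubs (`zi >= 2.5, pi >= 0.62`), module hubs
#' (`zi >= 2.5, pi < 0.62`), connectors (`zi < 2.5, pi >= 0.62`) and
#' peripherals (the rest); boundaries are inclusive on the hub side.
#'
#' @param zi,pi Numeric vectors.
#' @return Character vector of roles.
#' @export
classify_role <- function(zi, pi) {
  if (any(!is.finite(zi)) || any(!is.finite(pi))) abort("Non-finite Zi/Pi.")
  ifelse(zi >= 2.5 & pi >= 0.62, "network_hub",
         ifelse(zi >= 2.5, "module_hub",
                ifelse(pi >= 0.62, "connector", "peripheral")))
}

#' Keystone taxa per niche class
#'
#' Keystone taxa are the module hubs and connectors (network hubs, which
#' satisfy both criteria, are counted too). Proportions are computed
#' relative to each class's total number of taxa in the community, so
#' classes of different richness are comparable.
#'
#' @param roles Tibble from [zi_pi()] (needs `taxon`, `role`).
#' @param niche_classes Named character vector mapping every community taxon
#'   to its niche class (e.g. `class_strict` from [strict_filter()]).
#' @return Tibble per class: totals, network membership and keystone counts
#'   and proportions.
#' @export
keystone_tally <- function(roles, niche_classes) {
  stopifnot(is.data.frame(roles), !is.null(names(niche_classes)))
  keystone <- roles$taxon[roles$role %in%
                            c("module_hub", "connector", "network_hub")]
  tibble(niche_class = unname(niche_classes),
         taxon = names(niche_classes)) |>
    group_by(.data$niche_class) |>
    summarise(
      n_total = n(),
      n_in_network = sum(.data$taxon %in% roles$taxon),
      n_keystone = sum(.data$taxon %in% keystone),
      prop_in_network = .data$n_in_network / .data$n_total,
      prop_keystone = .data$n_keystone / .data$n_total,
      .groups = "drop")
}

#' Interdomain network of strict generalists and specialists
#'
#' Concatenates the strict generalist/specialist taxa of two domains
#' (opportunists are discarded), runs [sparcc()] and [edge_pvalues()] on the
#' combined table, and thresholds to a network whose nodes carry `domain`
#' and `niche_class` annotations.
#'
#' @param prok_table,euk_table [community_table()]s over identical samples.
#' @param prok_profiles,euk_profiles Classified profiles (after
#'   [strict_filter()]) for each domain.
#' @param r_min,alpha Edge thresholds.
#' @param n_bootstrap Bootstrap resamples for p-values.
#' @param seed RNG seed.
#' @return An `igraph` graph (see [threshold_network()]).
#' @export
interdomain_network <- function(prok_table, euk_table, prok_profiles,
                                euk_profiles, r_min = 0.6, alpha = 0.05,
                                n_bootstrap = 100, seed = 1) {
  stopifnot(inherits(prok_table, "community_table"),
            inherits(euk_table, "community_table"))
  if (!identical(colnames(prok_table$counts), colnames(euk_table$counts))) {
    abort("The two tables must share identical samples (same order).")
  }
  pick <- function(profiles) {
    if (!"class_strict" %in% names(profiles)) {
      abort("Profiles must come from strict_filter().")
    }
    profiles$taxon[profiles$class_strict != "opportunist"]
  }
  ptax <- pick(prok_profiles); etax <- pick(euk_profiles)
  if (length(ptax) == 0 || length(etax) == 0) {
    abort("Each domain needs at least one strict generalist or specialist.")
  }
  pm <- prok_table$counts[ptax, , drop = FALSE]
  em <- euk_table$counts[etax, , drop = FALSE]
  if (length(intersect(rownames(pm), rownames(em))) > 0) {
    rownames(pm) <- paste0("P_", rownames(pm))
    rownames(em) <- paste0("M_", rownames(em))
    ptax2 <- rownames(pm); etax2 <- rownames(em)
  } else {
    ptax2 <- ptax; etax2 <- etax
  }
  combined <- rbind(pm, em)
  ann <- tibble(
    taxon = c(ptax2, etax2),
    domain = rep(c("prokaryote", "microeukaryote"),
                 c(length(ptax2), length(etax2))),
    niche_class = c(
      prok_profiles$class_strict[match(ptax, prok_profiles$taxon)],
      euk_profiles$class_strict[match(etax, euk_profiles$taxon)])
  )
  rho <- sparcc(combined, seed = substream_seed(seed, "interdomain_rho"))
  pv <- edge_pvalues(combined, n_bootstrap = n_bootstrap,
                     seed = substream_seed(seed, "interdomain_p"))
  threshold_network(rho, pv, ann, r_min = r_min, alpha = alpha)
}

#' Random-removal stability experiment
#'
#' Removes a fraction of the nodes of one niche class at random and reports
#' the proportion of taxa remaining in the network, i.e. nodes that still
#' have at least one edge (secondary extinctions of newly isolated nodes
#' count as losses), relative to the original node count.
#'
#' @param network An `igraph` graph with a `niche_class` vertex attribute.
#' @param target Niche class to remove (`"generalist"` or `"specialist"`).
#' @param fraction Fraction of the target class removed (default 0.5).
#' @param reps Number of random repetitions (default 100).
#' @param seed RNG seed.
#' @return One-row tibble: `target`, `fraction`, `reps`, `mean_remaining`,
#'   `sd_remaining`; the per-repetition values are in attribute `values`.
#' @export
removal_experiment <- function(network, target, fraction = 0.5, reps = 100,
                               seed = 1) {
  cls <- igraph::vertex_attr(network, "niche_class")
  if (is.null(cls)) abort("Network lacks a `niche_class` vertex attribute.")
  pool <- which(cls == target)
  if (length(pool) < 1) abort(paste0("No nodes of class ", target, "."))
  n0 <- igraph::vcount(network)
  n_remove <- floor(fraction * length(pool))
  vals <- with_stream(seed, "removal", {
    vapply(seq_len(reps), function(b) {
      drop <- pool[sample.int(length(pool), n_remove)]
      gg <- igraph::delete_vertices(network, drop)
      sum(igraph::degree(gg) > 0) / n0
    }, numeric(1))
  })
  structure(tibble(target = target, fraction = fraction, reps = reps,
                   mean_remaining = mean(vals),
                   sd_remaining = stats::sd(vals)),
            values = vals)
}

global_efficiency <- function(network) {
  d <- igraph::distances(network)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' The maximal relative drop in global efficiency (mean inverse shortest
#' path length over ordered node pairs, 0 for disconnected pairs) caused by
#' removing a single node: `max_i (E - E_-i) / E`.
#'
#' @param network An `igraph` graph with at least 3 nodes.
#' @return Vulnerability in `[0, 1]` (negative contributions are possible
#'   for nodes whose removal increases mean efficiency; the max is reported).
#' @export
vulnerability <- function(network) {
  if (igraph::vcount(network) < 3) abort("Need at least 3 nodes.")
  e0 <- global_efficiency(network)
  if (e0 == 0) abort("Global efficiency is zero (no connected pairs).")
  contrib <- vapply(seq_len(igraph::vcount(network)), function(i) {
    (e0 - global_efficiency(igraph::delete_vertices(network, i))) / e0
  }, numeric(1))
  max(contrib)
}

#' Attack-tolerance robustness
#'
#' Nodes are removed one at a time in random order; after each removal the
#' fraction of the original nodes that survive with at least one edge is
#' recorded, and robustness is the area under this attack-tolerance curve
#' (trapezoidal, over removed fraction 0..1), averaged over `reps` random
#' orders. 0.5 is the upper bound reached by perfectly tolerant networks.
#'
#' @param network An `igraph` graph with at least 2 nodes.
#' @param reps Random removal orders.
#' @param seed RNG seed.
#' @return Mean area under the curve, in `[0, 1]`.
#' @export
robustness <- function(network, reps = 100, seed = 1) {
  n <- igraph::vcount(network)
  if (n < 2) abort("Need at least 2 nodes.")
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  with_stream(seed, "robustness", {
    mean(vapply(seq_len(reps), function(b) {
      robustness_curve_auc(adj, sample.int(n))
    }, numeric(1)))
  })
}

# One removal order -> AUC of the surviving (degree >= 1) fraction curve.
robustness_curve_auc <- function(adj, order) {
  n <- length(adj)
  deg <- vapply(adj, length, integer(1))
  alive <- rep(TRUE, n)
  connected <- sum(deg > 0)
  ys <- numeric(n + 1)
  ys[1] <- connected / n
  for (k in seq_len(n)) {
    v <- order[k]
    if (alive[v]) {
      if (deg[v] > 0) connected <- connected - 1
      alive[v] <- FALSE
      for (u in adj[[v]]) {
        if (alive[u]) {
          deg[u] <- deg[u] - 1
          if (deg[u] == 0) connected <- connected - 1
        }
      }
      deg[v] <- 0
    }
    ys[k + 1] <- connected / n
  }
  sum((ys[-1] + ys[-(n + 1)]) / 2) / n
}

bipartite_profiles <- function(network, side) {
  dom <- igraph::vertex_attr(network, "domain")
  if (is.null(dom)) abort("Network lacks a `domain` vertex attribute.")
  other <- setdiff(unique(dom), side)
  if (length(other) != 1) abort("Need exactly two domains for a bipartite view.")
  vn <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network)
  partners <- lapply(which(dom == side), function(i) {
    nb <- as.integer(adj[[i]])
    vn[nb[dom[nb] == other]]
  })
  names(partners) <- vn[dom == side]
  partners[vapply(partners, length, integer(1)) > 0]
}

#' Functional complementarity of a bipartite interdomain network
#'
#' Same-side nodes are compared by the Jaccard distance of their
#' cross-domain partner sets, clustered by average linkage, and the total
#' branch length of the resulting dendrogram is returned (0 when fewer than
#' two nodes have partners). Larger values mean the side's species interact
#' with more complementary (less redundant) sets of partners.
#'
#' @param network An interdomain `igraph` graph with a `domain` vertex
#'   attribute.
#' @param side Which side's dendrogram to measure; `"both"` sums the two.
#' @return Total dendrogram branch length (>= 0).
#' @export
functional_complementarity <- function(network,
                                       side = c("both", "prokaryote",
                                                "microeukaryote")) {
  side <- match.arg(side)
  if (side == "both") {
    return(functional_complementarity(network, "prokaryote") +
             functional_complementarity(network, "microeukaryote"))
  }
  partners <- bipartite_profiles(network, side)
  if (length(partners) < 2) return(0)
  n <- length(partners)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- partners[[i]]; b <- partners[[j]]
      d[i, j] <- d[j, i] <- 1 - length(intersect(a, b)) / length(union(a, b))
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  sum(ape::as.phylo(hc)$edge.length)
}

#' Mean niche overlap of a bipartite interdomain network
#'
#' Average pairwise similarity of the cross-domain interaction profiles of
#' same-side nodes (Morisita-Horn, which for binary partner sets reduces to
#' `2 |A intersect B| / (|A| + |B|)`). 1 when all nodes share identical
#' partner sets, 0 when all are disjoint.
#'
#' @inheritParams functional_complementarity
#' @return Mean overlap in `[0, 1]` (`NA` if no side has two connected
#'   nodes).
#' @export
niche_overlap <- function(network,
                          side = c("both", "prokaryote", "microeukaryote")) {
  side <- match.arg(side)
  if (side == "both") {
    vals <- c(niche_overlap_side(network, "prokaryote"),
              niche_overlap_side(network, "microeukaryote"))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    return(mean(vals))
  }
  niche_overlap_side(network, side)
}

niche_overlap_side <- function(network, side) {
  partners <- bipartite_profiles(network, side)
  if (length(partners) < 2) return(NA_real_)
  n <- length(partners)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- partners[[i]]; b <- partners[[j]]
      vals <- c(vals, 2 * length(intersect(a, b)) / (length(a) + length(b)))
    }
  }
  mean(vals)
}
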