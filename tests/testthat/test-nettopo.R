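two_clique_bridge <- function() {
  # two 4-cliques joined by one bridge edge a1-b1
  g <- igraph::disjoint_union(
    igraph::make_full_graph(4), igraph::make_full_graph(4))
  igraph::V(g)$name <- c(paste0("a", 1:4), paste0("b", 1:4))
  igraph::add_edges(g, c(1, 5))
}

test_that("Zi and Pi follow their definitions", {
  g <- two_clique_bridge()
  mem <- c(a1 = 1, a2 = 1, a3 = 1, a4 = 1, b1 = 2, b2 = 2, b3 = 2, b4 = 2)
  zp <- zi_pi(g, mem)
  # all links inside the own module -> pi = 0
  expect_equal(zp$pi[zp$taxon == "a2"], 0, tolerance = 1e-12)
  # a1 has 3 links in, 1 out of 4 total: pi = 1 - (3/4)^2 - (1/4)^2
  expect_equal(zp$pi[zp$taxon == "a1"], 1 - (3 / 4)^2 - (1 / 4)^2,
               tolerance = 1e-12)
  # within-module degrees are all 3 -> sd 0 -> zi = 0
  expect_true(all(zp$zi == 0))
  # against the brute-force definition on a richer graph
  withr::with_seed(4, h <- igraph::sample_gnp(12, 0.4))
  igraph::V(h)$name <- paste0("v", 1:12)
  h <- igraph::delete_vertices(h, which(igraph::degree(h) == 0))
  memh <- greedy_modules(h)$membership
  zph <- zi_pi(h, memh)
  oz <- oracle_zi_pi(graph_adj(h), memh[igraph::V(h)$name])
  expect_equal(zph$zi, oz$zi, tolerance = 1e-12)
  expect_equal(zph$pi, oz$pi, tolerance = 1e-12)
})

test_that("node with links split evenly across two modules has pi = 0.5", {
  g <- igraph::make_graph(~ x - a, x - b)
  mem <- c(x = 1, a = 1, b = 2)
  zp <- zi_pi(g, mem)
  expect_equal(zp$pi[zp$taxon == "x"], 0.5, tolerance = 1e-12)
})

test_that("roles partition the Zi-Pi plane with inclusive hub boundaries", {
  expect_identical(classify_role(3.0, 0.10), "module_hub")
  expect_identical(classify_role(1.0, 0.70), "connector")
  expect_identical(classify_role(2.5, 0.62), "network_hub")
  expect_identical(classify_role(2.49, 0.61), "peripheral")
  grid <- expand.grid(zi = seq(-1, 4, by = 0.5), pi = seq(0, 1, by = 0.1))
  roles <- classify_role(grid$zi, grid$pi)
  expect_true(all(roles %in% c("network_hub", "module_hub", "connector",
                               "peripheral")))
  expect_error(classify_role(NA, 0.5), "finite")
})

test_that("keystone tallies report class-relative proportions", {
  roles <- tibble::tibble(taxon = c("s1", "s2", "g1", "o1"),
                          role = c("module_hub", "connector", "peripheral",
                                   "network_hub"))
  classes <- c(s1 = "specialist", s2 = "specialist", s3 = "specialist",
               s4 = "specialist", s5 = "specialist", s6 = "specialist",
               s7 = "specialist", s8 = "specialist", s9 = "specialist",
               s10 = "specialist", g1 = "generalist", o1 = "opportunist")
  kt <- keystone_tally(roles, classes)
  expect_equal(kt$prop_keystone[kt$niche_class == "specialist"], 0.2)
  expect_equal(kt$n_keystone[kt$niche_class == "generalist"], 0)
  expect_equal(kt$n_keystone[kt$niche_class == "opportunist"], 1)
})

test_that("removal experiments match their definitions", {
  # star: removing the hub isolates every leaf
  star <- igraph::make_star(8, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:8)
  igraph::V(star)$niche_class <- c("generalist", rep("specialist", 7))
  out <- removal_experiment(star, "generalist", fraction = 1, reps = 5,
                            seed = 1)
  expect_equal(out$mean_remaining, 0)
  expect_equal(out$sd_remaining, 0)

  # removing half a clique leaves the rest fully connected
  cl <- igraph::make_full_graph(10)
  igraph::V(cl)$name <- paste0("v", 1:10)
  igraph::V(cl)$niche_class <- "specialist"
  out2 <- removal_experiment(cl, "specialist", fraction = 0.5, reps = 10,
                             seed = 2)
  expect_equal(out2$mean_remaining, 0.5)

  # fraction 0 removes nothing
  out0 <- removal_experiment(cl, "specialist", fraction = 0, reps = 3,
                             seed = 3)
  expect_equal(out0$mean_remaining, 1)
  expect_error(removal_experiment(cl, "generalist"), "No nodes")
})

test_that("removal means equal a same-seed independent re-simulation", {
  g <- two_clique_bridge()
  igraph::V(g)$niche_class <- rep(c("generalist", "specialist"), each = 4)
  out <- removal_experiment(g, "specialist", fraction = 0.5, reps = 100,
                            seed = 21)
  pool <- which(igraph::V(g)$niche_class == "specialist")
  adj <- graph_adj(g)
  vals <- withr::with_seed(habgen:::substream_seed(21, "removal"), {
    vapply(1:100, function(b) {
      drop <- pool[sample.int(length(pool), 2)]
      sub <- adj[-drop, -drop]
      sum(rowSums(sub) > 0) / nrow(adj)
    }, numeric(1))
  })
  expect_equal(out$mean_remaining, mean(vals), tolerance = 1e-12)
  expect_equal(out$sd_remaining, stats::sd(vals), tolerance = 1e-12)
})

test_that("vulnerability matches hand values and the brute-force oracle", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- paste0("v", 1:4)
  expect_equal(vulnerability(k4), 0, tolerance = 1e-12)
  path3 <- igraph::make_graph(~ a - b, b - c)
  # E = (4 * 1 + 2 * 1/2) / 6 = 5/6; removing b leaves no edges: E = 0
  expect_equal(vulnerability(path3), 1, tolerance = 1e-12)
  withr::with_seed(17, {
    for (i in 1:5) {
      g <- igraph::sample_gnp(sample(5:12, 1), 0.4)
      igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
      if (igraph::ecount(g) == 0) next
      expect_equal(vulnerability(g), oracle_vulnerability(graph_adj(g)),
                   tolerance = 1e-12)
    }
  })
})

test_that("bypassing an articulation point lowers vulnerability", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  triangle <- igraph::add_edges(path3, c(1, 3))  # a-c closes the cycle
  expect_gt(vulnerability(path3), vulnerability(triangle))
})

test_that("robustness matches exact enumeration and ranks topologies", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- paste0("v", 1:4)
  exact <- oracle_robustness_exact(graph_adj(k4))
  est <- robustness(k4, reps = 2000, seed = 5)
  expect_lt(abs(est - exact), 0.02)
  expect_identical(robustness(k4, reps = 50, seed = 8),
                   robustness(k4, reps = 50, seed = 8))
  # a star collapses faster than a clique of equal size
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  k6 <- igraph::make_full_graph(6); igraph::V(k6)$name <- paste0("v", 1:6)
  expect_lt(robustness(star, reps = 1000, seed = 3),
            robustness(k6, reps = 1000, seed = 3))
})

interdomain_toy <- function() {
  g <- igraph::make_graph(~ p1 - m1, p1 - m2, p2 - m1, p2 - m2, p3 - m3)
  igraph::V(g)$domain <- ifelse(startsWith(igraph::V(g)$name, "p"),
                                "prokaryote", "microeukaryote")
  g
}

test_that("functional complementarity totals dendrogram branch lengths", {
  g <- interdomain_toy()
  # prokaryote side: p1 and p2 share {m1, m2} (distance 0), p3 disjoint
  # (distance 1). Average linkage: merge p1,p2 at 0, then p3 at 1;
  # as a tree: branches 0, 0 (first merge) and 0.5, 0.5 (to the root)
  expect_equal(functional_complementarity(g, side = "prokaryote"), 1,
               tolerance = 1e-12)
  # microeukaryote side mirrors it
  expect_equal(functional_complementarity(g, side = "microeukaryote"), 1,
               tolerance = 1e-12)
  expect_equal(functional_complementarity(g), 2, tolerance = 1e-12)
  # identical partner sets contribute zero branch length
  g2 <- igraph::make_graph(~ p1 - m1, p2 - m1)
  igraph::V(g2)$domain <- c("prokaryote", "microeukaryote", "prokaryote")
  expect_equal(functional_complementarity(g2, side = "prokaryote"), 0,
               tolerance = 1e-12)
})

test_that("niche overlap averages partner-profile similarities", {
  g <- interdomain_toy()
  # prokaryote pairs: (p1,p2) share both partners -> 1; (p1,p3), (p2,p3)
  # disjoint -> 0; mean = 1/3
  expect_equal(niche_overlap(g, side = "prokaryote"), 1 / 3,
               tolerance = 1e-12)
  g2 <- igraph::make_graph(~ p1 - m1, p2 - m1)
  igraph::V(g2)$domain <- c("prokaryote", "microeukaryote", "prokaryote")
  expect_equal(niche_overlap(g2, side = "prokaryote"), 1, tolerance = 1e-12)
})

test_that("interdomain networks keep only strict taxa and recover a planted
          cross-domain edge", {
  cm <- diag(12)
  cm[1, 7] <- cm[7, 1] <- 0.9    # taxon 1 (prok) coupled to taxon 7 (euk)
  tab <- generate_correlated_compositions(cm, 150, 4000, seed = 13)
  prok <- community_table(tab$counts[1:6, ], tab$metadata)
  euk <- community_table(tab$counts[7:12, ], tab$metadata)
  mk_prof <- function(taxa, strict) {
    tibble::tibble(taxon = taxa,
                   class_strict = ifelse(strict, "specialist", "opportunist"))
  }
  pp <- mk_prof(rownames(prok$counts), c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                         FALSE))
  ep <- mk_prof(rownames(euk$counts), c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                        FALSE))
  g <- interdomain_network(prok, euk, pp, ep, n_bootstrap = 60, seed = 3)
  # opportunists never appear
  expect_false(any(c("taxon05", "taxon06", "taxon11", "taxon12") %in%
                     igraph::V(g)$name))
  # node labels partition into domain x class
  expect_setequal(unique(igraph::V(g)$domain),
                  c("prokaryote", "microeukaryote"))
  expect_true(all(igraph::V(g)$niche_class %in%
                    c("generalist", "specialist")))
  # the planted coupled pair is recovered
  edges <- igraph::as_data_frame(g)
  hit <- any((edges$from == "taxon01" & edges$to == "taxon07") |
               (edges$from == "taxon07" & edges$to == "taxon01"))
  expect_true(hit)
  expect_error(
    interdomain_network(prok, community_table(euk$counts[, 1:10],
                                              euk$metadata[1:10, ]), pp, ep),
    "identical samples")
})
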