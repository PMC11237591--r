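toy_tree <- function() ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")

test_that("beta-MNTD matches hand computation on a 4-tip tree", {
  tree <- toy_tree()
  # patristic distances: AB 3, AD 4.5, CB 6.5, CD 2
  x <- c(A = 2, C = 1)
  y <- c(B = 1, D = 3)
  # x-side: A (w 2/3) nearest in y = B at 3; C (w 1/3) nearest = D at 2
  # y-side: B (w 1/4) nearest in x = A at 3; D (w 3/4) nearest = C at 2
  manual <- ((2 / 3) * 3 + (1 / 3) * 2 + (1 / 4) * 3 + (3 / 4) * 2) / 2
  expect_equal(beta_mntd(x, y, tree), manual, tolerance = 1e-12)
  # identical communities: every taxon's nearest neighbour is itself
  expect_equal(beta_mntd(x, x, tree), 0, tolerance = 1e-12)
  # two singleton communities at patristic distance d
  expect_equal(beta_mntd(c(A = 5), c(D = 1), tree), 4.5, tolerance = 1e-12)
  expect_error(beta_mntd(c(Z = 1), y, tree), "absent")
})

test_that("beta-MNTD agrees with picante", {
  set.seed(9)
  tree <- ape::rtree(10)
  m <- matrix(rpois(20, 3), 2, 10,
              dimnames = list(c("c1", "c2"), tree$tip.label))
  m[1, 1] <- m[2, 2] <- 5  # ensure both non-empty
  ref <- as.matrix(picante::comdistnt(m, stats::cophenetic(tree),
                                      abundance.weighted = TRUE))
  expect_equal(beta_mntd(m[1, ], m[2, ], tree), ref["c1", "c2"],
               tolerance = 1e-10)
})

test_that("betaNTI is seeded, symmetric and guards degenerate nulls", {
  set.seed(2)
  tree <- ape::rtree(20)
  x <- stats::setNames(rpois(20, 2), tree$tip.label)
  y <- stats::setNames(rpois(20, 2), tree$tip.label)
  x[x == 0][1] <- 1; y[y == 0][1] <- 1
  b1 <- bnti(x, y, tree, n_null = 199, seed = 5)
  expect_identical(b1, bnti(x, y, tree, n_null = 199, seed = 5))
  expect_equal(b1, bnti(y, x, tree, n_null = 199, seed = 5),
               tolerance = 1e-12)
  expect_error(bnti(x, y, tree, n_null = 50), "n_null")
  # star phylogeny: all pairwise distances equal -> zero null variance
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_error(bnti(c(A = 1, B = 1), c(C = 1, D = 1), star, n_null = 99),
               "variance")
})

test_that("Raup-Crick equals an independent reimplementation per seed", {
  x <- c(z1 = 10, z2 = 5, z3 = 0, z4 = 2, z5 = 0)
  y <- c(z1 = 0, z2 = 6, z3 = 7, z4 = 0, z5 = 1)
  n_null <- 199
  got <- rc_bray(x, y, n_null = n_null, seed = 11)

  # oracle: same documented null-draw sequence, coded independently
  taxa <- union(names(x)[x > 0], names(y)[y > 0])
  xm <- ym <- stats::setNames(numeric(length(taxa)), taxa)
  xm[names(x)[x > 0]] <- x[x > 0]; ym[names(y)[y > 0]] <- y[y > 0]
  occ <- (xm > 0) + (ym > 0)
  rel <- (xm / sum(xm) + ym / sum(ym)) / 2
  bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
  obs <- bc(xm, ym)
  draw <- function(rich, total) {
    sp <- sample(seq_along(taxa), rich, prob = occ)
    cnt <- stats::setNames(numeric(length(taxa)), taxa)
    cnt[sp] <- 1
    if (total > rich) {
      cnt[sp] <- cnt[sp] + stats::rmultinom(1, total - rich, rel[sp])[, 1]
    }
    cnt
  }
  nulls <- withr::with_seed(habgen:::substream_seed(11, "rc_bray"), {
    vapply(seq_len(n_null), function(b) {
      bc(draw(sum(x > 0), sum(x)), draw(sum(y > 0), sum(y)))
    }, numeric(1))
  })
  manual <- (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null * 2 - 1
  expect_equal(got, manual, tolerance = 1e-12)
  expect_gte(got, -1); expect_lte(got, 1)
})

test_that("Raup-Crick hits -1 when the observed pair is maximally similar", {
  # an identical pair has observed BC = 0; with a 6-taxon pool and 1000
  # individuals per null community, null dissimilarities are > 0 (a tie
  # would need two independent draws to coincide exactly)
  x <- c(z1 = 500, z2 = 500)
  occ <- stats::setNames(rep(1, 6), paste0("z", 1:6))
  rel <- stats::setNames(rep(1 / 6, 6), paste0("z", 1:6))
  rc <- rc_bray(x, x, n_null = 99, occupancy = occ, rel_abund = rel,
                seed = 3)
  expect_equal(rc, -1, tolerance = 1e-12)
  expect_error(rc_bray(c(z1 = 0), c(z1 = 0), n_null = 99), "Empty")
})

test_that("assembly processes follow the two-stage decision rules exactly", {
  expect_identical(classify_process(-2.5, 0.99), "homogeneous_selection")
  expect_identical(classify_process(2.5, -0.99), "heterogeneous_selection")
  expect_identical(classify_process(0.5, 0.97), "dispersal_limitation")
  expect_identical(classify_process(0.5, -0.97), "homogenizing_dispersal")
  expect_identical(classify_process(1.0, 0.2), "drift")
  # boundary values fall through to the next rule (strict inequalities)
  expect_identical(classify_process(-2, -0.99), "homogenizing_dispersal")
  expect_identical(classify_process(2, 0.99), "dispersal_limitation")
  expect_identical(classify_process(0, 0.95), "drift")
  expect_identical(classify_process(0, -0.95), "drift")
  expect_identical(classify_process(2, 0.95), "drift")
  expect_error(classify_process(NA, 1), "finite")
})

test_that("assembly summaries count exactly and sum to one", {
  pairs <- tibble::tibble(
    group = "all",
    process = c("homogeneous_selection", "homogeneous_selection",
                "drift", "dispersal_limitation"))
  s <- summarize_assembly(pairs)
  expect_equal(s$fraction[s$process == "homogeneous_selection"], 0.5)
  expect_equal(s$fraction[s$process == "drift"], 0.25)
  expect_equal(s$fraction[s$process == "dispersal_limitation"], 0.25)
  expect_identical(sum(s$fraction), 1)
  expect_equal(unique(s$deterministic), 0.5)
  expect_equal(unique(s$stochastic), 0.5)

  all_drift <- tibble::tibble(group = "g", process = rep("drift", 7))
  s2 <- summarize_assembly(all_drift)
  expect_identical(unique(s2$stochastic), 1)

  # exactness property across random compositions
  withr::with_seed(6, {
    for (i in 1:20) {
      pr <- tibble::tibble(
        group = sample(c("a", "b"), 37, TRUE),
        process = sample(habgen:::assembly_processes, 37, TRUE))
      ss <- summarize_assembly(pr)
      for (g in unique(ss$group)) {
        expect_identical(sum(ss$fraction[ss$group == g]), 1)
      }
    }
  })
})

test_that("per-pair assembly tables classify consistently", {
  d <- synthetic_design(n_taxa = 40, n_parks = 2, replicates = 2,
                        depth = 600, seed = 14)
  g <- generate_community(d)
  tree <- generate_bd_tree(40, 1, 0, seed = 4)
  tree$tip.label <- rownames(g$table$counts)
  pairs <- assembly_pairs(g$table, tree, n_null = 99, seed = 2)
  expect_true(all(pairs$process == classify_process(pairs$bnti, pairs$rc)))
  expect_true(all(table(pairs$group) == choose(4, 2)))
  # reruns identical
  pairs2 <- assembly_pairs(g$table, tree, n_null = 99, seed = 2)
  expect_identical(pairs, pairs2)
})
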