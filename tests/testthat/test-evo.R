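eq_pars <- function(la, mu, q) {
  c(lambda_g = la, lambda_s = la, mu_g = mu, mu_s = mu, q_gs = q, q_sg = q)
}

test_that("equal-rate likelihood factorises into birth-death times Mk2", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      tr <- generate_bd_tree(n, 1, runif(1, 0, 0.5), seed = 300 + i)
      states <- stats::setNames(
        sample(c("generalist", "specialist"), n, TRUE), tr$tip.label)
      la <- runif(1, 0.5, 2); mu <- runif(1, 0, 0.4); q <- runif(1, 0.05, 0.5)
      for (root in c("equal", "weighted")) {
        expect_equal(
          bisse_loglik(tr, states, eq_pars(la, mu, q), root = root,
                       tol = 1e-10),
          oracle_bd_mk2(tr, states, la, mu, q, root),
          tolerance = 1e-6)
      }
    }
  })
})

test_that("likelihood is invariant to child order and continuous in short
          branches", {
  s <- simulate_bisse(c(lambda_g = 1, lambda_s = 1.6, mu_g = 0.1,
                        mu_s = 0.2, q_gs = 0.2, q_sg = 0.1), 25, seed = 6)
  pars <- c(lambda_g = 1, lambda_s = 1.6, mu_g = 0.1, mu_s = 0.2,
            q_gs = 0.2, q_sg = 0.1)
  ll <- bisse_loglik(s$tree, s$states, pars)
  rot <- ape::ladderize(s$tree, right = FALSE)
  expect_equal(bisse_loglik(rot, s$states, pars), ll, tolerance = 1e-7)

  # a cherry with shrinking branch lengths approaches the instantaneous
  # speciation limit smoothly
  lls <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", eps, eps))
    bisse_loglik(tr, c(A = "generalist", B = "generalist"), pars)
  }, numeric(1))
  expect_lt(abs(lls[2] - lls[3]), abs(lls[1] - lls[2]) + 1e-6)
  expect_true(all(is.finite(lls)))
})

test_that("likelihood input validation works", {
  tr <- generate_bd_tree(5, 1, 0, seed = 2)
  states <- stats::setNames(rep("generalist", 5), tr$tip.label)
  expect_error(bisse_loglik(tr, states[1:3], eq_pars(1, 0, 0.1)),
               "without a state")
  expect_error(bisse_loglik(tr, states, c(lambda_g = 1)), "named")
  bad <- eq_pars(1, 0, 0.1); bad["mu_g"] <- -1
  expect_error(bisse_loglik(tr, states, bad), ">= 0")
  utr <- ape::unroot(ape::rtree(5))
  expect_error(bisse_loglik(utr, stats::setNames(rep(0, 5), utr$tip.label),
                            eq_pars(1, 0, 0.1)), "rooted")
})

test_that("the full fit never undercuts the constrained fit", {
  for (i in 1:3) {
    s <- simulate_bisse(c(lambda_g = 1, lambda_s = 2, mu_g = 0.1,
                          mu_s = 0.1, q_gs = 0.4, q_sg = 0.4), 60,
                        seed = 40 + i)
    f <- bisse_fit(s$tree, s$states, n_starts = 2, seed = i)
    expect_gte(f$loglik_full, f$loglik_constrained)
    expect_gte(f$chi2_stat, 0)
    expect_equal(f$chi2_stat, 2 * (f$loglik_full - f$loglik_constrained),
                 tolerance = 1e-10)
    expect_true(all(f$rates >= 0))
  }
  s <- simulate_bisse(eq_pars(1, 0.1, 0.2), 30, seed = 77)
  expect_error(bisse_fit(s$tree, stats::setNames(
    rep("generalist", 30), s$tree$tip.label)), "Both states")
})

test_that("the fitted rates sit at a local likelihood maximum", {
  s <- simulate_bisse(c(lambda_g = 1, lambda_s = 2.5, mu_g = 0.1,
                        mu_s = 0.1, q_gs = 0.1, q_sg = 0.1), 120, seed = 9)
  f <- bisse_fit(s$tree, s$states, seed = 2)
  ll0 <- bisse_loglik(s$tree, s$states, f$rates)
  expect_equal(ll0, f$loglik_full, tolerance = 1e-6)
  for (k in seq_along(f$rates)) {
    for (fac in c(0.8, 1.25)) {
      pert <- f$rates
      pert[k] <- pert[k] * fac + 1e-8
      expect_lte(bisse_loglik(s$tree, s$states, pert), ll0 + 1e-6)
    }
  }
})

test_that("simulate + fit round-trip brackets the true speciation rates", {
  true <- c(lambda_g = 1, lambda_s = 2, mu_g = 0.1, mu_s = 0.1,
            q_gs = 0.15, q_sg = 0.15)
  est <- vapply(1:20, function(i) {
    s <- simulate_bisse(true, 150, seed = 500 + i)
    f <- bisse_fit(s$tree, s$states, n_starts = 1, seed = i)
    c(f$rates["lambda_g"], f$rates["lambda_s"])
  }, numeric(2))
  expect_gte(true["lambda_g"], stats::quantile(est[1, ], 0.05))
  expect_lte(true["lambda_g"], stats::quantile(est[1, ], 0.95))
  expect_gte(true["lambda_s"], stats::quantile(est[2, ], 0.05))
  expect_lte(true["lambda_s"], stats::quantile(est[2, ], 0.95))
})

test_that("diversification potential is exact arithmetic", {
  expect_equal(diversification_potential(2.0, 0.5, 1.0), 1.5,
               tolerance = 1e-12)
  expect_equal(diversification_potential(1.3, 0, 1.3), 0, tolerance = 1e-12)
  expect_equal(dp_ratio(4.5, 0.3), 15, tolerance = 1e-12)
  expect_error(dp_ratio(1, 0), "undefined")
  expect_error(diversification_potential(-1, 0, 0), ">= 0")
})

test_that("root-to-tip lengths are path sums with group comparison", {
  tr <- ape::read.tree(text = "(A:1,(B:0.2,C:0.6):0.5);")
  d <- root_to_tip_lengths(tr)
  expect_equal(d$distance[d$tip == "A"], 1, tolerance = 1e-12)
  expect_equal(d$distance[d$tip == "B"], 0.7, tolerance = 1e-12)
  expect_equal(d$distance[d$tip == "C"], 1.1, tolerance = 1e-12)
  # ultrametric tree: all distances equal
  ut <- generate_bd_tree(12, 1, 0, seed = 3)
  du <- root_to_tip_lengths(ut)
  expect_lt(diff(range(du$distance)), 1e-8)
  # group comparison on a tree whose specialists carry longer paths
  tr2 <- ape::read.tree(
    text = "((g1:0.1,g2:0.2):0.1,((s1:1,s2:1.2):0.5,s3:2):0.1);")
  states <- c(g1 = "generalist", g2 = "generalist", s1 = "specialist",
              s2 = "specialist", s3 = "specialist")
  cmp <- root_to_tip_compare(tr2, states)
  expect_gt(cmp$median_specialist, cmp$median_generalist)
  expect_lt(cmp$p_value, 0.2)
})
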