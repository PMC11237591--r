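test_that("niche-breadth indices match their closed forms", {
  expect_equal(levins_breadth(rep(0.2, 5)), 5, tolerance = 1e-12)
  expect_equal(levins_breadth(c(1, 0, 0, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(levins_breadth(c(0.5, 0.25, 0.25, 0, 0)), 1 / 0.375,
               tolerance = 1e-12)
  expect_equal(shannon_breadth(rep(0.2, 5)), log(5), tolerance = 1e-12)
  expect_equal(shannon_breadth(c(1, 0, 0, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(shannon_breadth(c(0.5, 0.5, 0, 0, 0)), log(2),
               tolerance = 1e-12)
  x <- c(rep(1, 45), rep(0, 45))
  expect_equal(occurrence_frequency(x), 0.5, tolerance = 1e-12)
  expect_equal(occurrence_frequency(rep(2, 90)), 1, tolerance = 1e-12)
  expect_equal(occurrence_frequency(c(1, rep(0, 89))), 1 / 90,
               tolerance = 1e-12)
  expect_error(levins_breadth(c(0, 0, 0)), "absent")
  expect_error(shannon_breadth(c(0.2, 0.2)), "sum to 1")
})

test_that("indices are invariant under habitat relabeling and monotone", {
  p <- c(0.4, 0.3, 0.2, 0.1, 0)
  for (i in 1:5) {
    pp <- sample(p)
    expect_equal(levins_breadth(pp), levins_breadth(p))
    expect_equal(shannon_breadth(pp), shannon_breadth(p))
  }
  # maximal at uniform shares, minimal at a point mass
  expect_lt(levins_breadth(p), levins_breadth(rep(0.2, 5)))
  expect_gt(levins_breadth(p), levins_breadth(c(1, 0, 0, 0, 0)))
  expect_lt(shannon_breadth(p), shannon_breadth(rep(0.2, 5)))
  expect_gt(shannon_breadth(p), shannon_breadth(c(1, 0, 0, 0, 0)))
})

test_that("habitat shares average within habitats before normalising", {
  tab <- toy_table()
  sh <- habitat_shares(tab)
  expect_true(all(abs(rowSums(sh) - 1) < 1e-12))
  # hand computation for zotu1: relative abundances (5/8, 0/9, 3/6, 2/13)
  rel <- c(5 / 8, 0 / 9, 3 / 6, 2 / 13)
  soil <- mean(rel[c(1, 3)]); water <- mean(rel[c(2, 4)])
  expect_equal(unname(sh["zotu1", c("soil", "water")]),
               c(soil, water) / (soil + water), tolerance = 1e-12)
})

test_that("the null classifier recovers planted labels on a small design", {
  d <- synthetic_design(n_taxa = 150, n_parks = 4, replicates = 2,
                        depth = 3000, seed = 21)
  g <- generate_community(d)
  tab <- filter_min_reads(g$table, 10)
  prof <- null_classify(tab, n_perm = 200, seed = 7)
  truth <- g$truth$label[match(prof$taxon, g$truth$taxon)]
  truth[truth == "background"] <- "opportunist"
  recall <- vapply(c("generalist", "specialist", "opportunist"),
                   function(k) mean(prof$class[truth == k] == k), numeric(1))
  expect_gt(recall["generalist"], 0.7)
  expect_gt(recall["specialist"], 0.7)
  expect_gt(recall["opportunist"], 0.85)
  # classes partition the taxa
  expect_true(all(prof$class %in% c("generalist", "specialist",
                                    "opportunist")))
  expect_equal(nrow(prof), nrow(tab$counts))
})

test_that("the classifier is reproducible and validates n_perm", {
  tab <- filter_min_reads(generate_community(
    synthetic_design(n_taxa = 40, n_parks = 2, replicates = 2, depth = 400,
                     seed = 2))$table, 1)
  p1 <- null_classify(tab, n_perm = 100, seed = 3)
  p2 <- null_classify(tab, n_perm = 100, seed = 3)
  expect_identical(p1$class, p2$class)
  expect_identical(p1$levins_hi, p2$levins_hi)
  expect_error(null_classify(tab, n_perm = 99), "n_perm")
})

test_that("strict filtering applies the read and percentile rules", {
  prof <- tibble::tibble(
    taxon = paste0("z", 1:24),
    total_reads = c(50L, 51L, rep(500L, 22)),
    levins_b = c(1, 1, seq(2, 4.8, length.out = 20), 4.9, 4.95),
    shannon_h = c(0, 0, seq(0.5, 1.5, length.out = 20), 1.6, 1.61),
    occ_f = c(0.1, 0.1, seq(0.3, 0.9, length.out = 20), 0.5, 0.95),
    class = c("specialist", "specialist", rep("generalist", 22)))
  out <- strict_filter(prof)
  # specialist with exactly 50 reads is excluded; 51 retained
  expect_false(out$strict_specialist[1])
  expect_true(out$strict_specialist[2])
  # taxon 23: top decile on B and H but median occupancy -> excluded
  expect_false(out$strict_generalist[23])
  # taxon 24: top decile on all three -> retained
  expect_true(out$strict_generalist[24])
  # strict sets are subsets of their classes
  expect_true(all(out$class[out$strict_generalist] == "generalist"))
  expect_true(all(out$class[out$strict_specialist] == "specialist"))
  expect_true(all(out$class_strict[!out$strict_generalist &
                                     !out$strict_specialist] == "opportunist"))
})

test_that("strict generalists equal a brute-force percentile intersection", {
  withr::with_seed(3, {
    n <- 20
    prof <- tibble::tibble(
      taxon = paste0("g", 1:n),
      total_reads = 1000L,
      levins_b = runif(n, 3, 5),
      shannon_h = runif(n, 1, 1.6),
      occ_f = runif(n, 0.5, 1),
      class = "generalist")
  })
  out <- strict_filter(prof)
  q <- function(v) stats::quantile(v, 0.9, names = FALSE)
  manual <- prof$levins_b >= q(prof$levins_b) &
    prof$shannon_h >= q(prof$shannon_h) & prof$occ_f >= q(prof$occ_f)
  expect_identical(out$strict_generalist, manual)
  # no generalists -> empty strict set, not an error
  prof2 <- prof; prof2$class <- "opportunist"
  expect_false(any(strict_filter(prof2)$strict_generalist))
})
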