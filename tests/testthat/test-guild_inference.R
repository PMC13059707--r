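test_that("network edges require strict |r| and p thresholds", {
  r <- matrix(c(1, 0.6, 0.5, 0.6, 1, -0.7, 0.5, -0.7, 1), 3, 3)
  p <- matrix(c(0, 0.01, 0.001, 0.01, 0, 0.04, 0.001, 0.04, 0), 3, 3)
  rm <- fake_rmcorr(r, p)
  abund <- matrix(0.25, 4, 3, dimnames = list(paste0("s", 1:4),
                                              rm$feature_ids))
  net <- build_network(rm, abund)
  # f1-f2 (r=0.6): edge; f1-f3 (r=0.5 exactly): no edge; f2-f3: negative edge
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$feature_a, net$edges$feature_b),
                  c("f1 f2", "f2 f3"))
  expect_equal(net$edges$sign[net$edges$feature_a == "f1"], "positive")
  expect_equal(net$edges$sign[net$edges$feature_b == "f3"], "negative")
  # degenerate features never form edges
  rm2 <- fake_rmcorr(r, p, degenerate = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(build_network(rm2, abund)$edges), 0)
})

test_that("edge set equals a brute-force threshold scan on simulated data", {
  sim <- simulate_community(small_scenario(seed = 31))
  rel <- to_relative(sim$counts)
  rm <- rmcorr_matrix(log_transform(rel), subject = sim$metadata$donor)
  net <- build_network(rm, rel, r_threshold = 0.5, p_threshold = 0.05)
  want <- 0
  ids <- rm$feature_ids
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    if (abs(rm$r[i, j]) > 0.5 && rm$p[i, j] < 0.05 &&
        !rm$degenerate[i] && !rm$degenerate[j]) want <- want + 1
  }
  expect_equal(nrow(net$edges), want)
  expect_false(any(net$edges$feature_a == net$edges$feature_b))
})

test_that("correlation distance is 1 - r with degenerate pairs at 1", {
  r <- matrix(c(1, 1, -1, 0, 1, 1, 0.5, 0, -1, 0.5, 1, 0, 0, 0, 0, 1), 4, 4)
  p <- matrix(0.5, 4, 4); diag(p) <- 0
  rm <- fake_rmcorr(r, p)
  d <- correlation_distance(rm)
  expect_equal(unname(d[1, 2]), 0)
  expect_equal(unname(d[1, 3]), 2)
  expect_equal(unname(d[1, 4]), 1)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("Ward tree separates planted blocks and merges monotonically", {
  bd <- block_distance(c(6, 5), seed = 41)
  tree <- ward_tree(bd$d)
  expect_equal(length(tree$labels), 11)
  expect_false(is.unsorted(tree$height))  # Ward merge heights non-decreasing
  top <- stats::cutree(tree, k = 2)
  expect_equal(adjusted_rand_index(top, bd$labels[names(top)]), 1)
  # deterministic under permuted input order (lexicographic tie-break)
  perm <- sample(nrow(bd$d))
  tree2 <- ward_tree(bd$d[perm, perm])
  expect_identical(stats::cutree(tree2, k = 2)[names(top)], top)
})

test_that("sequential PERMANOVA cut recovers planted blocks and keeps homogeneous ones whole", {
  bd <- block_distance(c(8, 7), seed = 42)
  tree <- ward_tree(bd$d)
  ga <- cut_tree_permanova(tree, bd$d, n_perm = 9999, alpha = 0.001, seed = 1)
  expect_equal(length(unique(ga$assignment)), 2)
  expect_equal(adjusted_rand_index(ga$assignment, bd$labels[names(ga$assignment)]), 1)
  # every feature assigned to exactly one guild, partitioning the leaves
  expect_setequal(names(ga$assignment), tree$labels)
  # one homogeneous block: i.i.d. distances around a common value -> 1 guild.
  # At this size every 2-group split is enumerated exhaustively, so the
  # minimum attainable p (1/choose(12,6) = 1/924) exceeds alpha and no
  # noise split can be accepted.
  n <- 12
  ids <- sprintf("h%02d", 1:n)
  d1 <- withr::with_seed(43, {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    v <- stats::runif(n * (n - 1) / 2, 0.45, 0.55)
    m[upper.tri(m)] <- v
    m + t(m)
  })
  ga1 <- cut_tree_permanova(ward_tree(d1), d1, n_perm = 9999, alpha = 0.001,
                            seed = 2)
  expect_equal(length(unique(ga1$assignment)), 1)
  # study defaults
  expect_equal(formals(cut_tree_permanova)$n_perm, 9999)
  expect_equal(formals(cut_tree_permanova)$alpha, 0.001)
  expect_error(cut_tree_permanova(tree, d1), "do not match")
})

test_that("guild count is monotone non-increasing as alpha tightens", {
  sim <- simulate_community(small_scenario(seed = 51))
  rel <- to_relative(sim$counts)
  rm <- rmcorr_matrix(log_transform(rel), subject = sim$metadata$donor)
  d <- correlation_distance(rm)
  tree <- ward_tree(d)
  k <- vapply(c(0.05, 0.01, 0.001), function(a) {
    ga <- cut_tree_permanova(tree, d, n_perm = 1999, alpha = a, seed = 3)
    length(unique(ga$assignment))
  }, numeric(1))
  expect_true(all(diff(k) <= 0))
})

test_that("the guild pipeline is seed-reproducible end to end", {
  run <- function() {
    sim <- simulate_community(small_scenario(seed = 61))
    rel <- to_relative(sim$counts)
    rm <- rmcorr_matrix(log_transform(rel), subject = sim$metadata$donor)
    d <- correlation_distance(rm)
    cut_tree_permanova(ward_tree(d), d, n_perm = 499, alpha = 0.01,
                       seed = 4, abund = rel)$assignment
  }
  expect_identical(run(), run())
})

test_that("guild aggregation sums members and conserves abundance", {
  abund <- matrix(c(0.1, 0.3, 0.6,
                    0.5, 0.25, 0.25), 2, 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  ga <- c(f1 = "CAG1", f2 = "CAG1", f3 = "CAG2")
  gt <- aggregate_guilds(abund, ga)
  expect_equal(gt[, "CAG1"], c(s1 = 0.4, s2 = 0.75))
  expect_equal(gt[, "CAG2"], c(s1 = 0.6, s2 = 0.25))
  expect_equal(rowSums(gt), rowSums(abund))  # conservation
  # singleton guild column equals the member feature column
  expect_equal(unname(gt[, "CAG2"]), unname(abund[, "f3"]))
  # columns ordered by descending overall abundance
  expect_true(all(diff(colMeans(gt)) <= 0))
  expect_error(aggregate_guilds(abund[, 1:2], ga), "missing.*f3")
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(71)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
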