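test_that("Bray-Curtis matches hand computations and conventions", {
  x <- rbind(s1 = c(2, 2), s2 = c(1, 3), s3 = c(2, 2), s4 = c(0, 5))
  d <- bray_curtis(x)
  expect_equal(unname(d["s1", "s2"]), 0.25)  # (1+1)/(3+5)
  expect_equal(unname(d["s1", "s3"]), 0)     # identical samples
  y <- rbind(a = c(1, 0), b = c(0, 2), z = c(0, 0), z2 = c(0, 0))
  dy <- bray_curtis(y)
  expect_equal(unname(dy["a", "b"]), 1)      # disjoint supports
  expect_equal(unname(dy["z", "z2"]), 0)     # double-zero convention
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(12)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(x))
  ord <- pcoa(d)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-9)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)  # reconstruction
  # collinear points: one informative axis, line recovered up to sign
  line <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  dl <- as.matrix(dist(line))
  ol <- pcoa(dl)
  expect_equal(sum(ol$eigenvalues > 1e-8 * max(ol$eigenvalues)), 1)
  expect_equal(unname(abs(diff(ol$coordinates[c("a", "c"), 1]))), 3,
               tolerance = 1e-10)
  # duplicated sample lands on identical coordinates
  d2 <- as.matrix(dist(rbind(x, s11 = x[1, ])))
  o2 <- pcoa(d2)
  expect_lt(max(abs(o2$coordinates["s11", ] - o2$coordinates["s1", ])), 1e-8)
  expect_error(pcoa(dl[1:2, 1:2]), ">= 3 samples")
})

test_that("aPCoA removes planted covariate variation and keeps orthogonal effects", {
  set.seed(13)
  n_per <- 20
  donor <- factor(rep(c("d1", "d2", "d3"), each = n_per))
  trt <- factor(rep(rep(c("A", "B"), each = n_per / 2), 3))
  x <- matrix(rnorm(3 * n_per * 4, sd = 0.5), 3 * n_per, 4)
  x <- x + 5 * model.matrix(~donor - 1) %*% matrix(rnorm(12), 3, 4)  # donor shift
  x <- x + 1.5 * (trt == "B") %o% c(1, -1, 0.5, 0)                   # treatment
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  d <- as.matrix(dist(x))
  # single-level covariate reduces to plain PCoA
  ord0 <- pcoa(d)
  ord1 <- apcoa(d, rep("all", nrow(x)))
  expect_equal(as.matrix(dist(ord1$coordinates[, 1:3])),
               as.matrix(dist(ord0$coordinates[, 1:3])), tolerance = 1e-8)
  # donor R^2 on the first two adjusted axes collapses
  adj <- apcoa(d, donor)
  d_adj <- as.matrix(dist(adj$coordinates[, 1:2]))
  r2_donor_adj <- permanova(d_adj, donor, n_perm = 19, seed = 1)$R2
  r2_donor_raw <- permanova(as.matrix(dist(ord0$coordinates[, 1:2])), donor,
                            n_perm = 19, seed = 1)$R2
  expect_lt(r2_donor_adj, 0.01)
  expect_lt(r2_donor_adj, r2_donor_raw)
  # treatment separation survives adjustment in this balanced design
  r2_trt_adj <- permanova(d_adj, trt, n_perm = 19, seed = 1)$R2
  r2_trt_raw <- permanova(d, trt, n_perm = 19, seed = 1)$R2
  expect_gt(r2_trt_adj, 0.5 * r2_trt_raw)
  expect_error(apcoa(d, factor(seq_len(nrow(x)))), "confounded")
})

test_that("PERMANOVA p equals exhaustive enumeration on 6-sample instances", {
  set.seed(14)
  for (rep in 1:20) {
    D <- random_euclid_dist(6)
    groups <- factor(rep(c("a", "b"), each = 3))
    fit <- permanova(D, groups, n_perm = 999)
    expect_equal(fit$method, "exact")
    expect_equal(fit$n_perm, 20)  # 6!/(3!3!)
    sets <- utils::combn(6, 3)
    f_all <- apply(sets, 2, function(s) {
      g <- rep("b", 6); g[s] <- "a"; naive_F(D, g)
    })
    expect_equal(fit$F, naive_F(D, as.character(groups)), tolerance = 1e-10)
    expect_equal(fit$p, mean(f_all >= fit$F - 1e-9), tolerance = 1e-12)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  set.seed(15)
  D <- random_euclid_dist(24)
  groups <- factor(rep(c("a", "b", "c"), each = 8))
  fit <- permanova(D, groups, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ groups, permutations = 99)
  expect_equal(fit$F, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("maximal separation attains the permutation floor", {
  x <- rbind(matrix(rnorm(45, 0, 0.01), 15), matrix(rnorm(45, 50, 0.01), 15))
  rownames(x) <- paste0("s", 1:30)
  fit <- permanova(as.matrix(dist(x)), factor(rep(1:2, each = 15)),
                   n_perm = 999, seed = 3)
  expect_equal(fit$method, "sampled")
  expect_equal(fit$p, 1 / 1000)
})

test_that("stratified permutations never cross donor blocks", {
  strata <- factor(rep(c("d1", "d2", "d3"), times = c(4, 6, 5)))
  for (i in 1:200) {
    perm <- guildflow:::.permute_within_strata(15, strata)
    expect_identical(as.character(strata[perm]), as.character(strata))
  }
  # a stratum with a single group is flagged
  D <- random_euclid_dist(8)
  g <- factor(c("a", "a", "b", "b", "a", "a", "a", "a"))
  s <- factor(rep(c("x", "y"), each = 4))
  expect_warning(permanova(D, g, n_perm = 19, strata = s, seed = 1),
                 "permutation freedom")
})

test_that("pairwise PERMANOVA adjusts across pairs by BH", {
  set.seed(16)
  x <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 3), 10),
             matrix(rnorm(40, 6), 10))
  rownames(x) <- paste0("s", 1:30)
  D <- as.matrix(dist(x))
  g3 <- factor(rep(c("a", "b", "c"), each = 10))
  tab <- pairwise_permanova(D, g3, n_perm = 99, seed = 4)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
  expect_true(all(tab$q >= tab$p))
  # two groups: single pair, q = p
  tab2 <- pairwise_permanova(D[1:20, 1:20], droplevels(g3[1:20]),
                             n_perm = 99, seed = 4)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$q, tab2$p)
  expect_equal(formals(pairwise_permanova)$n_perm, 999)
})

test_that("Procrustes recovers exact superimposability and ranks concordance", {
  set.seed(17)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 3 * X %*% R + 5
  rownames(Y) <- rownames(X)
  pr <- procrustes_protest(X, Y, n_perm = 99, seed = 5)
  expect_lt(pr$m2, 1e-12)
  expect_equal(pr$correlation, sqrt(1 - pr$m2), tolerance = 1e-6)
  # unrelated configurations are not spuriously significant at the floor
  Z <- matrix(rnorm(40), 20, 2, dimnames = dimnames(X))
  pz <- procrustes_protest(X, Z, n_perm = 99, seed = 6)
  expect_gt(pz$m2, 0.1)
  expect_error(procrustes_protest(X, Z[1:10, ], n_perm = 9), "same samples")
})
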