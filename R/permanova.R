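# Internal: within/total sums of squares from a squared-distance matrix.
# SS_total = sum_{i<j} d_ij^2 / N ; SS_within = sum_g sum_{i<j in g} d^2 / n_g
.permanova_F <- function(D2, groups) {
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = f, R2 = ss_between / ss_total)
}

# Internal: F statistics for B permuted label vectors, vectorized.
# P is an n x B matrix of permuted sample indices; column b induces labels
# groups[P[, b]].
.permanova_F_batch <- function(D2, groups, P) {
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  lab <- matrix(as.integer(groups)[P], nrow(P), ncol(P))
  ss_within <- 0
  for (g in seq_len(a)) {
    U <- (lab == g) * 1
    ng <- sum(groups == levels(groups)[g])
    ss_within <- ss_within + colSums(U * (D2 %*% U)) / (2 * ng)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Internal: one permutation of 1:n restricted to strata blocks.
.permute_within_strata <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  out <- seq_len(n)
  for (b in levels(factor(strata))) {
    idx <- which(strata == b)
    if (length(idx) > 1) out[idx] <- idx[sample.int(length(idx))]
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from a distance matrix: `F = (SS_between / (a - 1)) /
#' (SS_within / (N - a))`, with sums of squares from squared inter-point
#' distances. Significance is assessed by permuting group labels, restricted
#' within `strata` blocks when given (labels never move across blocks), with
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' For two groups without strata, when the number of distinct label
#' assignments `choose(N, n1)` does not exceed `n_perm`, the permutation
#' distribution is enumerated completely and `p = #\{F >= F_obs\} / B` over
#' all `B` assignments (the observed one included).
#'
#' @param d distance matrix or `dist`.
#' @param groups group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of permutations (default 999).
#' @param strata optional blocking factor for restricted permutations.
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `permanova_result`: `F`, `R2`, `p`, `n_perm`
#'   (permutations actually used), `method` (`"exact"` or `"sampled"`),
#'   `groups`, `strata`.
#' @export
permanova <- function(d, groups, n_perm = 999, strata = NULL, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (!is.null(strata)) {
    strata <- factor(strata)
    if (length(strata) != n) stop("strata length must match distance matrix")
    single <- tapply(groups, strata, function(g) length(unique(g)) == 1)
    if (any(single))
      warning("stratum with a single group contributes no permutation freedom: ",
              paste(names(single)[single], collapse = ", "))
  }
  D2 <- D^2
  obs <- .permanova_F(D2, groups)

  exact_possible <- is.null(strata) && nlevels(groups) == 2 &&
    choose(n, sum(groups == levels(groups)[1])) <= n_perm
  if (exact_possible) {
    idx1 <- which(groups == levels(groups)[1])
    idx2 <- which(groups == levels(groups)[2])
    sets <- utils::combn(n, length(idx1))
    B <- ncol(sets)
    P <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      P[sets[, b], b] <- idx1
      P[-sets[, b], b] <- idx2
    }
    f_all <- .permanova_F_batch(D2, groups, P)
    p <- mean(f_all >= obs["F"] - 1e-12)
    method <- "exact"; used <- B
  } else {
    draw <- function() {
      P <- matrix(0L, n, n_perm)
      for (b in seq_len(n_perm)) P[, b] <- .permute_within_strata(n, strata)
      P
    }
    P <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    f_perm <- .permanova_F_batch(D2, groups, P)
    p <- (1 + sum(f_perm >= obs["F"] - 1e-12)) / (1 + n_perm)
    method <- "sampled"; used <- n_perm
  }
  structure(list(F = unname(obs["F"]), R2 = unname(obs["R2"]), p = p,
                 n_perm = used, method = method, groups = groups,
                 strata = strata),
            class = "permanova_result")
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs [permanova()] on every pair of group levels (subject-stratified when
#' `strata` is given) and adjusts the p-values across pairs by BH.
#'
#' @param d distance matrix or `dist`.
#' @param groups group labels.
#' @param n_perm permutations per pair (default 999, the study's pairwise
#'   setting).
#' @param strata optional blocking factor (donor).
#' @param seed optional integer seed.
#' @return data.frame with `group_a`, `group_b`, `F`, `R2`, `p`, `q`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, strata = NULL,
                               seed = NULL) {
  D <- as.matrix(d)
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- groups %in% pairs[, i]
    sub_strata <- if (is.null(strata)) NULL else factor(strata[keep])
    fit <- permanova(D[keep, keep, drop = FALSE], droplevels(groups[keep]),
                     n_perm = n_perm, strata = sub_strata,
                     seed = if (is.null(seed)) NULL else seed + i)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               F = fit$F, R2 = fit$R2, p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
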