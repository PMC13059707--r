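#' Build the co-abundance network
#'
#' Edges are feature pairs whose repeated-measures correlation passes both
#' thresholds strictly (`|r| > r_threshold` and `p < p_threshold`, the
#' network convention of the study's Fig. 3A-style display). Degenerate
#' pairs never form edges. Node weight is the feature's mean relative
#' abundance.
#'
#' @param rm an `rmcorr_matrix`.
#' @param abund samples x features relative-abundance matrix covering the
#'   rmcorr features.
#' @param r_threshold absolute correlation threshold (default 0.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @return list of class `coabundance_network`: `nodes` (feature_id,
#'   mean_abundance), `edges` (feature_a, feature_b, r, p, sign).
#' @export
build_network <- function(rm, abund, r_threshold = 0.5, p_threshold = 0.05) {
  stopifnot(inherits(rm, "rmcorr_matrix"))
  ids <- rm$feature_ids
  if (!all(ids %in% colnames(abund)))
    stop("abundance table missing rmcorr feature(s): ",
         paste(setdiff(ids, colnames(abund)), collapse = ", "))
  nodes <- data.frame(feature_id = ids,
                      mean_abundance = colMeans(abund[, ids, drop = FALSE]),
                      stringsAsFactors = FALSE, row.names = NULL)
  idx <- which(upper.tri(rm$r), arr.ind = TRUE)
  r <- rm$r[idx]; p <- rm$p[idx]
  degen <- rm$degenerate[idx[, 1]] | rm$degenerate[idx[, 2]]
  keep <- !degen & abs(r) > r_threshold & p < p_threshold
  edges <- data.frame(feature_a = ids[idx[keep, 1]],
                      feature_b = ids[idx[keep, 2]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "coabundance_network")
}

#' Write a co-abundance network
#'
#' Edge list as TSV and, optionally, GraphML (loadable in Cytoscape).
#'
#' @param net a `coabundance_network`.
#' @param edge_path TSV output path for the edge list.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  stopifnot(inherits(net, "coabundance_network"))
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

#' 1 - correlation distance from an rmcorr matrix
#'
#' `d = 1 - r`, in `[0, 2]`, zero diagonal. Pairs involving a degenerate
#' feature have r treated as 0, hence distance 1.
#'
#' @param rm an `rmcorr_matrix`.
#' @return symmetric distance matrix with feature dimnames.
#' @export
correlation_distance <- function(rm) {
  stopifnot(inherits(rm, "rmcorr_matrix"))
  d <- 1 - rm$r
  diag(d) <- 0
  d
}

#' Ward linkage tree of the correlation distance
#'
#' Ward's minimum-variance hierarchical clustering (`ward.D2`) on the
#' precomputed distances. Features are ordered lexicographically first so the
#' tree is deterministic regardless of input column order.
#'
#' @param d feature x feature distance matrix.
#' @return an `hclust` object.
#' @export
ward_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need >= 2 features")
  ord <- order(rownames(d))
  stats::hclust(stats::as.dist(d[ord, ord]), method = "ward.D2")
}

#' Write a linkage tree as Newick
#' @param tree `hclust` object.
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# leaves under each node of an hclust merge table; nodes indexed as in
# `merge` (negative = leaf, positive = prior merge row)
.hclust_leaves <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  expand <- function(node) {
    if (node < 0) tree$labels[-node] else members[[node]]
  }
  for (i in seq_len(n - 1))
    members[[i]] <- c(expand(tree$merge[i, 1]), expand(tree$merge[i, 2]))
  members
}

#' Delimit guilds by sequential top-down PERMANOVA
#'
#' Walks the Ward tree from the root. At each internal node whose two child
#' clades both hold at least `min_clade` features, a PERMANOVA is run with
#' features as observations, the node's restriction of `d` as the distance,
#' and child membership as the grouping; if `p < alpha` the split is accepted
#' and both children are visited, otherwise the node's leaf set becomes one
#' guild. A split with a child smaller than `min_clade` is untestable
#' (PERMANOVA is undefined for a group of one) and is never accepted: the
#' node's leaf set terminates as one guild without testing. The result is a
#' total partition of the leaves in which every boundary was supported by a
#' significant test.
#'
#' Per-node permutation streams are seeded deterministically from `seed`, so
#' the same inputs and seed give the same partition at any `alpha`.
#'
#' @param tree `hclust` from [ward_tree()].
#' @param d the same distance matrix the tree was built from.
#' @param n_perm permutations per node test (study default 9,999).
#' @param alpha split acceptance threshold (study default 0.001).
#' @param min_clade smallest testable clade (default 2).
#' @param seed integer seed for the permutation streams.
#' @param abund optional samples x features relative-abundance matrix; when
#'   given, guilds are labelled `CAG1..CAGn` by descending total abundance,
#'   otherwise in tree order.
#' @return list of class `guild_assignment`: `assignment` (named character,
#'   feature -> guild id), `node_tests` (per tested node: size of each
#'   child, F, p, accepted), `tree`.
#' @export
cut_tree_permanova <- function(tree, d, n_perm = 9999, alpha = 0.001,
                               min_clade = 2, seed = 1L, abund = NULL) {
  d <- as.matrix(d)
  if (!setequal(tree$labels, rownames(d)))
    stop("tree labels and distance matrix ids do not match")
  members <- .hclust_leaves(tree)
  guilds <- list()
  tests <- list()
  node_leaves <- function(node) {
    if (node < 0) tree$labels[-node] else members[[node]]
  }
  visit <- function(node) {
    if (node < 0) {  # leaf
      guilds[[length(guilds) + 1]] <<- tree$labels[-node]
      return(invisible())
    }
    ch <- tree$merge[node, ]
    l1 <- node_leaves(ch[1]); l2 <- node_leaves(ch[2])
    leaves <- c(l1, l2)
    if (min(length(l1), length(l2)) < min_clade) {
      # untestable split: no evidence to divide, keep the clade whole
      guilds[[length(guilds) + 1]] <<- leaves
      return(invisible())
    }
    grp <- factor(rep(c("left", "right"), c(length(l1), length(l2))))
    fit <- permanova(d[leaves, leaves], grp, n_perm = n_perm,
                     seed = seed + node)
    accepted <- fit$p < alpha
    tests[[length(tests) + 1]] <<- data.frame(
      node = node, n_left = length(l1), n_right = length(l2),
      F = fit$F, p = fit$p, accepted = accepted)
    if (accepted) { visit(ch[1]); visit(ch[2]) }
    else guilds[[length(guilds) + 1]] <<- leaves
    invisible()
  }
  visit(nrow(tree$merge))

  ord <- seq_along(guilds)
  if (!is.null(abund)) {
    tot <- vapply(guilds, function(g)
      sum(colMeans(abund[, g, drop = FALSE])), numeric(1))
    ord <- order(tot, decreasing = TRUE)
  }
  assignment <- character(0)
  for (i in seq_along(ord)) {
    g <- guilds[[ord[i]]]
    assignment[g] <- paste0("CAG", i)
  }
  structure(list(assignment = assignment,
                 node_tests = if (length(tests)) do.call(rbind, tests)
                              else data.frame(),
                 tree = tree),
            class = "guild_assignment")
}

#' Aggregate feature abundances into guild abundances
#'
#' Guild abundance is the per-sample sum over member features; guild columns
#' are ordered by descending overall abundance.
#'
#' @param abund samples x features relative-abundance matrix.
#' @param ga a `guild_assignment` (or a named feature -> guild character
#'   vector).
#' @return samples x guilds matrix.
#' @export
aggregate_guilds <- function(abund, ga) {
  assignment <- if (inherits(ga, "guild_assignment")) ga$assignment else ga
  missing_feat <- setdiff(names(assignment), colnames(abund))
  if (length(missing_feat) > 0)
    stop("guild member feature(s) missing from abundance table: ",
         paste(missing_feat, collapse = ", "))
  guild_ids <- unique(assignment)
  gt <- vapply(guild_ids, function(g) {
    rowSums(abund[, names(assignment)[assignment == g], drop = FALSE])
  }, numeric(nrow(abund)))
  gt <- matrix(gt, nrow = nrow(abund),
               dimnames = list(rownames(abund), guild_ids))
  gt[, order(colMeans(gt), decreasing = TRUE), drop = FALSE]
}

#' Write a guild assignment as TSV
#' @param ga `guild_assignment`.
#' @param path output path.
#' @export
write_guild_assignment <- function(ga, path) {
  assignment <- if (inherits(ga, "guild_assignment")) ga$assignment else ga
  utils::write.table(
    data.frame(feature_id = names(assignment), guild = unname(assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
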