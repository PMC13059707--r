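#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features; bounded in
#' `[0, 1]`. A pair of all-zero samples is assigned distance 0 by convention.
#'
#' @param x samples x features non-negative abundance matrix.
#' @return symmetric distance matrix with sample dimnames.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative input")
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  d[!is.finite(d)] <- 0  # double-zero samples
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# Gower-centered matrix G = J (-0.5 d^2) J with J = I - 11'/n
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# eigendecomposition shared by pcoa/apcoa: keep axes with eigenvalue
# > 1e-8 * max, scale eigenvectors by sqrt(eigenvalue)
.ordinate_eigen <- function(G, sample_ids) {
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  vals <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), sum(pos))
  rownames(coords) <- sample_ids
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 proportion_explained = vals / sum(e$values[e$values > 0])),
            class = "ordination")
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2` followed by
#' eigendecomposition. Negative eigenvalues (Bray-Curtis is non-Euclidean)
#' are dropped without correction; proportion explained is relative to the
#' positive-eigenvalue total.
#'
#' @param d distance matrix or `dist` (>= 3 samples).
#' @return list of class `ordination`: `coordinates` (samples x axes, ordered
#'   by descending eigenvalue), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) < 3) stop("PCoA requires >= 3 samples")
  .ordinate_eigen(.gower_center(D), rownames(D))
}

#' Covariate-adjusted PCoA (aPCoA)
#'
#' Projects nuisance-covariate variation (here, donor) out of the
#' Gower-centered matrix before eigendecomposition: with `H` the
#' residual-maker of the covariate's indicator design (with intercept), the
#' adjusted matrix `H G H` is decomposed as in [pcoa()]. With a single-level
#' covariate `H` reduces to the centering matrix and the result equals plain
#' PCoA.
#'
#' @param d distance matrix or `dist`.
#' @param covariate factor aligned with the samples of `d` (>= 2 samples per
#'   level overall; one sample per level is confounded and rejected).
#' @return an `ordination`.
#' @export
apcoa <- function(d, covariate) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("aPCoA requires >= 3 samples")
  covariate <- factor(covariate)
  if (length(covariate) != n) stop("covariate length must match samples")
  if (nlevels(covariate) == n)
    stop("covariate has one sample per level: confounded with all variation")
  X <- if (nlevels(covariate) == 1) matrix(1, n, 1)
       else stats::model.matrix(~covariate)
  H <- diag(n) - X %*% solve(crossprod(X), t(X))
  G <- .gower_center(D)
  .ordinate_eigen(H %*% G %*% H, rownames(D))
}

#' Procrustes superimposition with PROTEST significance
#'
#' Optimal translation, rotation and uniform scaling of ordination `y` onto
#' `x` (symmetric scaling), minimizing the residual `m^2`; PROTEST assesses
#' `m^2` against a row-permutation null. By default the first two axes are
#' compared, matching plotted ordinations.
#'
#' @param x,y `ordination` objects (or coordinate matrices) over the same
#'   samples; rows are aligned by name.
#' @param n_perm PROTEST permutations (default 999).
#' @param seed optional integer seed.
#' @param n_axes number of leading axes to compare (default 2); `Inf` uses
#'   all shared axes.
#' @return list of class `procrustes_result`: `m2`, `correlation`
#'   (`sqrt(1 - m2)`), `p`, `n_perm`.
#' @export
procrustes_protest <- function(x, y, n_perm = 999, seed = NULL, n_axes = 2) {
  cx <- if (inherits(x, "ordination")) x$coordinates else as.matrix(x)
  cy <- if (inherits(y, "ordination")) y$coordinates else as.matrix(y)
  if (is.null(rownames(cx)) || is.null(rownames(cy)))
    stop("coordinates must have sample rownames")
  if (!setequal(rownames(cx), rownames(cy)))
    stop("x and y must cover the same samples")
  cy <- cy[rownames(cx), , drop = FALSE]
  k <- min(n_axes, ncol(cx), ncol(cy))
  if (k < 1) stop("rank-0 configuration")
  cx <- cx[, seq_len(k), drop = FALSE]
  cy <- cy[, seq_len(k), drop = FALSE]
  run <- function() vegan::protest(cx, cy, permutations = n_perm,
                                   symmetric = TRUE)
  pr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(m2 = pr$ss, correlation = pr$t0, p = pr$signif,
                 n_perm = n_perm),
            class = "procrustes_result")
}

#' Write ordination coordinates as TSV
#' @param ord `ordination`.
#' @param path output path.
#' @export
write_ordination <- function(ord, path) {
  out <- data.frame(sample_id = rownames(ord$coordinates),
                    ord$coordinates, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
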