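#' Repeated-measures correlation of one feature pair
#'
#' Bland-Altman repeated-measures correlation: both variables are centered
#' within subject (subject means removed), and r is the Pearson correlation
#' of the centered values. This removes between-subject variation so r
#' reflects the common within-subject association. Significance uses
#' `t = r * sqrt(df / (1 - r^2))` with `df = N - k - 1` (N observations, k
#' subjects), two-sided.
#'
#' If x or y has zero within-subject variance the correlation is undefined;
#' the pair is flagged degenerate and returned as `r = 0`, `p = 1`.
#'
#' @param x,y numeric vectors of equal length.
#' @param subject subject (donor) labels, one per observation; >= 2 subjects.
#' @return list with `r`, `p`, `df`, `degenerate`.
#' @export
rmcorr_pair <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject))
    stop("x, y and subject must have equal length")
  subject <- factor(subject)
  k <- nlevels(subject)
  n <- length(x)
  if (k < 2) stop("at least 2 subjects required")
  if (n - k < 3) stop("need at least 3 observations beyond the subject count")
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  df <- n - k - 1
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx < .Machine$double.eps * n || sy < .Machine$double.eps * n)
    return(list(r = 0, p = 1, df = df, degenerate = TRUE))
  r <- sum(xc * yc) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, df = df, degenerate = FALSE)
}

#' All-pairs repeated-measures correlation matrix
#'
#' Computes [rmcorr_pair()] for every pair of columns. Columns are centered
#' within subject once, after which the pairwise r matrix is the Pearson
#' correlation matrix of the centered data, so the computation is a single
#' cross-product. Degenerate columns (no within-subject variance) get r = 0
#' and p = 1 against every partner.
#'
#' @param x samples x features numeric matrix (typically log relative
#'   abundance).
#' @param subject subject label per sample (donor).
#' @return list of class `rmcorr_matrix`: `feature_ids`, `r`, `p`
#'   (symmetric matrices), `df`, `degenerate` (logical per feature).
#' @export
rmcorr_matrix <- function(x, subject) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  subject <- factor(subject)
  n <- nrow(x); k <- nlevels(subject)
  if (k < 2) stop("at least 2 subjects required")
  df <- n - k - 1
  xc <- apply(x, 2, function(col) col - ave(col, subject))
  ss <- colSums(xc^2)
  degen <- ss < .Machine$double.eps * n
  sdv <- sqrt(ss)
  sdv[degen] <- 1  # avoid division by zero; overwritten below
  r <- crossprod(sweep(xc, 2, sdv, "/"))
  r[r > 1] <- 1; r[r < -1] <- -1
  r[degen, ] <- 0; r[, degen] <- 0
  diag(r) <- 1
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p[abs(r) >= 1] <- 0
  p[degen, ] <- 1; p[, degen] <- 1
  diag(p) <- 0
  ids <- colnames(x)
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  structure(list(feature_ids = ids, r = r, p = p, df = df,
                 degenerate = stats::setNames(degen, ids)),
            class = "rmcorr_matrix")
}

#' Write an rmcorr matrix as a long-format TSV
#'
#' One row per unordered feature pair: `feature_a`, `feature_b`, `r`, `p`,
#' `degenerate_flag`.
#'
#' @param rm an `rmcorr_matrix`.
#' @param path output path.
#' @export
write_rmcorr <- function(rm, path) {
  stopifnot(inherits(rm, "rmcorr_matrix"))
  idx <- which(upper.tri(rm$r), arr.ind = TRUE)
  out <- data.frame(feature_a = rm$feature_ids[idx[, 1]],
                    feature_b = rm$feature_ids[idx[, 2]],
                    r = rm$r[idx], p = rm$p[idx],
                    degenerate_flag = rm$degenerate[idx[, 1]] |
                      rm$degenerate[idx[, 2]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
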