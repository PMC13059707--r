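#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' semantics, as in QIIME) to exactly `depth` reads. Samples with fewer total
#' reads than `depth` are dropped with a message rather than an error, since
#' batch designs tolerate occasional shallow samples.
#'
#' @param counts samples x features count matrix.
#' @param depth target depth; the study default is 28,000 reads per sample.
#' @param seed integer seed for the subsampling.
#' @return rarefied count matrix (possibly with fewer samples), with dropped
#'   sample ids in attribute `"dropped_samples"`.
#' @export
rarefy <- function(counts, depth = 28000, seed = 1L) {
  counts <- validate_count_table(counts)
  if (depth <= 0) stop("depth must be > 0")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  if (any(!keep))
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(rownames(counts)[!keep], collapse = ", "))
  kept <- counts[keep, , drop = FALSE]
  out <- withr::with_seed(seed, {
    t(apply(kept, 1, function(x) {
      if (sum(x) == depth) return(x)
      drawn <- sample(rep.int(seq_along(x), x), depth, replace = FALSE)
      tabulate(drawn, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(kept)
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- rownames(counts)[!keep]
  out
}

#' Filter features by prevalence
#'
#' Keeps features present (count > 0) in strictly more than `min_prevalence`
#' of the samples, following the ">30% prevalence" convention; prevalence is
#' evaluated globally across all samples.
#'
#' @param counts samples x features count matrix.
#' @param min_prevalence fraction in `[0, 1)`; default 0.30.
#' @return filtered count matrix with attribute `"coverage"`, the fraction of
#'   total reads retained.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.30) {
  counts <- validate_count_table(counts)
  if (min_prevalence < 0 || min_prevalence >= 1)
    stop("min_prevalence must be in [0, 1)")
  prev <- colMeans(counts > 0)
  keep <- prev > min_prevalence
  if (!any(keep)) stop("no features pass the prevalence filter")
  out <- counts[, keep, drop = FALSE]
  attr(out, "coverage") <- sum(out) / sum(counts)
  out
}

#' Convert counts to relative abundance
#'
#' @param counts samples x features matrix.
#' @return matrix of fractions; each sample row sums to 1 unless its total
#'   was zero (left at zero).
#' @export
to_relative <- function(counts) {
  if (any(counts < 0)) stop("negative values in count table")
  totals <- rowSums(counts)
  totals[totals == 0] <- 1
  sweep(counts, 1, totals, "/")
}

#' Log-transform an abundance table
#'
#' Computes `log(x + pseudo)`. `pseudo = "half-min"` (the default) uses half
#' the smallest nonzero value in the table, the usual zero-handling choice
#' for log-scale abundance models.
#'
#' @param x non-negative matrix.
#' @param pseudo positive number, or the string `"half-min"`.
#' @return transformed matrix; the pseudocount used is in attribute
#'   `"pseudo"`.
#' @export
log_transform <- function(x, pseudo = "half-min") {
  if (identical(pseudo, "half-min")) {
    nz <- x[x > 0]
    if (length(nz) == 0) stop("all-zero table: cannot derive half-min pseudocount")
    pseudo <- min(nz) / 2
  }
  if (!is.numeric(pseudo) || pseudo <= 0) stop("pseudo must be > 0 or 'half-min'")
  out <- log(x + pseudo)
  attr(out, "pseudo") <- pseudo
  out
}
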