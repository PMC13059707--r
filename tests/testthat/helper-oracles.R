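# Independent oracles used by module and acceptance tests. Each re-derives
# the quantity by a route different from the package implementation.

# ANCOVA route to the repeated-measures correlation: fit y ~ subject + x,
# r is the signed square root of SS_x / (SS_x + SS_error).
ancova_rmcorr <- function(x, y, subject) {
  fit <- stats::lm(y ~ subject + x, data = data.frame(x, y, subject))
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]; ss_e <- an["Residuals", "Sum Sq"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  list(r = r, p = an["x", "Pr(>F)"], df = an["Residuals", "Df"])
}

# PERMANOVA pseudo-F by direct double loops over sample pairs.
naive_F <- function(D, groups) {
  n <- nrow(D); a <- length(unique(groups))
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + D[idx[i], idx[j]]^2
    ss_w <- ss_w + s / length(idx)
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

random_euclid_dist <- function(n, p = 3) {
  x <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n), NULL))
  as.matrix(dist(x))
}

# Benjamini-Hochberg step-up closed form: q_(i) = min_{j>=i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- pmin(m * p[o] / seq_len(m), 1)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m); q[o] <- qs
  q
}

# balanced null design: 4 treatments x 3 donors x n_rep replicates at 24 h
null_design <- function(n_rep = 4) {
  g <- expand.grid(replicate = seq_len(n_rep), donor = c("d1", "d2", "d3"),
                   treatment = TREATMENT_LEVELS, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(g))),
             donor = g$donor, treatment = g$treatment, time_h = 24,
             replicate = g$replicate, stringsAsFactors = FALSE)
}
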