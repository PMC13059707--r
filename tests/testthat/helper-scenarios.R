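# Small, fast scenarios shared across test files.

# three planted guilds, reduced design: 4 trt x 2 times x 2 reps x 3 donors
small_scenario <- function(seed = 1L, library_size = 3000) {
  scenario_config(
    guilds = list(
      guild_spec("gA", 6, baseline_log_abundance = 0.5,
                 effect = c(Oxygen = 2, Fiber = -2, OxygenFiber = -2)),
      guild_spec("gB", 5, baseline_log_abundance = 0,
                 effect = c(Oxygen = -1.5, Fiber = 1.5, OxygenFiber = 1.5)),
      guild_spec("gC", 5, baseline_log_abundance = 0.5)
    ),
    time_points_h = c(0, 24), n_replicates = 2,
    library_size = library_size, seed = seed)
}

# no structure at all: zero effects, zero shared-factor loading
null_scenario <- function(seed = 1L, n_features = 50) {
  half <- n_features %/% 2
  scenario_config(
    guilds = list(
      guild_spec("n1", half, within_guild_corr = 0, donor_sd = 0.3,
                 noise_sd = 1),
      guild_spec("n2", n_features - half, within_guild_corr = 0,
                 donor_sd = 0.3, noise_sd = 1)
    ),
    library_size = 5000, seed = seed)
}

# hand-built rmcorr_matrix for threshold tests
fake_rmcorr <- function(r, p, ids = paste0("f", seq_len(nrow(r))),
                        degenerate = rep(FALSE, nrow(r))) {
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  structure(list(feature_ids = ids, r = r, p = p, df = 10L,
                 degenerate = stats::setNames(degenerate, ids)),
            class = "rmcorr_matrix")
}

# distance matrix with planted two-block structure
block_distance <- function(sizes, within = c(0.05, 0.15),
                           between = c(0.9, 1.1), seed = 1L) {
  n <- sum(sizes)
  ids <- sprintf("f%02d", seq_len(n))
  lab <- rep(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rng <- if (lab[i] == lab[j]) within else between
      d[i, j] <- d[j, i] <- stats::runif(1, rng[1], rng[2])
    }
    list(d = d, labels = stats::setNames(lab, ids))
  })
}
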