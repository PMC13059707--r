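#' Specify one planted guild
#'
#' A guild is a set of features sharing a latent abundance factor, a common
#' treatment response, and (optionally) an SCFA yield through which fermenter
#' guilds drive the sample chemistry.
#'
#' @param guild_id character label.
#' @param n_features number of member features (>= 1).
#' @param baseline_log_abundance baseline of the latent log-abundance.
#' @param effect named numeric vector of log-fold changes per treatment at
#'   full ramp; missing treatments default to 0. Reference (Control) is 0.
#' @param within_guild_corr loading on the guild-level shared factor, in
#'   `[0, 1]`; higher values make member features covary more tightly.
#' @param donor_sd standard deviation of the per-(guild, donor) random
#'   intercept.
#' @param noise_sd standard deviation of the per-(feature, sample) residual.
#' @param scfa_yield named numeric vector (`acetate`, `propionate`,
#'   `butyrate`), micromolar produced per unit of guild relative abundance.
#' @return a `guild_spec` list.
#' @export
guild_spec <- function(guild_id, n_features, baseline_log_abundance = 0,
                       effect = c(Oxygen = 0, Fiber = 0, OxygenFiber = 0),
                       within_guild_corr = 0.85, donor_sd = 0.4,
                       noise_sd = 0.3,
                       scfa_yield = c(acetate = 0, propionate = 0, butyrate = 0)) {
  if (n_features < 1) stop("n_features must be >= 1")
  if (within_guild_corr < 0 || within_guild_corr > 1)
    stop("within_guild_corr must be in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (donor_sd < 0) stop("donor_sd must be >= 0")
  eff <- c(Control = 0, Oxygen = 0, Fiber = 0, OxygenFiber = 0)
  if (length(effect) > 0) {
    if (is.null(names(effect))) stop("effect must be a named vector")
    bad <- setdiff(names(effect), TREATMENT_LEVELS)
    if (length(bad) > 0) stop("unknown treatment in effect: ", paste(bad, collapse = ", "))
    eff[names(effect)] <- effect
  }
  yld <- c(acetate = 0, propionate = 0, butyrate = 0)
  if (length(scfa_yield) > 0) yld[names(scfa_yield)] <- scfa_yield
  structure(list(guild_id = as.character(guild_id),
                 n_features = as.integer(n_features),
                 baseline_log_abundance = baseline_log_abundance,
                 effect = eff, within_guild_corr = within_guild_corr,
                 donor_sd = donor_sd, noise_sd = noise_sd,
                 scfa_yield = yld),
            class = "guild_spec")
}

#' Build a simulation scenario
#'
#' Defaults mirror the fermentation study design: 4 treatment arms x 4 time
#' points (0, 12, 24, 48 h) x 5 replicates x 3 donors, each sample
#' sequenced to a common library size of 28,000 reads.
#'
#' @param guilds list of [guild_spec()] objects (>= 2).
#' @param n_donors number of donors (>= 2).
#' @param treatments treatment arms.
#' @param time_points_h sampling times in hours.
#' @param n_replicates biological replicates per arm x time x donor.
#' @param library_size reads per sample (multinomial total).
#' @param chem_noise_sd measurement noise of each SCFA, micromolar.
#' @param ph_baseline,ph_kappa pH model: `pH = ph_baseline - ph_kappa *
#'   log1p(total SCFA in mM)`, clipped to `[3.8, 7.2]`.
#' @param seed integer seed; the whole draw is a deterministic function of it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(guilds,
                            n_donors = 3,
                            treatments = TREATMENT_LEVELS,
                            time_points_h = c(0, 12, 24, 48),
                            n_replicates = 5,
                            library_size = 28000,
                            chem_noise_sd = 200,
                            ph_baseline = 6.7,
                            ph_kappa = 0.75,
                            seed = 1L) {
  if (n_donors < 2) stop("n_donors must be >= 2")
  if (length(guilds) < 2) stop("at least 2 guilds required")
  if (library_size <= 0) stop("library_size must be > 0")
  if (!all(vapply(guilds, inherits, logical(1), "guild_spec")))
    stop("guilds must be a list of guild_spec objects")
  structure(list(guilds = guilds, n_donors = as.integer(n_donors),
                 treatments = treatments,
                 time_points_h = time_points_h,
                 n_replicates = as.integer(n_replicates),
                 library_size = as.integer(library_size),
                 chem_noise_sd = chem_noise_sd,
                 ph_baseline = ph_baseline, ph_kappa = ph_kappa,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default scenario emulating the study's guild phenotypes
#'
#' Encodes the qualitative response structure of the ex vivo oxygen x fiber
#' experiment:
#' * two opportunistic pathobiont guilds bloom under oxygen alone and are
#'   suppressed whenever fiber is present;
#' * three oxygen-sensitive, fiber-rescued anaerobe guilds (the SCFA
#'   fermenters, carrying positive `scfa_yield`);
#' * one "transitional" guild promoted only when oxygen and fiber co-occur;
#' * one guild responding to fiber regardless of oxygen;
#' * two neutral background guilds.
#'
#' Effect sizes are log-fold changes at full ramp (>= 24 h), chosen so that
#' the oxygen bloom, the fiber rescue and the chemistry coupling are all
#' recoverable at the design's sample size.
#'
#' @param seed scenario seed.
#' @return a [scenario_config()].
#' @export
default_paper_scenario <- function(seed = 1L) {
  guilds <- list(
    guild_spec("pathobiont_primary", 8, baseline_log_abundance = 0.5,
               effect = c(Oxygen = 2.5, Fiber = -2.5, OxygenFiber = -2.5)),
    guild_spec("pathobiont_secondary", 6, baseline_log_abundance = 0,
               effect = c(Oxygen = 2.0, Fiber = -2.0, OxygenFiber = -2.0)),
    guild_spec("fermenter_a", 7, baseline_log_abundance = -2.5,
               effect = c(Oxygen = -2.0, Fiber = 4.0, OxygenFiber = 3.5),
               scfa_yield = c(acetate = 25000, propionate = 10000, butyrate = 8000)),
    guild_spec("fermenter_b", 6, baseline_log_abundance = -2.5,
               effect = c(Oxygen = -1.8, Fiber = 3.8, OxygenFiber = 3.3),
               scfa_yield = c(acetate = 18000, propionate = 8000, butyrate = 10000)),
    guild_spec("fermenter_c", 6, baseline_log_abundance = -2.5,
               effect = c(Oxygen = -2.2, Fiber = 4.2, OxygenFiber = 3.7),
               scfa_yield = c(acetate = 15000, propionate = 12000, butyrate = 6000)),
    guild_spec("transitional", 5, baseline_log_abundance = -0.5,
               effect = c(Oxygen = 0, Fiber = 0, OxygenFiber = 2.0)),
    guild_spec("fiber_responder", 5, baseline_log_abundance = 0,
               effect = c(Oxygen = 0, Fiber = 1.5, OxygenFiber = 1.5),
               scfa_yield = c(acetate = 5000, propionate = 2000, butyrate = 2000)),
    guild_spec("background_a", 10, baseline_log_abundance = 1.0,
               within_guild_corr = 0.8),
    guild_spec("background_b", 8, baseline_log_abundance = 0.5,
               within_guild_corr = 0.8)
  )
  scenario_config(guilds = guilds, seed = seed)
}

# time ramp: treatment effects absent at 0 h (pre-treatment inoculum),
# full from 24 h onward
.ramp <- function(t) pmin(t / 24, 1)

#' Simulate a synthetic fermentation study
#'
#' For sample s and feature f in guild g the latent log-abundance is
#' `lambda_fs = baseline_g + effect_g(treatment_s) * ramp(time_s) +
#' donor_g(d_s) + within_guild_corr_g * Z_gs + eps_fs` with `Z_gs ~ N(0,1)` a
#' guild-by-sample shared factor, `donor_g(d) ~ N(0, donor_sd^2)` drawn once
#' per (guild, donor), and `eps ~ N(0, noise_sd^2)`. Counts are
#' `multinomial(library_size, softmax(lambda))` per sample, so every sample
#' sums to the library size exactly. Each SCFA is `sum_g yield_g * relative
#' abundance of g` plus truncated Gaussian noise; pH follows the scenario's
#' log-SCFA law.
#'
#' @param config a [scenario_config()].
#' @return list with `counts` (samples x features integer matrix), `metadata`
#'   (data.frame), `chem` (data.frame), and `truth` (feature-to-guild map,
#'   per-guild true effects, per-sample latent guild log-abundances).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, .simulate_community_impl(config))
}

.simulate_community_impl <- function(config) {
  gl <- config$guilds
  n_g <- length(gl)
  donors <- paste0("D", seq_len(config$n_donors))
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        time_h = config$time_points_h,
                        treatment = config$treatments,
                        donor = donors,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_s <- nrow(design)
  design$sample_id <- sprintf("S%03d", seq_len(n_s))
  meta <- data.frame(sample_id = design$sample_id,
                     donor = factor(design$donor),
                     treatment = factor(design$treatment, levels = TREATMENT_LEVELS),
                     time_h = design$time_h,
                     replicate = as.integer(design$replicate),
                     stringsAsFactors = FALSE)

  feature_guild <- rep(vapply(gl, `[[`, character(1), "guild_id"),
                       vapply(gl, `[[`, integer(1), "n_features"))
  n_f <- length(feature_guild)
  feature_ids <- sprintf("ASV%04d", seq_len(n_f))
  names(feature_guild) <- feature_ids

  ramp <- .ramp(meta$time_h)
  # per-(guild, donor) random intercepts
  donor_eff <- matrix(0, n_g, config$n_donors,
                      dimnames = list(NULL, donors))
  for (g in seq_len(n_g))
    donor_eff[g, ] <- stats::rnorm(config$n_donors, 0, gl[[g]]$donor_sd)
  # guild-by-sample shared factors
  Z <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)

  lambda <- matrix(0, n_s, n_f, dimnames = list(meta$sample_id, feature_ids))
  guild_latent <- matrix(0, n_s, n_g,
                         dimnames = list(meta$sample_id,
                                         vapply(gl, `[[`, character(1), "guild_id")))
  col <- 0
  for (g in seq_len(n_g)) {
    spec <- gl[[g]]
    trt_eff <- spec$effect[as.character(meta$treatment)] * ramp
    base_gs <- spec$baseline_log_abundance + trt_eff +
      donor_eff[g, as.character(meta$donor)] +
      spec$within_guild_corr * Z[g, ]
    guild_latent[, g] <- base_gs
    eps <- matrix(stats::rnorm(n_s * spec$n_features, 0, spec$noise_sd),
                  n_s, spec$n_features)
    lambda[, col + seq_len(spec$n_features)] <- base_gs + eps
    col <- col + spec$n_features
  }
  if (any(!is.finite(apply(lambda, 1, max))))
    stop("degenerate softmax: a sample has no finite latent abundance")

  counts <- matrix(0L, n_s, n_f, dimnames = dimnames(lambda))
  for (s in seq_len(n_s)) {
    w <- lambda[s, ] - max(lambda[s, ])  # softmax, numerically stable
    p <- exp(w) / sum(exp(w))
    counts[s, ] <- as.integer(stats::rmultinom(1, config$library_size, p))
  }

  # chemistry from true guild relative abundances (softmax scale)
  guild_rel <- matrix(0, n_s, n_g, dimnames = dimnames(guild_latent))
  rel <- t(apply(lambda, 1, function(l) { w <- exp(l - max(l)); w / sum(w) }))
  for (g in seq_len(n_g)) {
    idx <- which(feature_guild == gl[[g]]$guild_id)
    guild_rel[, g] <- rowSums(rel[, idx, drop = FALSE])
  }
  yields <- t(vapply(gl, `[[`, numeric(3), "scfa_yield"))  # guilds x 3 acids
  scfa <- guild_rel %*% yields  # micromolar
  scfa <- scfa + matrix(stats::rnorm(length(scfa), 0, config$chem_noise_sd),
                        nrow(scfa), ncol(scfa))
  scfa[scfa < 0] <- 0
  total_mM <- rowSums(scfa) / 1000
  pH <- pmin(pmax(config$ph_baseline - config$ph_kappa * log1p(total_mM),
                  3.8), 7.2)
  chem <- data.frame(sample_id = meta$sample_id, pH = pH,
                     acetate = scfa[, "acetate"],
                     propionate = scfa[, "propionate"],
                     butyrate = scfa[, "butyrate"],
                     stringsAsFactors = FALSE)

  effects <- do.call(rbind, lapply(gl, function(s)
    data.frame(guild_id = s$guild_id, treatment = names(s$effect),
               effect = unname(s$effect), stringsAsFactors = FALSE)))
  truth <- list(feature_guild = feature_guild,
                guild_effects = effects,
                guild_latent = guild_latent,
                guild_relative_abundance = guild_rel)
  list(counts = validate_count_table(counts), metadata = meta,
       chem = chem, truth = truth)
}
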