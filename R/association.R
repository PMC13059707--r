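# Internal: align metadata (and optionally chemistry) to a guild table's
# samples, applying the time filter (default: all post-0 h samples).
.assoc_frame <- function(gt, meta, chem = NULL, times = NULL) {
  meta <- validate_metadata(meta)
  absent <- setdiff(rownames(gt), meta$sample_id)
  if (length(absent) > 0)
    stop("guild table sample(s) missing from metadata: ",
         paste(absent, collapse = ", "))
  df <- meta[match(rownames(gt), meta$sample_id), ]
  keep <- if (is.null(times)) df$time_h > 0 else df$time_h %in% times
  df <- df[keep, , drop = FALSE]
  if (!is.null(chem)) {
    absent <- setdiff(df$sample_id, chem$sample_id)
    if (length(absent) > 0)
      stop("sample(s) missing from chemistry table: ",
           paste(absent, collapse = ", "))
    df <- cbind(df, chem[match(df$sample_id, chem$sample_id),
                         c("pH", "acetate", "propionate", "butyrate")])
  }
  df
}

# Internal: linear mixed model with donor random intercept; falls back to a
# donor fixed-effect fit when the mixed fit errors out. Returns the fixed
# slope rows of interest.
.fit_mixed <- function(formula_mixed, formula_fixed, data, terms) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula_mixed, data = data, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(summary(fit))
    model <- "mixed"
  } else {
    lf <- stats::lm(formula_fixed, data = data)
    cf <- stats::coef(summary(lf))
    model <- "fixed_fallback"
  }
  rows <- cf[terms, c(1, 2, ncol(cf)), drop = FALSE]
  data.frame(term = terms, coefficient = rows[, 1], se = rows[, 2],
             p = rows[, 3], model = model,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-guild association with treatment
#'
#' For each guild, fits a linear mixed model of log-transformed guild
#' abundance on treatment (reference = Control) with a donor random
#' intercept, the MaAsLin2-style configuration of the study. p-values use
#' Satterthwaite degrees of freedom; q-values are Benjamini-Hochberg over
#' the whole family of (guild x non-reference level) tests. Guilds with zero
#' abundance variance are flagged and excluded from the FDR family.
#'
#' @param gt samples x guilds abundance matrix (from [aggregate_guilds()]).
#' @param meta sample metadata.
#' @param reference reference treatment level (default `"Control"`).
#' @param times time points (h) to include; `NULL` (default) uses all
#'   post-0 h samples.
#' @param pseudo pseudocount rule passed to [log_transform()].
#' @return data.frame: `guild`, `treatment`, `coefficient`,
#'   `std_coefficient`, `se`, `p`, `q`, `model`, `flagged`.
#' @export
fit_guild_treatment <- function(gt, meta, reference = "Control",
                                times = NULL, pseudo = "half-min") {
  df0 <- .assoc_frame(gt, meta, times = times)
  if (nlevels(droplevels(df0$treatment)) < 2)
    stop("need >= 2 treatment levels")
  logs <- log_transform(gt[df0$sample_id, , drop = FALSE], pseudo = pseudo)
  trt <- stats::relevel(droplevels(df0$treatment), ref = reference)
  terms <- paste0("treatment", setdiff(levels(trt), reference))
  res <- lapply(colnames(gt), function(g) {
    y <- logs[, g]
    if (stats::var(y) < .Machine$double.eps)
      return(data.frame(guild = g,
                        treatment = setdiff(levels(trt), reference),
                        coefficient = NA_real_, std_coefficient = NA_real_,
                        se = NA_real_, p = NA_real_, model = NA_character_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    d <- data.frame(y = y, treatment = trt, donor = df0$donor)
    out <- .fit_mixed(y ~ treatment + (1 | donor), y ~ treatment + donor,
                      d, terms)
    data.frame(guild = g, treatment = sub("^treatment", "", out$term),
               coefficient = out$coefficient,
               std_coefficient = out$coefficient / stats::sd(y),
               se = out$se, p = out$p, model = out$model, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  res$q[!res$flagged] <- stats::p.adjust(res$p[!res$flagged], method = "BH")
  res
}

#' Per-guild association with SCFA concentrations
#'
#' For each guild x SCFA pair, fits log guild abundance (z-scored) on the
#' z-scored SCFA concentration with a donor random intercept; the slope is
#' the standardized coefficient, invariant to the units of either variable.
#' q-values are BH over all guild x SCFA tests.
#'
#' @param gt samples x guilds abundance matrix.
#' @param chem chemistry table covering the samples.
#' @param meta sample metadata.
#' @param scfas which chemistry columns to model (default the three SCFAs).
#' @param times,pseudo as in [fit_guild_treatment()].
#' @return data.frame: `guild`, `scfa`, `coefficient` (original units),
#'   `std_coefficient`, `se` (of the standardized slope), `p`, `q`, `model`,
#'   `flagged`.
#' @export
fit_guild_scfa <- function(gt, chem, meta,
                           scfas = c("acetate", "propionate", "butyrate"),
                           times = NULL, pseudo = "half-min") {
  chem <- validate_chem(chem)
  df0 <- .assoc_frame(gt, meta, chem = chem, times = times)
  logs <- log_transform(gt[df0$sample_id, , drop = FALSE], pseudo = pseudo)
  for (s in scfas)
    if (stats::sd(df0[[s]]) < .Machine$double.eps)
      stop("constant SCFA column: ", s)
  grid <- expand.grid(guild = colnames(gt), scfa = scfas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$guild[i]; s <- grid$scfa[i]
    y <- logs[, g]; x <- df0[[s]]
    if (stats::var(y) < .Machine$double.eps)
      return(data.frame(guild = g, scfa = s, coefficient = NA_real_,
                        std_coefficient = NA_real_, se = NA_real_,
                        p = NA_real_, model = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    d <- data.frame(ys = as.numeric(scale(y)), xs = as.numeric(scale(x)),
                    donor = df0$donor)
    out <- .fit_mixed(ys ~ xs + (1 | donor), ys ~ xs + donor, d, "xs")
    data.frame(guild = g, scfa = s,
               coefficient = out$coefficient * stats::sd(y) / stats::sd(x),
               std_coefficient = out$coefficient, se = out$se, p = out$p,
               model = out$model, flagged = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  res$q[!res$flagged] <- stats::p.adjust(res$p[!res$flagged], method = "BH")
  res
}

#' Chemistry response versus treatment with Tukey contrasts
#'
#' Fits the study's chemistry model — a linear mixed-effects model of the
#' response (pH or an SCFA) on treatment with donor as a random intercept —
#' and reports all pairwise treatment contrasts with Tukey's
#' studentized-range adjustment on the estimated marginal means. With fewer
#' than 2 donors the model falls back to fixed effects with a warning.
#'
#' @param chem chemistry table.
#' @param meta sample metadata.
#' @param response one of `"pH"`, `"acetate"`, `"propionate"`, `"butyrate"`.
#' @param times time points to include; `NULL` (default) = all post-0 h.
#' @return data.frame of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p_tukey`.
#' @export
fit_chem_treatment <- function(chem, meta,
                               response = c("pH", "acetate", "propionate",
                                            "butyrate"),
                               times = NULL) {
  response <- match.arg(response)
  chem <- validate_chem(chem)
  meta <- validate_metadata(meta)
  df <- merge(meta, chem, by = "sample_id")
  df <- if (is.null(times)) df[df$time_h > 0, ] else df[df$time_h %in% times, ]
  if (nlevels(droplevels(df$treatment)) < 2)
    stop("need >= 2 treatment levels")
  df$y <- df[[response]]
  df$treatment <- droplevels(df$treatment)
  if (nlevels(droplevels(df$donor)) < 2) {
    warning("fewer than 2 donors: falling back to a fixed-effects model")
    fit <- stats::lm(y ~ treatment, data = df)
  } else {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ treatment + (1 | donor), data = df, REML = TRUE)))
  }
  emm <- emmeans::emmeans(fit, "treatment")
  ct <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "tukey")
  data.frame(contrast = as.character(ct$contrast), estimate = ct$estimate,
             se = ct$SE, df = ct$df, t = ct$t.ratio, p_tukey = ct$p.value,
             stringsAsFactors = FALSE)
}
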