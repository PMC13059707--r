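#!/usr/bin/env Rscript
# Stage 5 — guild-level association models and chemistry contrasts.
#
# Per-guild linear mixed models (donor random intercept) of log guild
# abundance versus treatment (reference = Control) and versus each SCFA
# (standardized coefficients), with Benjamini-Hochberg FDR across each
# family; and the pH/SCFA mixed model with Tukey-adjusted pairwise
# treatment contrasts.

library(guildflow)

meta <- read_metadata("results/data/metadata.tsv")
chem <- read_chem("results/data/chem.tsv")
gt_df <- utils::read.delim("results/guild_table.tsv", check.names = FALSE)
gt <- as.matrix(gt_df[, -1]); rownames(gt) <- gt_df$sample_id

at <- fit_guild_treatment(gt, meta)
utils::write.table(at, "results/association_treatment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
as_ <- fit_guild_scfa(gt, chem, meta)
utils::write.table(as_, "results/association_scfa.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
ct <- do.call(rbind, lapply(c("pH", "acetate", "propionate", "butyrate"),
  function(v) cbind(response = v, fit_chem_treatment(chem, meta, v))))
utils::write.table(ct, "results/chem_contrasts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("guilds significantly shifted vs Control (q < 0.05):\n")
sig <- at[!is.na(at$q) & at$q < 0.05, ]
print(data.frame(guild = sig$guild, treatment = sig$treatment,
                 coef = round(sig$coefficient, 2),
                 q = signif(sig$q, 2)), row.names = FALSE)
cat("\npH Tukey contrasts (mixed model, donor random intercept):\n")
php <- ct[ct$response == "pH", c("contrast", "estimate", "p_tukey")]
php$estimate <- round(php$estimate, 2); php$p_tukey <- signif(php$p_tukey, 2)
print(php, row.names = FALSE)
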