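#!/usr/bin/env Rscript
# Stage 4 — ordination and community-level testing.
#
# Bray-Curtis dissimilarity at the ASV and guild level, donor-adjusted PCoA
# (aPCoA), subject-stratified pairwise PERMANOVA across the four arms, and
# Procrustes/PROTEST concordance between the ASV-level and guild-level
# adjusted ordinations (the dimension-reduction validity check).

library(guildflow)

rare <- read_count_table("results/data/counts_rarefied.tsv")
meta <- read_metadata("results/data/metadata.tsv")
meta <- meta[match(rownames(rare), meta$sample_id), ]
gt_df <- utils::read.delim("results/guild_table.tsv", check.names = FALSE)
gt <- as.matrix(gt_df[, -1]); rownames(gt) <- gt_df$sample_id

d_asv <- bray_curtis(to_relative(rare))
d_cag <- bray_curtis(gt)
ord_asv <- apcoa(d_asv, meta$donor)
ord_cag <- apcoa(d_cag, meta$donor)
write_ordination(ord_asv, "results/apcoa_asv.tsv")
write_ordination(ord_cag, "results/apcoa_cag.tsv")

pw <- pairwise_permanova(d_cag, meta$treatment, n_perm = 999,
                         strata = meta$donor, seed = 4L)
utils::write.table(pw, "results/pairwise_permanova.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
pro <- procrustes_protest(ord_asv, ord_cag, n_perm = 999, seed = 5L)

adj2 <- as.matrix(dist(ord_cag$coordinates[, 1:2]))
raw2 <- as.matrix(dist(pcoa(d_cag)$coordinates[, 1:2]))
cat(sprintf("donor R2 on first two axes: %.3f unadjusted -> %.2e adjusted\n",
            permanova(raw2, meta$donor, n_perm = 19, seed = 1)$R2,
            permanova(adj2, meta$donor, n_perm = 19, seed = 1)$R2))
cat("pairwise subject-stratified PERMANOVA (999 permutations):\n")
print(cbind(pw[, c("group_a", "group_b")], round(pw[, c("F", "R2", "p", "q")], 4)))
cat(sprintf("Procrustes ASV vs CAG aPCoA: m2 = %.4f (correlation %.3f), PROTEST p = %.3f\n",
            pro$m2, pro$correlation, pro$p))
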