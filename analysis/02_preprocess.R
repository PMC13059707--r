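#!/usr/bin/env Rscript
# Stage 2 — rarefaction and prevalence filtering.
#
# Rarefies every sample to 28,000 reads (hypergeometric subsampling) and
# keeps ASVs present in strictly more than 30% of samples, the inclusion
# rule for guild inference. Writes the prevalent count table and the
# relative/log-relative abundance tables consumed downstream.

library(guildflow)

counts <- read_count_table("results/data/counts.tsv")
rare <- rarefy(counts, depth = 28000, seed = 2L)
prev <- prevalence_filter(rare, min_prevalence = 0.30)
write_count_table(rare, "results/data/counts_rarefied.tsv")
write_count_table(prev, "results/data/counts_prevalent.tsv")

cat(sprintf("rarefied %d/%d samples to depth 28,000 (%d dropped)\n",
            nrow(rare), nrow(counts), length(attr(rare, "dropped_samples"))))
cat(sprintf("prevalence filter (>30%%): kept %d/%d ASVs covering %.1f%% of reads\n",
            ncol(prev), ncol(rare), 100 * attr(prev, "coverage")))
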