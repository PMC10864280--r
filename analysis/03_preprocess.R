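#!/usr/bin/env Rscript
# Preprocessing: depth and prevalence filters + CLR for the genus counts,
# missingness rule + median imputation + log-z scaling for metabolites.
# Writes the transformed tables under results/.

library(cotwin)

counts <- read_feature_table("results/cohort/counts.tsv")
metab <- read_feature_table("results/cohort/metabolites.tsv")
md <- read_metadata("results/cohort/metadata.tsv")

storage.mode(counts) <- "integer"
counts <- filter_taxa(filter_samples_by_depth(counts, min_depth = 10000))
log <- attr(counts, "filter_log")
cat("taxon filter removals:",
    length(log$singleton_taxa), "singletons,",
    length(log$single_sample_taxa), "single-sample,",
    length(log$zero_taxa), "all-zero,",
    length(log$empty_samples), "empty samples\n")

clr <- clr_transform(counts)
cat(sprintf("CLR: %d samples x %d genera, max |row sum| = %.2e\n",
            nrow(clr), ncol(clr), max(abs(rowSums(clr)))))

metab_z <- preprocess_metabolites(metab)
dropped <- attr(metab_z, "dropped")
cat(sprintf("metabolites: %d kept, %d dropped by the 25%% missingness rule\n",
            ncol(metab_z), length(dropped)))

write_feature_table(clr, "results/genus_clr.tsv")
write_feature_table(metab_z, "results/metabolites_logz.tsv")
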