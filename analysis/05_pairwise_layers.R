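#!/usr/bin/env Rscript
# Pyramid layers a-c: paired Wilcoxon screening of genera, metabolites and
# predicted pathways over MZ-discordant, DZ-discordant and all-discordant
# twin pairs, plus the cross-layer overlap sets.

library(cotwin)

clr <- read_feature_table("results/genus_clr.tsv")
metab_z <- read_feature_table("results/metabolites_logz.tsv")
pathways <- read_feature_table("results/cohort/pathways.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
md <- md[md$sample_id %in% rownames(clr), ]

fams <- list(genus = list(x = clr, alpha = 0.05),
             metabolite = list(x = metab_z, alpha = 0.05),
             pathway = list(x = pathways[md$sample_id, ], alpha = 0.1))

for (fam in names(fams)) {
  res <- list()
  for (ly in c("a", "b", "c")) {
    r <- pairwise_layer(fams[[fam]]$x, md, ly, alpha = fams[[fam]]$alpha,
                        feature_kind = fam)
    res[[ly]] <- r
    write.table(r, sprintf("results/layer_%s_%s.tsv", fam, ly),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%-10s layer %s: %2d / %d significant (n_pairs = %d)\n",
                fam, ly, sum(r$significant), nrow(r), r$n_pairs[1]))
  }
  ov <- layer_overlaps(res)
  cat(sprintf("%-10s overlap a&b: %s; common to a,b,c: %s\n\n", fam,
              paste(ov$pairwise[["a&b"]], collapse = ","),
              paste(ov$common, collapse = ",")))
  write.table(ov$counts, sprintf("results/overlaps_%s.tsv", fam),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
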