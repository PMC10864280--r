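#!/usr/bin/env Rscript
# Pyramid layers d-e: zygosity-stratified linear mixed-model screens with
# BH-FDR control. Layer d compares healthy co-twins of discordant pairs
# with all affected twins; layer e compares all healthy with all affected.
# Covariates: age, sex, BMI, antibiotics, vegetable and fruit intake.

library(cotwin)

clr <- read_feature_table("results/genus_clr.tsv")
metab_z <- read_feature_table("results/metabolites_logz.tsv")
pathways <- read_feature_table("results/cohort/pathways.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
md <- md[md$sample_id %in% rownames(clr), ]

fams <- list(genus = list(x = clr, fdr = 0.2),
             metabolite = list(x = metab_z, fdr = 0.2),
             pathway = list(x = pathways[md$sample_id, ], fdr = 0.25))

for (fam in names(fams)) {
  for (st in c("d", "e")) {
    res <- screen_features(fams[[fam]]$x, md, st,
                           fdr_threshold = fams[[fam]]$fdr)
    write.table(res, sprintf("results/lmm_%s_%s.tsv", fam, st),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf(
      "%-10s setup %s (%d healthy vs %d affected): %d / %d at FDR < %.2f\n",
      fam, st, attr(res, "n_healthy"), attr(res, "n_affected"),
      sum(res$significant), nrow(res), fams[[fam]]$fdr))
    top <- res[order(res$p), ][1, ]
    cat(sprintf("   top hit: %s  beta_md = %+.3f  p = %.2e  q = %.3f\n",
                top$feature, top$beta_md, top$p, top$q))
  }
}
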