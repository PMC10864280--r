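#!/usr/bin/env Rscript
# Genus-pathway Spearman correlation network over the differential
# features, computed in the layer-d population (healthy co-twins + all
# affected twins), BH-adjusted across all tested pairs, edges kept at
# |rho| > 0.2 and FDR < 0.05. The edge table is Cytoscape-importable.

library(cotwin)

clr <- read_feature_table("results/genus_clr.tsv")
pathways <- read_feature_table("results/cohort/pathways.tsv")
md <- read_metadata("results/cohort/metadata.tsv")
md <- md[md$sample_id %in% rownames(clr), ]

sig_features <- function(files, col = "significant") {
  unique(unlist(lapply(files, function(f) {
    r <- read.delim(f, stringsAsFactors = FALSE)
    r$feature[r[[col]]]
  })))
}
diff_g <- sig_features(sprintf("results/%s.tsv",
  c("layer_genus_a", "layer_genus_b", "layer_genus_c",
    "lmm_genus_d", "lmm_genus_e")))
diff_p <- sig_features(sprintf("results/%s.tsv",
  c("layer_pathway_a", "layer_pathway_b", "layer_pathway_c",
    "lmm_pathway_d", "lmm_pathway_e")))
cat("differential genera:", length(diff_g),
    " differential pathways:", length(diff_p), "\n")

net <- build_network(clr, pathways[md$sample_id, ],
                     setup_samples(md, "d"), diff_g, diff_p)
write_edges(net, "results/edges.tsv")
cat(sprintf("%d edge(s) at |rho| > 0.2, FDR < 0.05\n", nrow(net)))
if (nrow(net)) {
  print(net[order(-abs(net$rho)), ], row.names = FALSE, digits = 3)
  cat("\nnode degrees:\n")
  print(attr(net, "degree"))
}
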