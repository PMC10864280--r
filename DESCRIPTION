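Package: cotwin
Title: Co-Twin Control Analysis of Microbiome and Metabolome in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A layered ("pyramid") co-twin control workflow for identifying
    disease-associated gut microbial genera, circulating metabolites and
    predicted metabolic pathways in cohorts of monozygotic and dizygotic
    twins. Provides compositional preprocessing (depth and prevalence
    filters, genus agglomeration, centered log-ratio transform), pair-level
    cohort description (concordance, prevalence, zygosity association
    tests), within-pair versus between-pair beta-diversity comparisons,
    paired nonparametric screening over discordant twin pairs, a
    zygosity-stratified random-intercept linear mixed model with
    Benjamini-Hochberg screening, a genus-pathway Spearman correlation
    network, and a synthetic twin-cohort generator (liability-threshold
    phenotypes, pair-correlated log-normal-multinomial counts, correlated
    metabolite panels) with recorded ground truth so every stage can be
    exercised and validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
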