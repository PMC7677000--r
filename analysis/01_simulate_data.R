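#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — positive- and negative-mode
# LC-MS feature tables (six replicates per group: LB blank, pooled QC, six
# protective strains, and the non-protective control B313), with five known
# compounds planted as differential features per mode. Tables and the truth
# set go to results/.

suppressPackageStartupMessages(library(symbioscreen))
dir.create("results", showWarnings = FALSE)

seed <- 20260928
lib <- read_compound_library()
cand <- lib[!lib$is_nutrient, ]
strains <- c("B108", "B253", "B263", "B424", "B505", "B585")
# five true candidates per mode (strong in one strain, absent from B313) ...
planted <- lapply(1:5, function(i) {
  planted_candidate(i, strains[1 + (i - 1) %% 6], fc_vs_lb = 50,
                    fc_vs_b313 = 40, compound_cas = cand$cas[i])
})
# ... on top of ~95 ordinary bacterial metabolites shared by most strains
# including B313 (upregulated vs the medium blank but flat vs B313): in the
# study roughly 6-11% of detected features were differential per strain, so
# a 1000-feature panel carries on the order of a hundred
set.seed(seed)
shared <- lapply(31:125, function(i) {
  planted_candidate(i, c(strains, "B313")[
    sample.int(7, sample(4:7, 1))], fc_vs_lb = runif(1, 4, 30),
    fc_vs_b313 = 1)
})

for (mode in c("positive", "negative")) {
  cfg <- sim_feature_config(n_features_per_mode = 1000, missing_rate = 0.02,
                            seed = seed + (mode == "negative"))
  sim <- simulate_feature_table(cfg, c(planted, shared), ion_mode = mode)
  sim <- assign_compound_mz(sim, lib)
  write_feature_table(sim$table,
                      file.path("results", paste0("features_", mode, ".tsv")))
  utils::write.table(sim$truth,
                     file.path("results", paste0("truth_", mode, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s mode: %d features x %d samples, %d planted candidates\n",
              mode, nrow(sim$table$features), nrow(sim$table$samples),
              length(unique(sim$truth$feature_index))))
}
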