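#!/usr/bin/env Rscript
# Stage 3: annotate the screened candidates by accurate mass within 10 ppm
# ([M+H]+ / [M-H]- adducts), drop nutrient compounds, and reduce to the
# unique compound list. Also reproduces the compound dedup on the packaged
# transcription of the published 32-row candidate table.

suppressPackageStartupMessages(library(symbioscreen))

lib <- read_compound_library()
candidates <- read_candidate_table("results/candidates.tsv")
ann <- exclude_nutrients(annotate_features(candidates, lib, tol_ppm = 10))
final <- finalize_candidates(candidates, ann)
utils::write.table(final[setdiff(names(final), "support")],
                   "results/final_compounds.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("simulated screen: %d candidate rows -> %d unique compounds\n",
            nrow(candidates), nrow(final)))
print(final[c("compound", "cas", "n_support", "strains")])

published <- read_candidate_table(
  system.file("extdata", "table1_candidates.tsv", package = "symbioscreen"))
pub_final <- finalize_candidates(published)
cat(sprintf("published candidate table: %d rows -> %d unique compounds\n",
            nrow(published), nrow(pub_final)))
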