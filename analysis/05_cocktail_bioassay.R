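#!/usr/bin/env Rscript
# Stage 5: formulate the protective cocktail from the published nonaxenic
# body-surface means (>= 0.1 mg/liter inclusion rule -> the seven organic
# acids), lay out the 2^1..2^-6 dose series, and summarize simulated
# germination and mycelial-growth bioassays as rates relative to control
# with the ANOVA-variant selection tree and letter display.

suppressPackageStartupMessages(library(symbioscreen))

recipe <- build_recipe(read_surface_concentrations(), "nonaxenic", 0.1)
print(recipe)
doses <- dose_series(recipe)
utils::write.table(doses, "results/dose_series.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# dose-dependent inhibition; ~15% of control at the in-situ dose, echoing
# the strong published suppression there
effect <- function(d) 1 / (1 + 5.5 * d)
for (assay in c("germination", "growth")) {
  d <- simulate_bioassay(doses$dose_multiplier, effect, n_reps = 6,
                         seed = 20260905 + (assay == "growth"),
                         assay = assay)
  rr <- relative_rate(d)
  s <- dose_response_summary(d)
  utils::write.table(rr, file.path("results", paste0(assay, "_rates.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s: omnibus %s, p = %.3g\n", assay, s$omnibus$method,
              s$omnibus$p_value))
  print(merge(rr, s$groups[c("dose_multiplier", "letters")],
              by = "dose_multiplier"), digits = 3)
  insitu <- rr$relative_rate_pct[rr$dose_multiplier == 1]
  cat(sprintf("%s at the in-situ dose: %.1f%% of control\n", assay, insitu))
}
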