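#!/usr/bin/env Rscript
# Stage 6: does the cocktail protect infected axenic larvae? Simulated
# time-to-death records (45 larvae per arm, checked every 2 days until
# pupation at day 20) under fungal infection with and without the cocktail,
# summarized with Kaplan-Meier curves and pairwise log-rank tests.

suppressPackageStartupMessages(library(symbioscreen))

surv <- simulate_survival(
  c("Blank" = 0.002, "Blank+Cocktail" = 0.002,
    "Blank+Bb" = 0.12, "Blank+Bb+Cocktail" = 0.03),
  n_per_group = 45, horizon_days = 20, obs_interval_days = 2,
  seed = 20260906)
utils::write.table(surv, "results/survival_records.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (g in unique(surv$group)) {
  km <- km_estimate(surv, g)
  cat(sprintf("%-18s final survival %5.1f%%\n", g,
              100 * attr(km, "final_survival")))
}

pairs <- list(c("Blank", "Blank+Bb"),
              c("Blank", "Blank+Cocktail"),
              c("Blank+Bb", "Blank+Bb+Cocktail"))
res <- do.call(rbind, lapply(pairs, function(p) {
  lr <- logrank_test(surv, p[1], p[2])
  cbind(data.frame(group_a = p[1], group_b = p[2]), lr)
}))
utils::write.table(res, "results/logrank_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(res, digits = 4)
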