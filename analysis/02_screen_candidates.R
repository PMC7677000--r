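#!/usr/bin/env Rscript
# Stage 2: pre-screening hygiene (QC-RSD filter, min/2 imputation, median
# normalization), model diagnostics (PCA, PLS-DA permutation check for one
# contrast), and the two-step candidate cascade: >= 2-fold vs the LB blank
# (with Welch p < 0.05 and VIP >= 2), union with B313's differential set,
# then >= 10-fold vs B313. Expects stage 1 outputs in results/.

suppressPackageStartupMessages(library(symbioscreen))

tables <- list()
for (mode in c("positive", "negative")) {
  tab <- read_feature_table(file.path("results",
                                      paste0("features_", mode, ".tsv")))
  filt <- qc_filter(tab)
  norm <- normalize_intensities(impute_missing(filt), "median")
  cat(sprintf("%s mode: %d features, %d after QC filter\n",
              mode, nrow(tab$features), nrow(filt$features)))
  tables[[mode]] <- norm
}

# overview PCA and an overfitting check on one strain-vs-LB model
pos <- tables$positive
pc <- pca(pos, 2)
cat(sprintf("PCA (positive mode): PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pc$explained_variance_fraction[1],
            100 * pc$explained_variance_fraction[2]))
sel <- pos$samples$group %in% c("B108", "LB")
sub <- feature_table(pos$features, pos$samples[sel, ],
                     pos$intensities[, sel])
perm <- permutation_test(sub, sub$samples$group, n_perm = 100, seed = 1,
                         k_folds = 6)
print(perm)

candidates <- run_cascade(tables)
utils::write.table(candidates, "results/candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(nrow(candidates), "candidate feature/strain rows written\n")

# how the screen did against the planted truth
truth <- do.call(rbind, lapply(c("positive", "negative"), function(m)
  utils::read.table(file.path("results", paste0("truth_", m, ".tsv")),
                    header = TRUE, sep = "\t")))
# true candidates are the planted features that meet both fold-change rules
truth <- truth[truth$fc_vs_lb >= 2 & truth$fc_vs_b313 >= 10 &
                 truth$strain != "B313", ]
hits <- paste(candidates$feature_id, candidates$strain)
planted <- paste(truth$feature_id, truth$strain)
cat(sprintf("recall %.2f, precision %.2f against the planted truth\n",
            mean(planted %in% hits), mean(hits %in% planted)))
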