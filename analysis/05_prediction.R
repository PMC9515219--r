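#!/usr/bin/env Rscript
# Stage 5 — nested cross-validated LASSO prediction of the shared dimension
# from the multiscale panel: 5 outer x 5 inner folds, penalty chosen by
# lowest inner-CV MAE, 100 repeats, and a 500-shuffle region-permutation
# test of the mean out-of-fold correlation.

suppressPackageStartupMessages(library(transgrad))

meta <- read_parcellation_meta("results/data/meta.tsv")
scores <- read_parcel_table("results/shared_dimension/scores.tsv", meta, "panel")
pc1 <- parcel_map(scores$values[, 1], meta, "PC1")
panel <- read_parcel_table("results/features/panel.tsv", meta, "panel")

pred <- nested_lasso_predict(panel, pc1, n_repeats = 100, seed = 21L)
pred <- permutation_test_prediction(panel, pc1, n_perm = 500, seed = 22L,
                                    observed = pred)
cat(sprintf("prediction of the shared dimension: r = %.3f +/- %.3f, MAE = %.3f +/- %.3f, p_perm = %.4g\n",
            mean(pred$r), sd(pred$r), mean(pred$mae), sd(pred$mae), pred$p_perm))

sel <- data.frame(feature = names(pred$selection_frequency),
                  selection_frequency = unname(pred$selection_frequency))
sel <- sel[order(-sel$selection_frequency), ]
cat("most frequently selected features:\n")
print(utils::head(sel, 5), row.names = FALSE)

dir.create("results/prediction", showWarnings = FALSE, recursive = TRUE)
write.table(sel, "results/prediction/selection_frequency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(mean_r = mean(pred$r), sd_r = sd(pred$r),
                          mean_mae = mean(pred$mae), sd_mae = sd(pred$mae),
                          p_perm = pred$p_perm),
                     "results/prediction/summary.json",
                     auto_unbox = TRUE, digits = NA)
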