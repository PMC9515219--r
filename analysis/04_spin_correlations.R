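#!/usr/bin/env Rscript
# Stage 4 — spin-test correlations of the shared dimension with every
# multiscale feature.
#
# The panel concatenates the two gradients, the five profile features and the
# ten transmitter maps (rescaled to 0-100). Significance of each Pearson
# correlation comes from 1000 hemisphere-preserving spherical rotations of
# the shared-dimension map, with BH-FDR across the panel.

suppressPackageStartupMessages(library(transgrad))

meta <- read_parcellation_meta("results/data/meta.tsv")
scores <- read_parcel_table("results/shared_dimension/scores.tsv", meta, "panel")
pc1 <- parcel_map(scores$values[, 1], meta, "PC1")
grads <- read_parcel_table("results/features/gradients.tsv", meta, "panel")
cyto <- read_parcel_table("results/features/cyto_features.tsv", meta, "panel")
tx <- read_parcel_table("results/data/transmitters.tsv", meta, "panel")
tx_scaled <- vapply(seq_along(tx$features), function(j)
  rescale_0_100(parcel_map(tx$values[, j], meta))$values, numeric(68))
panel <- feature_panel(cbind(grads$values, cyto$values, tx_scaled), meta,
                       features = c(grads$features, cyto$features, tx$features))
write_parcel_table(panel, "results/features/panel.tsv")

spins <- generate_spins(meta, n_rotations = 1000, seed = 11L)
tab <- test_feature_panel(pc1, panel, spins)
dir.create("results/correlations", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/correlations/spin_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- tab[tab$q_fdr < 0.05, ]
cat(sprintf("%d of %d features significant after spin-FDR (q < 0.05):\n",
            nrow(sig), nrow(tab)))
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %-22s r = %+.3f  p_spin = %.4f  q = %.4f\n",
              sig$feature[i], sig$r[i], sig$p_spin[i], sig$q_fdr[i]))
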