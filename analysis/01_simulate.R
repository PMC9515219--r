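#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Emulates the inputs of a transdiagnostic cortical-thickness analysis on a
# 68-region parcellation: six condition-wise effect-size maps sharing one
# planted disease dimension (loadings 1, 1, 1, 0.8, 0.8, 0.6; condition noise
# sized so the shared component carries ~half the variance), 14-depth
# intracortical intensity profiles whose peak depth tracks the planted map,
# connectivity with the planted map as its principal axis, and ten
# transmitter-style maps, two of them informative. Everything downstream
# reads these tables from disk.

suppressPackageStartupMessages(library(transgrad))

seed <- 1L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
meta <- make_parcellation(cfg)
shared <- simulate_smooth_map(meta, cfg$lengthscale, seed = seed + 100L)
effects <- simulate_effect_matrix(meta, shared, cfg)

s01 <- (shared$values - min(shared$values)) / diff(range(shared$values))
peak_map <- parcel_map(0.1 + 0.8 * (1 - s01), meta, "peak_depth")
amp_map <- parcel_map(rep(2, 68), meta, "amplitude")
profiles <- simulate_profiles(meta, peak_map, amp_map,
                              n_depths = cfg$profile_depths, seed = seed + 101L)
conn <- simulate_connectivity(meta, shared, noise = 0.02, seed = seed + 102L)
tx <- simulate_feature_panel(meta, shared,
  sim_config(seed = seed + 103L, n_features = 10L, informative_features = 1:2,
             effect_beta = c(1, 1)))
tx <- feature_panel(tx$values, meta,
                    features = c("D1", "D2", "5HT1a", "5HT1b", "5HT2a",
                                 "FDOPA", "GABAa", "DAT", "NAT", "SERT"),
                    provenance = rep("transmitter", 10))

write_parcellation_meta(meta, file.path(data_dir, "meta.tsv"))
write_parcel_table(effects, file.path(data_dir, "effects.tsv"))
write_parcel_table(feature_panel(profiles$intensities, meta,
                                 features = sprintf("d%02d", 1:cfg$profile_depths)),
                   file.path(data_dir, "profiles.tsv"))
write_parcel_table(conn, file.path(data_dir, "connectivity.tsv"))
write_parcel_table(tx, file.path(data_dir, "transmitters.tsv"))
jsonlite::write_json(list(planted_shared = unname(shared$values),
                          planted_peak = unname(peak_map$values),
                          informative_transmitters = c("D1", "D2")),
                     file.path(data_dir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d regions x %d conditions plus profiles/connectivity/transmitters to %s\n",
            68, length(cfg$shared_loadings), data_dir))
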