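#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' stage parameter at its reference value: PCA with column centering only,
#' connectivity sparsified at 10% row density, diffusion embedding with
#' alpha = 0.5 and t = 0, 1000 spin rotations, 5/5 nested CV folds, 100
#' repeats and 1000 target-shuffling permutations. The `simulation` block
#' holds the [sim_config()] fields; a config may instead point `inputs` at
#' TSV files produced elsewhere.
#'
#' @param seed master seed recorded into every stochastic stage.
#' @return A nested list; amenable to `yaml::write_yaml()` /
#'   [load_pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulation = list(n_regions_per_hemisphere = 34L, lengthscale = 0.6,
                         shared_loadings = c(1, 1, 1, 0.8, 0.8, 0.6),
                         noise_sd = 0.88, profile_depths = 14L,
                         n_transmitters = 10L, informative_transmitters = 2L,
                         transmitter_beta = 1, transmitter_noise_sd = sqrt(3)),
       shared_dimension = list(scaling_mode = "center", run_loco = TRUE),
       gradients = list(density = 0.1, alpha = 0.5, t = 0, n_components = 5L),
       spatial = list(n_spins = 1000L),
       prediction = list(k_outer = 5L, k_inner = 5L, n_repeats = 100L,
                         run_permutation = TRUE, n_perm = 1000L,
                         reduced_repeats = 1L))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()], so a
#' config file only needs to state what deviates from the defaults.
#'
#' @param path YAML file.
#' @return A configuration list.
#' @export
load_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_cfg(default_pipeline_config(), user)
}

write_conn_table <- function(conn, path) write_parcel_table(conn, path)

read_conn_table <- function(path, meta, kind) {
  fp <- read_parcel_table(path, meta, container = "panel")
  connectivity_matrix(fp$values, meta, kind = kind)
}

read_profiles_table <- function(path, meta) {
  fp <- read_parcel_table(path, meta, container = "panel")
  profile_set(fp$values, meta, source = "from-disk")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or ingestion of supplied
#' tables), shared-dimension extraction with leave-one-condition-out and
#' community/hierarchy stratification, profile moments and
#' externopyramidization, microstructural and functional gradient
#' estimation, spin-test correlation of the shared dimension against the
#' assembled multiscale feature panel with FDR correction, and nested LASSO
#' prediction with an optional region-shuffling permutation test.
#'
#' Every stage writes its outputs as TSV/JSON under `out_dir` and downstream
#' stages re-read those files, so any stage can be rerun independently. The
#' consolidated machine-readable report lands in `report.json`; a one-line-
#' per-stage log with parameters and seeds in `pipeline.log`. Deterministic
#' for a fixed config.
#'
#' @param config a configuration list ([default_pipeline_config()] or
#'   [load_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = logfile)
  log_stage <- function(stage, ...) {
    kv <- c(...)
    cat(sprintf("%s\t%s\n", stage,
                paste(names(kv), unname(kv), sep = "=", collapse = " ")),
        file = logfile, append = TRUE)
  }
  seed <- config$seed
  report <- list(seed = seed)

  ## stage 1: simulate ------------------------------------------------------
  sim <- config$simulation
  cfg <- sim_config(n_regions_per_hemisphere = sim$n_regions_per_hemisphere,
                    seed = seed, lengthscale = sim$lengthscale,
                    shared_loadings = unlist(sim$shared_loadings),
                    noise_sd = sim$noise_sd,
                    profile_depths = sim$profile_depths)
  meta <- make_parcellation(cfg)
  shared <- simulate_smooth_map(meta, cfg$lengthscale, seed = child_seed(seed, 1L))
  effects <- simulate_effect_matrix(meta, shared, cfg)
  s01 <- (shared$values - min(shared$values)) / diff(range(shared$values))
  peak_map <- parcel_map(0.1 + 0.8 * (1 - s01), meta, "peak_depth")
  amp_raw <- simulate_smooth_map(meta, cfg$lengthscale, child_seed(seed, 2L))$values
  amp_map <- parcel_map(1 + 0.5 * (amp_raw - min(amp_raw)) / diff(range(amp_raw)),
                        meta, "amplitude")
  profiles <- simulate_profiles(meta, peak_map, amp_map,
                                n_depths = cfg$profile_depths,
                                seed = child_seed(seed, 3L))
  conn <- simulate_connectivity(meta, shared, noise = 0.02,
                                seed = child_seed(seed, 4L))
  tx_cfg <- sim_config(n_regions_per_hemisphere = sim$n_regions_per_hemisphere,
                       seed = child_seed(seed, 5L), lengthscale = sim$lengthscale,
                       n_features = sim$n_transmitters,
                       informative_features = seq_len(sim$informative_transmitters),
                       effect_beta = rep(sim$transmitter_beta,
                                         sim$informative_transmitters),
                       feature_noise_sd = sim$transmitter_noise_sd)
  transmitters <- simulate_feature_panel(meta, shared, tx_cfg)
  tx_names <- c("D1", "D2", "5HT1a", "5HT1b", "5HT2a",
                "FDOPA", "GABAa", "DAT", "NAT", "SERT")[seq_len(sim$n_transmitters)]
  transmitters <- feature_panel(transmitters$values, meta, features = tx_names,
                                provenance = rep("transmitter", sim$n_transmitters))

  write_parcellation_meta(meta, file.path(out_dir, "meta.tsv"))
  write_parcel_table(effects, file.path(out_dir, "effects.tsv"))
  pr_panel <- feature_panel(profiles$intensities, meta,
                            features = sprintf("d%02d", seq_len(cfg$profile_depths)))
  write_parcel_table(pr_panel, file.path(out_dir, "profiles.tsv"))
  write_conn_table(conn, file.path(out_dir, "connectivity.tsv"))
  write_parcel_table(transmitters, file.path(out_dir, "transmitters.tsv"))
  truth <- list(planted_shared = unname(shared$values),
                planted_peak = unname(peak_map$values),
                planted_axis = unname(attr(conn, "planted_axis")),
                informative_transmitters = tx_names[seq_len(sim$informative_transmitters)])
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("simulate", seed = seed, regions = n_regions(meta),
            conditions = length(cfg$shared_loadings))

  ## stage 2: shared dimension ----------------------------------------------
  meta <- read_parcellation_meta(file.path(out_dir, "meta.tsv"))
  effects <- read_parcel_table(file.path(out_dir, "effects.tsv"), meta, "effects")
  sd_cfg <- config$shared_dimension
  fit <- fit_shared_dimension(effects, scaling_mode = sd_cfg$scaling_mode)
  pc1 <- scores_map(fit, 1L)
  write_parcel_table(feature_panel(fit$scores, meta), file.path(out_dir, "scores.tsv"))
  report$shared_dimension <- list(
    variance_explained = fit$variance_explained,
    pc1_recovery_r = unname(stats::cor(pc1$values, truth$planted_shared)))
  if (isTRUE(sd_cfg$run_loco)) {
    loco <- leave_one_condition_out(effects, fit, scaling_mode = sd_cfg$scaling_mode)
    utils::write.table(loco, file.path(out_dir, "loco.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$loco <- loco
  }
  report$stratification <- list(community = stratify_map(pc1, "community"),
                                hierarchy = stratify_map(pc1, "hierarchy"))
  log_stage("shared_dimension", scaling = sd_cfg$scaling_mode,
            ve1 = sprintf("%.4f", fit$variance_explained[1L]))

  ## stage 3: profile features ----------------------------------------------
  profiles <- read_profiles_table(file.path(out_dir, "profiles.tsv"), meta)
  moments <- profile_moments(profiles)
  ep <- externopyramidization(profiles)
  cyto <- feature_panel(cbind(moments$values, externopyramidization = ep$values),
                        meta, provenance = c(moments$provenance, "externopyramidization"))
  write_parcel_table(cyto, file.path(out_dir, "cyto_features.tsv"))
  report$profile_features <- list(
    ep_peak_depth_rho = unname(stats::cor(ep$values, truth$planted_peak,
                                          method = "spearman")))
  log_stage("profile_features", depths = length(profiles$depth_fractions))

  ## stage 4: gradients ------------------------------------------------------
  g_cfg <- config$gradients
  conn <- read_conn_table(file.path(out_dir, "connectivity.tsv"), meta, "functional")
  mpc <- build_mpc(profiles)
  g_fc <- connectivity_gradients(conn, density = g_cfg$density,
                                 alpha = g_cfg$alpha, t = g_cfg$t,
                                 n_components = g_cfg$n_components)
  g_mpc <- connectivity_gradients(mpc, density = g_cfg$density,
                                  alpha = g_cfg$alpha, t = g_cfg$t,
                                  n_components = g_cfg$n_components)
  grads <- feature_panel(cbind(gradient_mpc = g_mpc$gradients[, 1L],
                               gradient_fc = g_fc$gradients[, 1L]),
                         meta, provenance = c("gradient", "gradient"))
  write_parcel_table(grads, file.path(out_dir, "gradients.tsv"))
  report$gradients <- list(
    fc_axis_recovery_rho = unname(abs(stats::cor(g_fc$gradients[, 1L],
                                                 truth$planted_axis,
                                                 method = "spearman"))),
    fc_eigenvalues = g_fc$eigenvalues[seq_len(3L)],
    mpc_eigenvalues = g_mpc$eigenvalues[seq_len(3L)])
  log_stage("gradients", density = g_cfg$density, alpha = g_cfg$alpha, t = g_cfg$t)

  ## stage 5: spin correlations ----------------------------------------------
  sp_cfg <- config$spatial
  grads <- read_parcel_table(file.path(out_dir, "gradients.tsv"), meta, "panel")
  cyto <- read_parcel_table(file.path(out_dir, "cyto_features.tsv"), meta, "panel")
  transmitters <- read_parcel_table(file.path(out_dir, "transmitters.tsv"), meta, "panel")
  tx_rescaled <- vapply(seq_along(transmitters$features), function(j)
    rescale_0_100(parcel_map(transmitters$values[, j], meta))$values,
    numeric(n_regions(meta)))
  panel <- feature_panel(cbind(grads$values, cyto$values, tx_rescaled), meta,
                         features = c(grads$features, cyto$features,
                                      transmitters$features))
  scores <- read_parcel_table(file.path(out_dir, "scores.tsv"), meta, "panel")
  pc1 <- parcel_map(scores$values[, 1L], meta, "PC1")
  spins <- generate_spins(meta, n_rotations = sp_cfg$n_spins,
                          seed = child_seed(seed, 6L))
  corr_tab <- test_feature_panel(pc1, panel, spins)
  utils::write.table(corr_tab, file.path(out_dir, "correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_parcel_table(panel, file.path(out_dir, "panel.tsv"))
  report$correlations <- corr_tab
  log_stage("spin_correlations", n_spins = sp_cfg$n_spins,
            seed = child_seed(seed, 6L))

  ## stage 6: prediction ------------------------------------------------------
  p_cfg <- config$prediction
  panel <- read_parcel_table(file.path(out_dir, "panel.tsv"), meta, "panel")
  pred <- nested_lasso_predict(panel, pc1, k_outer = p_cfg$k_outer,
                               k_inner = p_cfg$k_inner,
                               n_repeats = p_cfg$n_repeats,
                               seed = child_seed(seed, 7L))
  if (isTRUE(p_cfg$run_permutation))
    pred <- permutation_test_prediction(panel, pc1, n_perm = p_cfg$n_perm,
                                        seed = child_seed(seed, 8L),
                                        reduced_repeats = p_cfg$reduced_repeats,
                                        observed = pred,
                                        k_outer = p_cfg$k_outer,
                                        k_inner = p_cfg$k_inner)
  sel <- data.frame(feature = names(pred$selection_frequency),
                    selection_frequency = unname(pred$selection_frequency))
  utils::write.table(sel, file.path(out_dir, "selection_frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$prediction <- list(mean_r = mean(pred$r), sd_r = stats::sd(pred$r),
                            mean_mae = mean(pred$mae), sd_mae = stats::sd(pred$mae),
                            p_perm = pred$p_perm,
                            selection_frequency = pred$selection_frequency)
  log_stage("prediction", repeats = p_cfg$n_repeats,
            mean_r = sprintf("%.4f", mean(pred$r)))

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(report)
}
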