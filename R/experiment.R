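#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end cross-instrument
#' experiment: simulation settings, SPXY split size, standard-set
#' sizes per transfer method, transfer hyperparameters, classifier
#' grids and seeds. Defaults reproduce the reference design: 144
#' samples (48 per class) measured on both instruments, a 2:1
#' train:prediction SPXY split, standard sets of 15/10/20 for
#' PDS/SST/ATLD, PDS window width 25 with 6 components, 6 SST
#' components, 2 ATLD factors, and three 60x60 spliced cubes at ratios
#' 0.5:1:2, 1:1:1 and 2:1:1.
#'
#' @param n_per_class samples per class.
#' @param n_train SPXY training-set size.
#' @param standards named integer vector of standard-set sizes.
#' @param pds_w,pds_components PDS window halfwidth and components.
#' @param sst_components SST retained components.
#' @param atld_factors ATLD factors.
#' @param svm_C_grid,svm_gamma_grid SVM search grids.
#' @param plsda_max_components PLS-DA component-search cap.
#' @param cube_ratios list of beef:chicken:duck ratio triples
#'   (class order alphabetical: beef, chicken, duck).
#' @param cube_shape `c(rows, cols)` of the spliced cubes.
#' @param cube_noise_sd slave noise used for the cubes.
#' @param within_class_sd within-class variability of the species
#'   models.
#' @param size_k_grid standard-set sizes evaluated for the sizing
#'   curve.
#' @param seed master seed; all stage seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_per_class = 48L,
                              n_train = 96L,
                              standards = c(pds = 15L, sst = 10L, atld = 20L),
                              pds_w = 12L, pds_components = 6L,
                              sst_components = 6L,
                              atld_factors = 2L,
                              svm_C_grid = c(1, 10, 100),
                              svm_gamma_grid = c(0.01, 0.1, 1),
                              plsda_max_components = 12L,
                              cube_ratios = list(c(0.5, 1, 2), c(1, 1, 1),
                                                 c(2, 1, 1)),
                              cube_shape = c(60L, 60L),
                              cube_noise_sd = 0.004,
                              within_class_sd = 0.05,
                              size_k_grid = c(3L, 5L, 10L, 15L, 20L, 25L),
                              seed = 1L) {
  cfg <- as.list(environment())
  m <- length(default_meat_models()) * n_per_class
  if (n_train >= m) stop("n_train must be smaller than the sample count")
  if (max(standards) > n_train) stop("standard sets larger than training set")
  if (max(cfg$size_k_grid) > n_train) stop("size_k_grid exceeds training set")
  class(cfg) <- "experiment_config"
  cfg
}

#' Read / write an experiment configuration as YAML
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns an `experiment_config` (unknown
#'   keys are rejected).
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$standards)) raw$standards <- unlist(raw$standards)
  do.call(experiment_config, raw)
}

#' Run the full cross-instrument experiment
#'
#' Executes the complete pipeline on synthetic data: paired
#' master/slave acquisition, resampling to the common 400-800 nm
#' slave grid, SPXY partitioning, standard-set sizing curve, fitting
#' of the three transfers, spectral-angle/correlation diagnostics
#' before and after transfer, master-trained PLS-DA and SVM applied
#' to the slave test set before and after transfer, and pixel-wise
#' mapping of three spliced cubes with proportion recovery. Writes
#' four CSV reports (`transfer_diagnostics.csv`, `sizing_curve.csv`,
#' `accuracy_comparison.csv`, `proportion_recovery.csv`), one PNG map
#' per cube and transfer state, and `manifest.json`.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of class `run_manifest` with the config,
#'   its hash, seeds, report paths and the in-memory result tables.
#' @export
run_experiment <- function(config = experiment_config(), out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_transfer_study(config)
  paths <- list(
    transfer_diagnostics = file.path(out_dir, "transfer_diagnostics.csv"),
    sizing_curve = file.path(out_dir, "sizing_curve.csv"),
    accuracy_comparison = file.path(out_dir, "accuracy_comparison.csv"),
    proportion_recovery = file.path(out_dir, "proportion_recovery.csv"))
  utils::write.csv(res$diagnostics, paths$transfer_diagnostics,
                   row.names = FALSE)
  utils::write.csv(res$sizing_curve, paths$sizing_curve, row.names = FALSE)
  utils::write.csv(res$accuracy, paths$accuracy_comparison,
                   row.names = FALSE)
  utils::write.csv(res$proportion_table, paths$proportion_recovery,
                   row.names = FALSE)
  map_paths <- character(0)
  for (nm in names(res$maps)) {
    p <- file.path(out_dir, paste0("map_", nm, ".png"))
    render_map(res$maps[[nm]], p)
    map_paths[nm] <- p
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_experiment_config(config, cfg_path)
  manifest <- structure(
    list(config = config,
         config_hash = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         paths = c(paths, list(maps = map_paths, config = cfg_path)),
         version = as.character(utils::packageVersion("hsitransfer")),
         results = res),
    class = "run_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         version = manifest$version,
         paths = lapply(manifest$paths, unname)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Core computation of the experiment (no files written)
#'
#' Same stages as [run_experiment()] but returning the result tables
#' directly; useful for seed sweeps and testing.
#'
#' @param config an [experiment_config()].
#' @param with_cubes simulate and classify the spliced cubes (the most
#'   expensive stage); set `FALSE` for diagnostics-only runs.
#' @param with_sizing compute the standard-set sizing curve.
#' @return list with `diagnostics`, `sizing_curve`, `accuracy`,
#'   `proportion_table`, `maps`, and the fitted `models`.
#' @export
run_transfer_study <- function(config = experiment_config(),
                               with_cubes = TRUE, with_sizing = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- as.integer(config$seed)
  models <- default_meat_models(within_class_sd = config$within_class_sd)
  pair <- generate_paired_sets(models, n_per_class = config$n_per_class,
                               seed = seed)
  grid <- pair$slave$wavelengths_nm
  master <- resample_to_grid(pair$master, grid)
  slave <- pair$slave
  split <- spxy_split(master$spectra, master$labels, config$n_train)
  tr <- split$train_indices
  te <- split$prediction_indices
  std_idx <- lapply(config$standards, function(k)
    select_standard_samples(split, k))
  Xm_tr <- master$spectra[tr, , drop = FALSE]
  Xm_te <- master$spectra[te, , drop = FALSE]
  Xs_te <- slave$spectra[te, , drop = FALSE]
  transfers <- list(
    pds = fit_pds(master$spectra[std_idx$pds, ], slave$spectra[std_idx$pds, ],
                  w = config$pds_w, n_components = config$pds_components),
    sst = fit_sst(master$spectra[std_idx$sst, ], slave$spectra[std_idx$sst, ],
                  n_components = config$sst_components),
    atld = fit_atld(master$spectra[std_idx$atld, ],
                    slave$spectra[std_idx$atld, ],
                    n_factors = config$atld_factors))
  diag_rows <- lapply(c(list(none = NULL), transfers), function(mod) {
    Xt <- transfer_spectra(mod, Xs_te)
    d <- transfer_diagnostics(Xm_te, Xt)
    data.frame(mean_angle_deg = d$mean_angle_deg,
               mean_correlation = d$mean_correlation)
  })
  diagnostics <- cbind(
    data.frame(method = names(diag_rows),
               n_standards = c(0L, unname(config$standards))),
    do.call(rbind, diag_rows))
  rownames(diagnostics) <- NULL
  sizing <- NULL
  if (with_sizing) {
    cand <- select_standard_samples(split, max(config$size_k_grid))
    sizing <- size_standard_set(
      master$spectra[cand, , drop = FALSE], slave$spectra[cand, , drop = FALSE],
      function(m, s) fit_sst(m, s, n_components =
                               min(config$sst_components, nrow(m) - 1L)),
      config$size_k_grid, Xm_te, Xs_te)
    best_k <- attr(sizing, "best_k")
    sizing <- cbind(method = "sst", sizing)
    attr(sizing, "best_k") <- best_k
  }
  classifiers <- list(
    plsda = fit_plsda(Xm_tr, master$labels[tr],
                      max_components = config$plsda_max_components,
                      seed = seed + 11L),
    svm = fit_svm(Xm_tr, master$labels[tr], C_grid = config$svm_C_grid,
                  gamma_grid = config$svm_gamma_grid, seed = seed + 12L))
  accuracy <- before_after_comparison(Xs_te, slave$labels[te],
                                      transfers, classifiers)
  prop_rows <- list(); maps <- list()
  if (with_cubes) {
    slave_cube_instr <- slave_instrument(noise_sd = config$cube_noise_sd)
    for (ri in seq_along(config$cube_ratios)) {
      ratio <- config$cube_ratios[[ri]]
      cube <- generate_spliced_cube(models, proportions = ratio,
                                    shape = config$cube_shape,
                                    slave = slave_cube_instr,
                                    seed = seed + 100L * ri)
      for (state in c("none", "sst")) {
        mod <- if (state == "sst") transfers$sst else NULL
        map <- classify_cube(cube, classifiers$svm, transfer = mod)
        pr <- proportions(map, cube)
        prop_rows[[length(prop_rows) + 1L]] <- cbind(
          data.frame(cube = paste(ratio, collapse = ":"), transfer = state),
          pr)
        maps[[paste0("ratio", ri, "_", state)]] <- map
      }
    }
  }
  list(diagnostics = diagnostics, sizing_curve = sizing,
       accuracy = accuracy,
       proportion_table = if (length(prop_rows)) do.call(rbind, prop_rows),
       maps = maps,
       models = list(split = split, transfers = transfers,
                     classifiers = classifiers, common_grid = grid))
}
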