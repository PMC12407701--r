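# End-to-end pipeline: generate or read data, fit families, rank, classify,
# intersect; with a manifest recording seeds and settings.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: optimization
#' bounds, integration tolerances during fitting, multistart budget, the
#' fixed low protein initial condition, the noise-scale floor, scaling scope,
#' acceptability rule and classifier settings. Every stochastic stage draws
#' its seed deterministically from `seed`.
#'
#' @param experiments character vector of experiments to run.
#' @param data optional named list of expression tibbles per experiment; if
#'   `NULL`, synthetic data are generated from `true_model_label` under the
#'   experimental design.
#' @param true_model_label generating structure for synthetic data (a name
#'   from [named_models()]).
#' @param cv synthetic noise level.
#' @param n_starts multistart budget per model.
#' @param seed master seed.
#' @param max_models optional cap on the number of family members fitted per
#'   experiment (lowest indices first); `NULL` fits the full family.
#' @param accept_mode,accept_k acceptability rule (see
#'   [select_acceptance_threshold()]); `accept_k` may be a fraction (< 1) of
#'   the fitted structures or an absolute count.
#' @param max_depth,k_folds classifier settings.
#' @param scaling_scope [max_scale()] scope applied to each dataset.
#' @param preset_p0,sigma_floor,rtol,atol,maxit,n_hops numerical settings
#'   (see [fit_model()]).
#' @return A `grn_config` list.
#' @export
grn_config <- function(experiments = c("WT", "eud1_KO", "sult1_KO"),
                       data = NULL, true_model_label = "model_11574",
                       cv = 0.2, n_starts = 50, seed = 1, max_models = NULL,
                       accept_mode = "rank_k", accept_k = 0.0723,
                       max_depth = 5, k_folds = 5,
                       scaling_scope = "experiment_global",
                       preset_p0 = 1e-3, sigma_floor = 1e-6,
                       rtol = 1e-6, atol = 1e-8, maxit = 200, n_hops = 20) {
  structure(
    list(experiments = experiments, data = data,
         true_model_label = true_model_label, cv = cv, n_starts = n_starts,
         seed = seed, max_models = max_models, accept_mode = accept_mode,
         accept_k = accept_k, max_depth = max_depth, k_folds = k_folds,
         scaling_scope = scaling_scope, preset_p0 = preset_p0,
         sigma_floor = sigma_floor, rtol = rtol, atol = atol, maxit = maxit,
         n_hops = n_hops),
    class = "grn_config"
  )
}

experiment_family <- function(experiment) {
  switch(experiment,
    WT = build_family(),
    eud1_KO = knockout_family("eud-1"),
    sult1_KO = knockout_family("sult-1"),
    abort(sprintf("unknown experiment %s.", experiment))
  )
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain each experiment's dataset (supplied or synthetic) and
#' max-scale it; (2) fit the experiment's model family; (3) rank the fits
#' into a cost curve and label acceptability; (4) for the wild-type
#' experiment, train the acceptability classifier on structural features and
#' extract its model set; (5) intersect the experiments' model sets. Writes
#' fit tables (TSV), model sets (JSON) and a manifest (JSON, with the master
#' seed, per-stage seeds and settings) into `out_dir`.
#'
#' @param config a [grn_config()].
#' @param out_dir output directory (created if missing); per-model fit
#'   checkpoints go into `out_dir/checkpoints/<experiment>`.
#' @return Invisibly, a list with `datasets`, `fits`, `curves`, `sets`,
#'   `classifier`, `intersection` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("grn_run_")) {
  stopifnot(inherits(config, "grn_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(),
                   settings = config[setdiff(names(config), "data")])
  opts <- list(maxit = config$maxit, preset_p0 = config$preset_p0,
               sigma_floor = config$sigma_floor, rtol = config$rtol,
               atol = config$atol, n_hops = config$n_hops)
  datasets <- list(); fits <- list(); curves <- list(); sets <- list()
  classifier <- NULL
  for (exp in config$experiments) {
    design <- experimental_design(exp)
    family <- experiment_family(exp)
    data_seed <- derive_seed(config$seed, match(exp, config$experiments))
    data <- config$data[[exp]]
    if (is.null(data)) {
      truth <- named_models()[[config$true_model_label]]
      model <- if (is.null(design$knockout)) truth else {
        reduce_for_knockout(truth, design$knockout)
      }
      data <- generate_dataset(model, reference_params(model),
                               times = design$times,
                               replicates = design$replicates,
                               cv = config$cv, seed = data_seed,
                               experiment = exp)
    }
    data <- max_scale(data, scope = config$scaling_scope)
    datasets[[exp]] <- data
    indices <- seq_len(family$size) - 1
    if (!is.null(config$max_models)) {
      indices <- head(indices, config$max_models)
    }
    fit_seed <- derive_seed(config$seed, 100 + match(exp, config$experiments))
    fits[[exp]] <- fit_family(
      family, dplyr::select(data, -"experiment"), n_starts = config$n_starts,
      seed = fit_seed, indices = indices,
      checkpoint_dir = file.path(out_dir, "checkpoints", exp),
      options = opts
    )
    curve <- cost_curve(fits[[exp]])
    k <- if (config$accept_k < 1) {
      max(1, round(config$accept_k * nrow(curve)))
    } else config$accept_k
    curve <- select_acceptance_threshold(curve, mode = config$accept_mode,
                                         k = k)
    curves[[exp]] <- curve
    sets[[exp]] <- grn_model_set(
      curve$model_index[curve$acceptable], experiment = exp,
      description = paste0(config$accept_mode, " acceptability"),
      knockout = family$knockout
    )
    readr::write_tsv(
      dplyr::select(curve, -dplyr::any_of("theta")),
      file.path(out_dir, paste0("fits_", exp, ".tsv"))
    )
    model_set_to_json(sets[[exp]],
                      file.path(out_dir, paste0("set_", exp, ".json")))
    manifest$stages[[exp]] <- list(data_seed = data_seed,
                                   fit_seed = fit_seed,
                                   n_models = length(indices))
  }
  if ("WT" %in% names(curves) && !is.null(config$max_models)) {
    # classifier trained on the fitted subset's features
    wt_curve <- curves$WT
    feats <- family_feature_matrix()[wt_curve$model_index + 1, ]
    classifier <- train_acceptability_classifier(
      feats, wt_curve$acceptable,
      max_depth = config$max_depth, k_folds = config$k_folds,
      seed = derive_seed(config$seed, 999)
    )
  } else if ("WT" %in% names(curves)) {
    wt_curve <- curves$WT
    feats <- family_feature_matrix()
    labels <- logical(nrow(feats))
    labels[wt_curve$model_index[wt_curve$acceptable] + 1] <- TRUE
    classifier <- train_acceptability_classifier(
      feats, labels, max_depth = config$max_depth, k_folds = config$k_folds,
      seed = derive_seed(config$seed, 999)
    )
  }
  intersection <- if (length(sets) > 1 && "WT" %in% names(sets)) {
    intersect_model_sets(unname(sets))
  }
  if (!is.null(intersection)) {
    model_set_to_json(intersection, file.path(out_dir, "set_intersection.json"))
  }
  manifest$versions <- list(grnsets = as.character(utils::packageVersion("grnsets")),
                            R = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(datasets = datasets, fits = fits, curves = curves,
                 sets = sets, classifier = classifier,
                 intersection = intersection, manifest = manifest,
                 out_dir = out_dir))
}
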