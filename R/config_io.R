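#' Build an experiment configuration from a YAML file
#'
#' The YAML mirrors the constructor arguments, with one top-level block per
#' component (`phantom`, `lesion_model`, `design`, `features`, `policy`) plus
#' scalar fields `k`, `thresholds`, `selection_sets`, `seed`. Missing blocks
#' fall back to the package defaults, so a minimal file may set only what it
#' changes, e.g.:
#'
#' ```yaml
#' phantom: {grid_shape: [32, 32, 32], n_paired: 40, n_external: 20}
#' design:  {sample_sizes: [5, 10, 20], n_draws: 20}
#' seed: 7
#' ```
#'
#' @param path YAML file path.
#' @param seed optional master-seed override.
#' @return A [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    if (is.null(raw[[block]])) ctor() else do.call(ctor, raw[[block]])
  }
  args <- list(
    phantom = build("phantom", phantom_params),
    lesion_model = build("lesion_model", lesion_volume_model),
    design = build("design", design_params),
    features = build("features", feature_config),
    policy = build("policy", training_point_policy))
  for (f in c("k", "thresholds", "selection_sets"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  args$seed <- if (!is.null(seed)) seed else raw$seed %||% 1L
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
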