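#' Full experiment configuration
#'
#' Bundles the phantom, population model, resampling design, classifier and
#' evaluation settings for an end-to-end run. The experiment master `seed`
#' drives every stage through named substreams (cohort generation, each
#' (size, replicate) draw, each model fit), overriding `phantom$seed`.
#'
#' @param phantom a [phantom_params()].
#' @param lesion_model a [lesion_volume_model()].
#' @param design a [design_params()].
#' @param features a [feature_config()].
#' @param policy a [training_point_policy()].
#' @param k neighbour count for the classifier.
#' @param thresholds probability threshold grid (default 0 to 1 by 0.1, 11
#'   values).
#' @param selection_sets validation sets used for global threshold selection
#'   (default: the two internal sets).
#' @param seed master seed of the experiment.
#' @return An object of class `wmh_experiment_config`.
#' @seealso [experiment_profile()] for ready-made configurations.
#' @export
experiment_config <- function(phantom = phantom_params(),
                              lesion_model = lesion_volume_model(),
                              design = design_params(),
                              features = feature_config(),
                              policy = training_point_policy(),
                              k = 40L,
                              thresholds = seq(0, 1, by = 0.1),
                              selection_sets = c("internal_bl", "internal_fu"),
                              seed = 1L) {
  stopifnot(inherits(phantom, "wmh_phantom_params"),
            inherits(lesion_model, "wmh_lesion_model"),
            inherits(design, "wmh_design_params"),
            inherits(features, "wmh_feature_config"),
            inherits(policy, "wmh_point_policy"))
  if (any(thresholds < 0 | thresholds > 1) || is.unsorted(thresholds))
    stop("`thresholds` must be an increasing grid in [0, 1]", call. = FALSE)
  if (any(design$sample_sizes > phantom$n_paired))
    stop("sample sizes must not exceed the paired-participant count",
         call. = FALSE)
  if (!all(selection_sets %in% c("internal_bl", "internal_fu", "external")))
    stop("unknown validation set in `selection_sets`", call. = FALSE)
  structure(
    list(phantom = phantom, lesion_model = lesion_model, design = design,
         features = features, policy = policy, k = as.integer(k),
         thresholds = as.numeric(thresholds),
         selection_sets = selection_sets, seed = as.integer(seed)),
    class = "wmh_experiment_config")
}

#' Built-in experiment profiles
#'
#' * `"toy"` — 8 paired + 4 external subjects on 24^3 grids, sizes \{2, 4\},
#'   5 draws: finishes in seconds, used by the test suite.
#' * `"scaled"` — 40 paired + 20 external subjects on 32^3 grids, sizes
#'   \{5, 10, 20\}, 20 draws, reference caps 200/1000: a desk-scale version of
#'   the study that preserves its qualitative behaviour (minutes).
#' * `"full"` — 80 paired + 41 external subjects on 64^3 grids, sizes 10-40
#'   step 5, 100 draws, reference caps 2000/10000: the full study design
#'   (hours; intended for overnight runs).
#'
#' @param profile one of `"toy"`, `"scaled"`, `"full"`.
#' @param seed master seed.
#' @return A [experiment_config()].
#' @export
experiment_profile <- function(profile = c("toy", "scaled", "full"),
                               seed = 1L) {
  profile <- match.arg(profile)
  switch(profile,
    toy = experiment_config(
      phantom = phantom_params(grid_shape = c(24, 24, 24), n_paired = 8L,
                               n_external = 4L),
      design = design_params(sample_sizes = c(2L, 4L), n_draws = 5L),
      policy = training_point_policy(100L, 500L),
      k = 15L, seed = seed),
    scaled = experiment_config(
      phantom = phantom_params(grid_shape = c(32, 32, 32), n_paired = 40L,
                               n_external = 20L),
      design = design_params(sample_sizes = c(5L, 10L, 20L), n_draws = 20L),
      policy = training_point_policy(200L, 1000L),
      k = 40L, seed = seed),
    full = experiment_config(
      phantom = phantom_params(grid_shape = c(64, 64, 64), n_paired = 80L,
                               n_external = 41L),
      design = design_params(sample_sizes = seq(10L, 40L, 5L), n_draws = 100L),
      policy = training_point_policy(2000L, 10000L),
      k = 40L, seed = seed))
}

# Strip S3 classes and expand named atomic vectors so a config serializes to
# plain JSON with names intact.
jsonify_config <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), jsonify_config)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

# Observations of a split as a single tibble with a validation_set column.
split_observations <- function(split) {
  dplyr::bind_rows(
    dplyr::mutate(split$internal_bl, validation_set = "internal_bl"),
    dplyr::mutate(split$internal_fu, validation_set = "internal_fu"),
    dplyr::mutate(split$external, validation_set = "external"))
}

# Volumes (ml) of one probability vector at every threshold, plus Dice
# against the manual mask, all from voxel counts.
threshold_metrics <- function(p, manual_vec, thresholds, voxel_ml) {
  a <- sum(manual_vec)
  vapply(thresholds, function(t) {
    keep <- if (t == 0) p > 0 else p >= t - 1e-9
    b <- sum(keep)
    inter <- sum(keep & manual_vec)
    dice <- if (a + b == 0) NA_real_ else 2 * inter / (a + b)
    c(pred_vox = b, dice = dice)
  }, c(pred_vox = 0, dice = 0))
}

#' Run the full resampling experiment
#'
#' Executes every stage: cohort generation, design enumeration, per-(size,
#' replicate) training draws with leakage-consistent splits, classifier
#' fitting, probability prediction on every validation observation, volume
#' and Dice extraction at every threshold, and summary/report emission
#' (via [report_experiment()]). Work units are (sample size, replicate)
#' pairs; each writes its raw records to `outdir/records/` as it completes,
#' and `resume = TRUE` skips finished units, so interrupted runs restart
#' where they stopped. Identical configurations (including seed) produce
#' byte-identical raw-record CSVs.
#'
#' @param config a [experiment_config()].
#' @param outdir output directory.
#' @param resume reuse finished work units found in `outdir/records/`. With
#'   `resume = FALSE` an `outdir` already containing records is an error, to
#'   avoid silently mixing runs.
#' @param plots also emit the report plots (default `FALSE`; see
#'   [report_experiment()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, the list returned by [report_experiment()], with the
#'   cohort attached as `cohort`.
#' @export
run_experiment <- function(config, outdir, resume = FALSE, plots = FALSE,
                           quiet = TRUE) {
  stopifnot(inherits(config, "wmh_experiment_config"))
  t0 <- Sys.time()
  records_dir <- file.path(outdir, "records")
  if (dir.exists(records_dir) && length(dir(records_dir)) > 0 && !resume)
    stop("`outdir` already contains records from a previous run; ",
         "use resume = TRUE to continue it or point to a fresh directory",
         call. = FALSE)
  dir.create(records_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(...) if (!quiet) message(sprintf(...))

  # --- stage: cohort -------------------------------------------------------
  phantom <- config$phantom
  phantom$seed <- substream_seed(config$seed, "cohort")
  say("generating cohort (%d paired + %d external)...",
      phantom$n_paired, phantom$n_external)
  cohort <- generate_cohort(phantom, config$lesion_model)
  obs_table <- cohort_observations(cohort)

  # --- stage: design -------------------------------------------------------
  design_tab <- enumerate_design(config$design, phantom$n_paired,
                                 phantom$n_external)
  write.csv(design_tab, file.path(outdir, "design.csv"), row.names = FALSE)

  # --- feature cache -------------------------------------------------------
  all_subjects <- c(cohort$resampling, cohort$external)
  keys <- vapply(all_subjects, function(s)
    paste(s$participant_id, s$timepoint, sep = "_"), "")
  voxel_ml <- prod(phantom$voxel_dims) / 1000
  cache <- lapply(all_subjects, function(s) {
    fx <- extract_features(s, config$features)
    list(features = fx$features,
         manual_vec = s$manual_mask[fx$voxels],
         manual_ml = sum(s$manual_mask) * voxel_ml)
  })
  names(cache) <- keys
  subj_by_key <- all_subjects
  names(subj_by_key) <- keys

  # --- stage: draws / fit / predict ---------------------------------------
  for (n in config$design$sample_sizes) {
    for (rep_i in seq_len(config$design$n_draws)) {
      draw_id <- sprintf("n%02d_r%03d", n, rep_i)
      unit_file <- file.path(records_dir, paste0(draw_id, ".csv"))
      members_file <- file.path(records_dir, paste0(draw_id, "_members.csv"))
      if (resume && file.exists(unit_file) && file.exists(members_file)) {
        say("unit %s already done, skipping", draw_id)
        next
      }
      draw <- draw_training_set(
        cohort, n, seed = substream_seed(config$seed, "draw", n, rep_i),
        replicate = rep_i)
      split <- build_split(draw, cohort)
      leak <- verify_no_leakage(draw, split, cohort)
      if (!leak$pass)
        stop("internal error: leakage detected in ", draw_id, call. = FALSE)

      train_keys <- paste(draw$members$participant_id, draw$members$timepoint,
                          sep = "_")
      classifier <- fit_wmh_classifier(
        subj_by_key[train_keys], k = config$k, policy = config$policy,
        config = config$features,
        seed = substream_seed(config$seed, "fit", n, rep_i),
        draw_id = draw_id)

      val <- split_observations(split)
      rows <- vector("list", nrow(val))
      for (i in seq_len(nrow(val))) {
        key <- paste(val$participant_id[i], val$timepoint[i], sep = "_")
        cx <- cache[[key]]
        p <- predict_probability_vector(classifier, cx$features)
        m <- threshold_metrics(p, cx$manual_vec, config$thresholds, voxel_ml)
        pred_ml <- m["pred_vox", ] * voxel_ml
        rows[[i]] <- tibble::tibble(
          draw_id = draw_id, sample_size = n, replicate = rep_i,
          participant_id = val$participant_id[i],
          timepoint = val$timepoint[i],
          validation_set = val$validation_set[i],
          threshold = config$thresholds,
          manual_ml = cx$manual_ml,
          predicted_ml = pred_ml,
          error_ml = signed_error(pred_ml, cx$manual_ml),
          dice = m["dice", ])
      }
      unit <- dplyr::bind_rows(rows)
      write.csv(unit, unit_file, row.names = FALSE)
      members <- dplyr::mutate(
        draw$members, draw_id = draw_id, sample_size = n, replicate = rep_i,
        manual_ml = vapply(train_keys, function(k2) cache[[k2]]$manual_ml, 0))
      write.csv(members, members_file, row.names = FALSE)
      say("unit %s done (%d records)", draw_id, nrow(unit))
    }
  }

  # --- stage: combine ------------------------------------------------------
  unit_files <- sort(dir(records_dir, pattern = "_members\\.csv$",
                         full.names = TRUE))
  draws_tab <- dplyr::bind_rows(lapply(unit_files, read.csv))
  rec_files <- sort(setdiff(dir(records_dir, pattern = "\\.csv$",
                                full.names = TRUE), unit_files))
  records <- dplyr::bind_rows(lapply(rec_files, read.csv))
  write.csv(records, file.path(outdir, "raw_records.csv"), row.names = FALSE)
  write.csv(draws_tab, file.path(outdir, "draws.csv"), row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  files <- file.path(outdir, c("design.csv", "raw_records.csv", "draws.csv"))
  manifest <- list(
    package_version = as.character(packageVersion("wmhresample")),
    config = jsonify_config(config),
    seeds = list(master = config$seed,
                 cohort = substream_seed(config$seed, "cohort")),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  # --- stage: summaries / report ------------------------------------------
  out <- report_experiment(outdir, plots = plots)
  out$cohort <- cohort
  invisible(out)
}
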