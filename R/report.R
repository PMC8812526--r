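#' Summarize a finished experiment from its raw records
#'
#' Recomputes every summary table of an experiment directly from
#' `raw_records.csv` and `draws.csv` (so deleting the summaries and
#' re-running the report reproduces them exactly):
#'
#' * `summaries` — per-model statistics (mean, SD, median, IQR of signed
#'   errors) by draw, validation set and threshold;
#' * `threshold_selection` — the per-threshold aggregate and the selected
#'   global threshold t*;
#' * `error_by_size` — mean (SD) across models of the per-model mean signed
#'   error, by sample size and validation set, at t*;
#' * `composition` — per-draw low-volume training proportions vs model error
#'   at t*, with a decile-binned summary;
#' * `stratified` — mean signed error and Dice by ground-truth volume
#'   stratum at t*.
#'
#' With `plots = TRUE` two figures are written: per-model mean error by
#' sample size (boxplots) and manual vs predicted volume with per-model
#' linear fits.
#'
#' @param outdir directory of a completed [run_experiment()] run.
#' @param plots write `error_by_size.pdf` and `volume_scatter.pdf`.
#' @return Invisibly, a list with elements `records`, `draws`, `summaries`,
#'   `selected_threshold`, `threshold_selection`, `error_by_size`,
#'   `composition`, `stratified`.
#' @export
report_experiment <- function(outdir, plots = TRUE) {
  rec_path <- file.path(outdir, "raw_records.csv")
  draws_path <- file.path(outdir, "draws.csv")
  man_path <- file.path(outdir, "manifest.json")
  if (!file.exists(rec_path) || !file.exists(draws_path) ||
      !file.exists(man_path))
    stop("`outdir` is not a completed run (missing raw_records.csv, ",
         "draws.csv or manifest.json)", call. = FALSE)
  records <- tibble::as_tibble(read.csv(rec_path))
  draws_tab <- tibble::as_tibble(read.csv(draws_path))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  thresholds <- manifest$config$thresholds
  selection_sets <- manifest$config$selection_sets

  # per-model summaries (same statistics as summarize_model)
  summaries <- dplyr::summarise(
    dplyr::group_by(records, .data$draw_id, .data$sample_size,
                    .data$validation_set, .data$threshold),
    n_observations = dplyr::n(),
    mean_error = mean(.data$error_ml),
    sd_error = ifelse(dplyr::n() > 1, sd(.data$error_ml), 0),
    median_error = median(.data$error_ml),
    iqr_error = unname(diff(quantile(.data$error_ml, c(0.25, 0.75),
                                     type = 7))),
    .groups = "drop")
  write.csv(summaries, file.path(outdir, "summaries.csv"), row.names = FALSE)

  sel <- select_threshold(summaries, sets = selection_sets,
                          thresholds = thresholds)
  sel_tab <- dplyr::mutate(sel$table, selected = .data$threshold == sel$threshold)
  write.csv(sel_tab, file.path(outdir, "threshold_selection.csv"),
            row.names = FALSE)

  at_star <- summaries[summaries$threshold == sel$threshold, ]
  error_by_size <- dplyr::summarise(
    dplyr::group_by(at_star, .data$sample_size, .data$validation_set),
    n_models = dplyr::n(),
    mean_of_means = mean(.data$mean_error),
    sd_of_means = ifelse(dplyr::n() > 1, sd(.data$mean_error), 0),
    .groups = "drop")
  write.csv(error_by_size, file.path(outdir, "error_by_size.csv"),
            row.names = FALSE)

  # model-level error at t* across all validation observations
  rec_star <- records[records$threshold == sel$threshold, ]
  model_errors <- dplyr::summarise(
    dplyr::group_by(rec_star, .data$draw_id),
    mean_error = mean(.data$error_ml), .groups = "drop")
  volumes <- dplyr::distinct(records, .data$participant_id, .data$timepoint,
                             .data$manual_ml)
  comp <- composition_analysis(
    draws_tab[c("draw_id", "participant_id", "timepoint")],
    volumes, model_errors)
  write.csv(comp$records, file.path(outdir, "composition.csv"),
            row.names = FALSE)
  write.csv(comp$binned, file.path(outdir, "composition_binned.csv"),
            row.names = FALSE)

  strat <- stratified_errors(rec_star)
  write.csv(strat, file.path(outdir, "stratified.csv"), row.names = FALSE)

  if (plots) {
    plot_error_by_size(at_star, file.path(outdir, "error_by_size.pdf"))
    plot_volume_scatter(rec_star, file.path(outdir, "volume_scatter.pdf"))
  }

  invisible(list(records = records, draws = draws_tab, summaries = summaries,
                 selected_threshold = sel$threshold,
                 threshold_selection = sel_tab,
                 error_by_size = error_by_size,
                 composition = comp, stratified = strat))
}

# Boxplots of per-model mean signed error by sample size, one panel per
# validation set.
plot_error_by_size <- function(at_star, path) {
  p <- ggplot2::ggplot(at_star,
         ggplot2::aes(x = factor(.data$sample_size), y = .data$mean_error)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ validation_set) +
    ggplot2::labs(x = "training sample size",
                  y = "per-model mean signed error (ml)") +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 8, height = 4)
  invisible(path)
}

# Manual vs predicted volume at t*, one thin linear fit per model.
plot_volume_scatter <- function(rec_star, path) {
  p <- ggplot2::ggplot(rec_star,
         ggplot2::aes(x = .data$manual_ml, y = .data$predicted_ml)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.5) +
    ggplot2::geom_smooth(ggplot2::aes(group = .data$draw_id),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.2, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::facet_grid(validation_set ~ sample_size) +
    ggplot2::labs(x = "manual volume (ml)", y = "predicted volume (ml)") +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 10, height = 6)
  invisible(path)
}
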