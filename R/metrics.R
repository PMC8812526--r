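#' Lesion volume of a binary mask in ml
#'
#' @param mask binary array (logical, or numeric of 0/1).
#' @param voxel_dims voxel size in mm per axis.
#' @return Voxel count times voxel volume (mm^3) divided by 1000, in ml.
#' @examples
#' mask_volume_ml(array(1, c(10, 10, 10)), c(1, 1, 1))  # 1 ml
#' @export
mask_volume_ml <- function(mask, voxel_dims) {
  if (!is.logical(mask) && !all(mask %in% c(0, 1)))
    stop("`mask` must be binary", call. = FALSE)
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("`voxel_dims` must be 3 positive lengths (mm)", call. = FALSE)
  sum(mask != 0) * prod(voxel_dims) / 1000
}

#' Signed volume error in ml
#'
#' Predicted minus manual volume: positive values are overestimation,
#' negative underestimation.
#'
#' @param predicted,manual volumes in ml.
#' @return `predicted - manual` (vectorized).
#' @export
signed_error <- function(predicted, manual) {
  predicted - manual
}

#' Per-model summary of signed volume errors
#'
#' Arithmetic mean, sample SD (n-1 denominator), median and interquartile
#' range of the signed errors of one model on one validation set at one
#' threshold. The IQR uses the linear-interpolation quartile convention
#' (`quantile` type 7). A single observation has no sample SD; it is reported
#' as 0 with `sd_defined = FALSE`.
#'
#' @param errors numeric vector of signed errors (ml); at least one.
#' @return A one-row tibble: `n_observations`, `mean_error`, `sd_error`,
#'   `median_error`, `iqr_error`, `sd_defined`.
#' @export
summarize_model <- function(errors) {
  if (length(errors) == 0) stop("no records to summarize", call. = FALSE)
  n <- length(errors)
  s <- if (n > 1) sd(errors) else 0
  q <- unname(quantile(errors, c(0.25, 0.75), type = 7))
  tibble::tibble(
    n_observations = n,
    mean_error = mean(errors),
    sd_error = s,
    median_error = median(errors),
    iqr_error = q[2] - q[1],
    sd_defined = n > 1)
}

#' Select the global probability threshold
#'
#' Aggregates the per-model mean signed errors over the designated validation
#' sets at each threshold, and picks the threshold minimizing the magnitude
#' of the aggregate (default), or the signed aggregate itself with
#' `use_magnitude = FALSE`. Exact ties resolve to the larger threshold (the
#' more conservative mask).
#'
#' @param summaries tibble of per-model summaries with columns
#'   `validation_set`, `threshold`, `mean_error` (e.g. the `summaries` table
#'   of [run_experiment()]).
#' @param sets validation sets entering the selection; defaults to the two
#'   internal sets.
#' @param use_magnitude minimize `|mean|` (default) or the signed mean.
#' @param thresholds expected threshold grid; every value must be present in
#'   `summaries` for every selected set.
#' @return A list: `threshold` (the selected t*) and `table`, the
#'   per-threshold aggregate used for selection.
#' @export
select_threshold <- function(summaries,
                             sets = c("internal_bl", "internal_fu"),
                             use_magnitude = TRUE,
                             thresholds = seq(0, 1, by = 0.1)) {
  need <- c("validation_set", "threshold", "mean_error")
  if (!all(need %in% names(summaries)))
    stop("`summaries` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sub <- summaries[summaries$validation_set %in% sets, ]
  if (nrow(sub) == 0) stop("no summaries for the designated sets", call. = FALSE)
  have <- sort(unique(round(sub$threshold, 6)))
  if (!all(round(thresholds, 6) %in% have))
    stop("threshold grid incomplete: missing ",
         paste(setdiff(round(thresholds, 6), have), collapse = ", "),
         call. = FALSE)
  tab <- dplyr::summarise(dplyr::group_by(sub, .data$threshold),
                          mean_error = mean(.data$mean_error),
                          .groups = "drop")
  tab$abs_mean_error <- abs(tab$mean_error)
  score <- if (use_magnitude) tab$abs_mean_error else tab$mean_error
  best <- which(score <= min(score) + 1e-12)
  t_star <- max(tab$threshold[best])  # ties -> larger threshold
  list(threshold = t_star, table = tab)
}

#' Dice similarity index of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. An empty manual mask with a non-empty prediction
#' scores 0 (pure overestimation). When both masks are empty the index is
#' undefined and returned as `NA` (excluded from averages) unless
#' `both_empty = "one"`, which maps the case to 1.
#'
#' @param manual,predicted binary arrays on the same grid.
#' @param both_empty `"undefined"` (default, returns `NA`) or `"one"`.
#' @return A number in `[0, 1]`, or `NA` for the undefined case.
#' @export
dice_si <- function(manual, predicted, both_empty = c("undefined", "one")) {
  both_empty <- match.arg(both_empty)
  if (!identical(dim(manual), dim(predicted)))
    stop("masks must share the same grid", call. = FALSE)
  a <- sum(manual != 0)
  b <- sum(predicted != 0)
  if (a + b == 0)
    return(if (both_empty == "one") 1 else NA_real_)
  2 * sum(manual != 0 & predicted != 0) / (a + b)
}

#' Training-set composition analysis
#'
#' For each training draw, the proportion of members whose ground-truth
#' lesion volume is below 0.1 ml and below 0.5 ml, joined with the draw's
#' model-level mean signed error; plus a binned report of mean error by
#' decile of the low-volume proportion. A systematic negative association
#' (few low-volume members -> overestimating model, many -> underestimating)
#' indicates a composition effect.
#'
#' @param draw_members tibble with columns `draw_id`, `participant_id`,
#'   `timepoint` (one row per training member; e.g. the `draws` table of
#'   [run_experiment()]).
#' @param volumes tibble of ground-truth volumes (`participant_id`,
#'   `timepoint`, `manual_ml`), e.g. from [cohort_observations()].
#' @param model_errors tibble with `draw_id` and `mean_error` at the
#'   selected threshold.
#' @param cutoffs the two low-volume cutoffs (ml).
#' @return A list: `records` (per draw: `draw_id`, `prop_low1`, `prop_low2`,
#'   `mean_error`) and `binned` (mean error by decile of `prop_low2`).
#' @export
composition_analysis <- function(draw_members, volumes, model_errors,
                                 cutoffs = c(0.1, 0.5)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  joined <- dplyr::left_join(draw_members, volumes,
                             by = c("participant_id", "timepoint"))
  if (anyNA(joined$manual_ml))
    stop("some training members have no ground-truth volume", call. = FALSE)
  records <- dplyr::summarise(
    dplyr::group_by(joined, .data$draw_id),
    prop_low1 = mean(.data$manual_ml < cutoffs[1]),
    prop_low2 = mean(.data$manual_ml < cutoffs[2]),
    .groups = "drop")
  records <- dplyr::inner_join(records, model_errors, by = "draw_id")
  records$bin <- cut(records$prop_low2, breaks = seq(0, 1, by = 0.1),
                     include.lowest = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(records, .data$bin),
    n_models = dplyr::n(),
    mean_error = mean(.data$mean_error),
    .groups = "drop")
  records$bin <- NULL
  list(records = records, binned = binned)
}

#' Volume-stratified error summary
#'
#' Bins observations by ground-truth volume (default strata: exactly 0,
#' (0, 0.1], (0.1, 0.5], (0.5, 2], > 2 ml) and reports per-bin mean signed
#' error and mean Dice. In the zero bin the mean error is necessarily
#' `>= 0`: a zero volume cannot be underestimated.
#'
#' @param records tibble with columns `manual_ml`, `error_ml` and optionally
#'   `dice` (taken at a single threshold).
#' @param breaks positive interior break points in ml.
#' @return A tibble: `bin`, `n`, `mean_error`, `mean_dice` (NA-excluded).
#' @export
stratified_errors <- function(records, breaks = c(0.1, 0.5, 2)) {
  stopifnot(all(breaks > 0), !is.unsorted(breaks))
  labels <- c(paste0("(0,", breaks[1], "]"),
              paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]"),
              paste0(">", breaks[length(breaks)]))
  bin <- ifelse(
    records$manual_ml == 0, "0",
    as.character(cut(records$manual_ml, c(0, breaks, Inf), labels = labels)))
  records$bin <- factor(bin, levels = c("0", labels))
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$bin, .drop = TRUE),
    n = dplyr::n(),
    mean_error = mean(.data$error_ml),
    mean_dice = if ("dice" %in% names(records)) mean(.data$dice, na.rm = TRUE)
                else NA_real_,
    .groups = "drop")
  out
}
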