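#' Resampling design parameters
#'
#' Training sets are drawn without replacement at several sample sizes, with
#' many replicates per size. Defaults mirror the study design: sizes 10 to 40
#' in steps of 5, 100 random draws per size.
#'
#' @param sample_sizes ordered integer vector of training-set sizes (each
#'   `>= 1`).
#' @param n_draws replicates per sample size (`>= 1`).
#' @param seed master seed for the design; each (size, replicate) draw runs
#'   on its own substream.
#' @return An object of class `wmh_design_params`.
#' @export
design_params <- function(sample_sizes = seq(10L, 40L, by = 5L),
                          n_draws = 100L, seed = 1L) {
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) < 1 || any(sample_sizes < 1))
    stop("`sample_sizes` must all be >= 1", call. = FALSE)
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  structure(list(sample_sizes = sample_sizes, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "wmh_design_params")
}

#' Draw one random training set
#'
#' Chooses `n` distinct participants uniformly without replacement from the
#' resampling partition, and for each one observation (BL or FU) uniformly.
#' Only one observation per participant may enter a training set, the first
#' half of the leakage rule.
#'
#' @param cohort a `wmh_cohort`.
#' @param n training-set size; must not exceed the number of paired
#'   participants.
#' @param seed optional substream seed.
#' @param replicate replicate index recorded in the draw id.
#' @return A `wmh_draw`: `sample_size`, `replicate`, `draw_id`, and `members`
#'   (tibble of `participant_id`, `timepoint`).
#' @export
draw_training_set <- function(cohort, n, seed = NULL, replicate = 1L) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  ids <- resampling_ids(cohort)
  if (n > length(ids))
    stop(sprintf("training size %d exceeds the %d paired participants",
                 n, length(ids)), call. = FALSE)
  draw <- function() {
    chosen <- ids[sample.int(length(ids), n)]
    tibble::tibble(participant_id = chosen,
                   timepoint = sample(c("BL", "FU"), n, replace = TRUE))
  }
  members <- if (is.null(seed)) draw() else with_substream(seed, draw())
  structure(list(sample_size = as.integer(n), replicate = as.integer(replicate),
                 draw_id = sprintf("n%02d_r%03d", n, replicate),
                 members = members),
            class = "wmh_draw")
}

#' Build the leakage-consistent validation split for a draw
#'
#' Every participant with any scan in the training set is excluded from the
#' internal validation sets entirely (both scans). The remaining participants
#' contribute their BL scan to the internal-BL set and their FU scan to the
#' internal-FU set, so each participant appears once per set. The external
#' set is the fixed never-trained-on partition.
#'
#' @param draw a `wmh_draw` from [draw_training_set()].
#' @param cohort the `wmh_cohort` the draw was taken from.
#' @return A `wmh_split`: tibbles `internal_bl`, `internal_fu`, `external`
#'   (columns `participant_id`, `timepoint`).
#' @export
build_split <- function(draw, cohort) {
  stopifnot(inherits(draw, "wmh_draw"), inherits(cohort, "wmh_cohort"))
  ids <- resampling_ids(cohort)
  if (!all(draw$members$participant_id %in% ids))
    stop("draw contains participants not in this cohort's resampling partition",
         call. = FALSE)
  held_out <- setdiff(ids, draw$members$participant_id)
  ext <- dplyr::bind_rows(lapply(cohort$external, function(s)
    tibble::tibble(participant_id = s$participant_id, timepoint = s$timepoint)))
  structure(
    list(internal_bl = tibble::tibble(participant_id = held_out,
                                      timepoint = "BL"),
         internal_fu = tibble::tibble(participant_id = held_out,
                                      timepoint = "FU"),
         external = ext,
         draw_id = draw$draw_id),
    class = "wmh_split")
}

#' Check a (draw, split) pair for participant-level data leakage
#'
#' Passes iff no participant id appears both in the training draw and in
#' either internal validation set, and no external participant belongs to the
#' resampling partition.
#'
#' @param draw a `wmh_draw`.
#' @param split a `wmh_split`.
#' @param cohort optional `wmh_cohort`; when supplied, the external partition
#'   is additionally checked for overlap with the resampling ids.
#' @return A list with `pass` (logical) and `violations` (character vector of
#'   offending participant ids, empty on pass).
#' @export
verify_no_leakage <- function(draw, split, cohort = NULL) {
  stopifnot(inherits(draw, "wmh_draw"), inherits(split, "wmh_split"))
  internal_ids <- c(split$internal_bl$participant_id,
                    split$internal_fu$participant_id)
  bad <- intersect(draw$members$participant_id, internal_ids)
  if (!is.null(cohort))
    bad <- union(bad, intersect(split$external$participant_id,
                                resampling_ids(cohort)))
  list(pass = length(bad) == 0L, violations = bad)
}

#' Enumerate the resampling design
#'
#' One row per training sample size, giving the internal BL/FU and external
#' validation counts, the number of predicted masks per model, and the
#' overall count across replicates; totals are attached as attributes.
#'
#' @param params a [design_params()].
#' @param n_paired number of paired participants (default 80).
#' @param n_external size of the external validation set (default 41).
#' @return A tibble with columns `sample_size`, `internal_bl`, `internal_fu`,
#'   `external`, `per_model`, `overall`, plus attributes `total_models` and
#'   `total_predictions`.
#' @examples
#' d <- enumerate_design(design_params())
#' d
#' attr(d, "total_predictions")  # 105700 at study defaults
#' @export
enumerate_design <- function(params = design_params(), n_paired = 80L,
                             n_external = 41L) {
  stopifnot(inherits(params, "wmh_design_params"))
  if (any(params$sample_sizes > n_paired))
    stop("sample sizes must not exceed `n_paired`", call. = FALSE)
  n <- params$sample_sizes
  tab <- tibble::tibble(
    sample_size = n,
    internal_bl = n_paired - n,
    internal_fu = n_paired - n,
    external = as.integer(n_external),
    per_model = 2L * (n_paired - n) + as.integer(n_external),
    overall = (2L * (n_paired - n) + as.integer(n_external)) * params$n_draws)
  attr(tab, "total_models") <- length(n) * params$n_draws
  attr(tab, "total_predictions") <- sum(tab$overall)
  tab
}

#' Report duplicate training sets across replicates
#'
#' Sampling is independent across replicates, so identical member sets are
#' possible (though unlikely); this reports rather than forbids them.
#'
#' @param draws a list of `wmh_draw` objects.
#' @return A tibble of duplicated member sets (`key`, `draw_ids`, `n_copies`);
#'   zero rows when all draws are distinct.
#' @export
report_duplicate_draws <- function(draws) {
  keys <- vapply(draws, function(d) {
    m <- d$members[order(d$members$participant_id), ]
    paste(m$participant_id, m$timepoint, sep = ":", collapse = ",")
  }, "")
  ids <- vapply(draws, `[[`, "", "draw_id")
  dup <- split(ids, keys)
  dup <- dup[lengths(dup) > 1L]
  tibble::tibble(
    key = names(dup),
    draw_ids = unname(vapply(dup, paste, "", collapse = ";")),
    n_copies = unname(lengths(dup)))
}
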