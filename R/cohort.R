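#' Generate a full synthetic study cohort
#'
#' Produces the study dataset: `n_paired` participants with paired baseline
#' (BL) and follow-up (FU) phantoms (the resampling partition) plus
#' `n_external` independent FU observations (the external validation
#' partition, never used for training). Target lesion volumes are sampled
#' from the population model and clamped to 85% of the phantom's WM-eligible
#' capacity, so heavy-tail draws remain realizable on small grids. The whole
#' cohort is reproducible from `params$seed`: every participant runs on a
#' named substream, so changing cohort size does not perturb earlier
#' participants.
#'
#' @param params a [phantom_params()].
#' @param model a [lesion_volume_model()].
#' @return A `wmh_cohort`: list with `resampling` (list of `wmh_subject`, BL
#'   and FU per participant), `external` (list of `wmh_subject`), and the
#'   `params`/`model` provenance echo.
#' @examples
#' p <- phantom_params(grid_shape = c(24, 24, 24), n_paired = 2, n_external = 1,
#'                     seed = 7)
#' cohort <- generate_cohort(p, lesion_volume_model())
#' cohort_observations(cohort)
#' @export
generate_cohort <- function(params = phantom_params(),
                            model = lesion_volume_model()) {
  stopifnot(inherits(params, "wmh_phantom_params"),
            inherits(model, "wmh_lesion_model"))
  geometry <- phantom_geometry(params)
  cap_ml <- 0.85 * phantom_capacity_ml(params, geometry)

  resampling <- vector("list", 2L * params$n_paired)
  for (i in seq_len(params$n_paired)) {
    pid <- sprintf("P%03d", i)
    vol <- min(cap_ml, sample_lesion_volume(
      model, 1L, seed = substream_seed(params$seed, "volume", pid)))
    bl <- generate_subject(params, vol, pid, "BL",
                           seed = substream_seed(params$seed, "subject", pid, "BL"),
                           geometry = geometry)
    fu <- make_followup(bl, model, params,
                        seed = substream_seed(params$seed, "subject", pid, "FU"),
                        geometry = geometry)
    resampling[[2L * i - 1L]] <- bl
    resampling[[2L * i]] <- fu
  }

  external <- vector("list", params$n_external)
  for (i in seq_len(params$n_external)) {
    pid <- sprintf("E%03d", i)
    vol <- min(cap_ml, sample_lesion_volume(
      model, 1L, seed = substream_seed(params$seed, "volume", pid)))
    external[[i]] <- generate_subject(
      params, vol, pid, "FU",
      seed = substream_seed(params$seed, "subject", pid, "FU"),
      geometry = geometry)
  }

  structure(list(resampling = resampling, external = external,
                 params = params, model = model),
            class = "wmh_cohort")
}

#' @export
print.wmh_cohort <- function(x, ...) {
  obs <- cohort_observations(x)
  cat("<wmh_cohort>\n")
  cat(sprintf("  %d paired participants (%d observations) + %d external\n",
              x$params$n_paired, length(x$resampling), length(x$external)))
  cat(sprintf("  manual volume (ml): median %.2f, IQR %.2f, %.0f%% lesion-free\n",
              median(obs$manual_ml), IQR(obs$manual_ml),
              100 * mean(obs$manual_ml == 0)))
  invisible(x)
}

#' Tabulate the observations of a cohort
#'
#' @param cohort a `wmh_cohort`.
#' @return A tibble with one row per observation: `participant_id`,
#'   `timepoint`, `partition` (`"resampling"` or `"external"`), and
#'   `manual_ml`, the ground-truth lesion volume.
#' @export
cohort_observations <- function(cohort) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  row1 <- function(s, part) tibble::tibble(
    participant_id = s$participant_id, timepoint = s$timepoint,
    partition = part,
    manual_ml = mask_volume_ml(s$manual_mask, s$voxel_dims))
  dplyr::bind_rows(
    dplyr::bind_rows(lapply(cohort$resampling, row1, part = "resampling")),
    dplyr::bind_rows(lapply(cohort$external, row1, part = "external")))
}

#' Fetch one observation from a cohort
#'
#' @param cohort a `wmh_cohort`.
#' @param participant_id,timepoint identify the observation.
#' @return The matching `wmh_subject`.
#' @export
get_subject <- function(cohort, participant_id, timepoint) {
  pool <- c(cohort$resampling, cohort$external)
  for (s in pool)
    if (identical(s$participant_id, participant_id) &&
        identical(s$timepoint, timepoint)) return(s)
  stop(sprintf("no observation %s/%s in cohort", participant_id, timepoint),
       call. = FALSE)
}

resampling_ids <- function(cohort) {
  unique(vapply(cohort$resampling, `[[`, "", "participant_id"))
}

#' @importFrom stats IQR
NULL
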