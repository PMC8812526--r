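#' Write a cohort to disk as NIfTI volumes plus a master index
#'
#' Each observation is written as four NIfTI-1 files (`flair`, `t1`,
#' `brain_mask`, `manual_mask`, all `.nii.gz`, voxel dimensions encoded in the
#' header) and the cohort is indexed by a tab-separated master file with one
#' row per observation: `participant_id`, `timepoint` (`BL`/`FU`),
#' `partition` (`resampling`/`external`) and the four file paths. Generator
#' provenance (phantom parameters and lesion model) is stored alongside as
#' JSON so that [read_cohort()] round-trips the cohort losslessly.
#'
#' @param cohort a `wmh_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with `index` (path of the master TSV) and
#'   `provenance` (path of the JSON echo).
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)

  write_vol <- function(vol, voxel_dims, path) {
    im <- RNifti::asNifti(vol)
    RNifti::pixdim(im) <- voxel_dims
    RNifti::writeNifti(im, path)
    path
  }
  one <- function(s, part) {
    stub <- file.path(dir, sprintf("%s_%s", s$participant_id, s$timepoint))
    tibble::tibble(
      participant_id = s$participant_id, timepoint = s$timepoint,
      partition = part,
      flair_path = write_vol(s$flair, s$voxel_dims, paste0(stub, "_flair.nii.gz")),
      t1_path = write_vol(s$t1, s$voxel_dims, paste0(stub, "_t1.nii.gz")),
      brainmask_path = write_vol(s$brain_mask + 0, s$voxel_dims,
                                 paste0(stub, "_brainmask.nii.gz")),
      manualmask_path = write_vol(s$manual_mask + 0, s$voxel_dims,
                                  paste0(stub, "_manualmask.nii.gz")))
  }
  index <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(cohort$resampling, one, part = "resampling")),
    dplyr::bind_rows(lapply(cohort$external, one, part = "external")))

  index_path <- file.path(dir, "cohort_index.tsv")
  utils::write.table(index, index_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  prov_path <- file.path(dir, "cohort_provenance.json")
  pp <- unclass(cohort$params)
  pp$tissue_means <- lapply(pp$tissue_means, as.list)  # keep names in JSON
  jsonlite::write_json(
    list(params = pp, model = unclass(cohort$model)),
    prov_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(index = index_path, provenance = prov_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort_index.tsv` and the NIfTI volumes.
#' @return A `wmh_cohort`, voxel-identical to the one written.
#' @export
read_cohort <- function(dir) {
  index_path <- file.path(dir, "cohort_index.tsv")
  if (!file.exists(index_path))
    stop("no cohort_index.tsv under ", dir, call. = FALSE)
  index <- utils::read.delim(index_path, stringsAsFactors = FALSE)

  prov <- jsonlite::read_json(file.path(dir, "cohort_provenance.json"),
                              simplifyVector = FALSE)
  pp <- prov$params
  params <- phantom_params(
    grid_shape = unlist(pp$grid_shape), voxel_dims = unlist(pp$voxel_dims),
    tissue_means = lapply(pp$tissue_means, unlist),
    noise_sd = pp$noise_sd, partial_volume = pp$partial_volume,
    n_paired = pp$n_paired, n_external = pp$n_external, seed = pp$seed,
    blob_mean_voxels = pp$blob_mean_voxels,
    lesion_margin = unlist(pp$lesion_margin))
  model <- do.call(lesion_volume_model, lapply(prov$model, unlist))

  read_vol <- function(path) {
    im <- RNifti::readNifti(path)
    list(data = array(as.numeric(im), dim = dim(im)),
         voxel_dims = RNifti::pixdim(im))
  }
  subjects <- lapply(seq_len(nrow(index)), function(i) {
    row <- index[i, ]
    fl <- read_vol(row$flair_path)
    t1 <- read_vol(row$t1_path)
    bm <- read_vol(row$brainmask_path)
    mm <- read_vol(row$manualmask_path)
    new_subject(row$participant_id, row$timepoint,
                fl$data, t1$data,
                bm$data > 0.5, mm$data > 0.5, as.numeric(fl$voxel_dims))
  })
  structure(
    list(resampling = subjects[index$partition == "resampling"],
         external = subjects[index$partition == "external"],
         params = params, model = model),
    class = "wmh_cohort")
}
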