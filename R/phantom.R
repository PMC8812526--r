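#' Phantom generation parameters
#'
#' Configuration for the 3D digital head phantom: grid and voxel geometry,
#' tissue intensity models for the FLAIR-like and T1-like channels, noise, and
#' cohort sizes. The phantom is a nested-ellipsoid head (background, grey
#' matter shell, white matter, central CSF-like core) in which lesions are
#' seeded as quasi-spherical blobs; lesions are hyperintense on FLAIR and
#' mildly hypointense on T1, as WMH are on real images.
#'
#' @param grid_shape voxels per axis (all `>= 16`). Default 64^3: large enough
#'   for multi-blob lesion geometry, small enough for desk-scale experiments.
#' @param voxel_dims voxel size in mm per axis (all `> 0`). Fully configurable
#'   so anisotropic acquisitions (e.g. 0.45 x 0.45 x 5 mm FLAIR) can be
#'   emulated in tests.
#' @param tissue_means,tissue_sds named per-channel intensity means (arbitrary
#'   units) for `background`, `wm`, `gm`, `csf`, `lesion`. Lesion FLAIR mean
#'   must exceed WM FLAIR mean (FLAIR hyperintensity).
#' @param noise_sd additive Gaussian noise SD applied to both channels.
#' @param partial_volume logical; when `TRUE` a one-pass 6-neighbour box
#'   smoothing is applied before noise, blurring tissue boundaries the way
#'   partial-volume averaging does on real scans.
#' @param n_paired number of participants with paired BL and FU scans.
#' @param n_external number of external (never-trained-on) observations.
#' @param seed master RNG seed; all per-participant work runs on named
#'   substreams derived from it.
#' @param blob_mean_voxels mean voxels per lesion blob (Poisson); this is the
#'   granularity at which target volumes are realized.
#' @param lesion_margin inner/outer ellipsoidal-radius bounds of the
#'   WM region eligible for lesion seeding (keeps lesions off the CSF core
#'   and the cortical shell).
#' @return An object of class `wmh_phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           voxel_dims = c(1, 1, 1),
                           tissue_means = list(
                             flair = c(background = 0, wm = 100, gm = 120,
                                       csf = 30, lesion = 170),
                             t1 = c(background = 0, wm = 120, gm = 90,
                                    csf = 40, lesion = 100)),
                           noise_sd = 10,
                           partial_volume = TRUE,
                           n_paired = 80,
                           n_external = 41,
                           seed = 42L,
                           blob_mean_voxels = 30,
                           lesion_margin = c(0.30, 0.75)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16))
    stop("`grid_shape` must be 3 axes, all >= 16", call. = FALSE)
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("`voxel_dims` must be 3 positive lengths (mm)", call. = FALSE)
  tn <- c("background", "wm", "gm", "csf", "lesion")
  for (ch in c("flair", "t1")) {
    if (!all(tn %in% names(tissue_means[[ch]])))
      stop("`tissue_means$", ch, "` must name ", paste(tn, collapse = ", "),
           call. = FALSE)
  }
  if (tissue_means$flair[["lesion"]] <= tissue_means$flair[["wm"]])
    stop("lesion FLAIR mean must exceed WM FLAIR mean (WMH are hyperintense)",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_paired < 0 || n_external < 0)
    stop("cohort counts must be >= 0", call. = FALSE)
  if (length(lesion_margin) != 2 || lesion_margin[1] <= 0.25 ||
      lesion_margin[2] >= 0.88 || lesion_margin[1] >= lesion_margin[2])
    stop("`lesion_margin` must satisfy 0.25 < inner < outer < 0.88",
         call. = FALSE)

  structure(
    list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
         tissue_means = tissue_means, tissue_sds = NULL,
         noise_sd = noise_sd, partial_volume = isTRUE(partial_volume),
         n_paired = as.integer(n_paired), n_external = as.integer(n_external),
         seed = as.integer(seed),
         blob_mean_voxels = blob_mean_voxels,
         lesion_margin = lesion_margin),
    class = "wmh_phantom_params"
  )
}

#' @export
print.wmh_phantom_params <- function(x, ...) {
  cat("<wmh_phantom_params>\n")
  cat(sprintf("  grid %s at %s mm; noise SD %.1f; partial volume: %s\n",
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$voxel_dims), collapse = "x"),
              x$noise_sd, x$partial_volume))
  cat(sprintf("  cohort: %d paired participants + %d external; seed %d\n",
              x$n_paired, x$n_external, x$seed))
  invisible(x)
}

# Tissue geometry shared by every subject on the same grid: nested ellipsoids
# (brain r <= 1, GM shell r in (0.88, 1], CSF core r <= 0.25, WM in between)
# in the normalized ellipsoidal radial coordinate r. Computed once per cohort.
phantom_geometry <- function(params) {
  d <- params$grid_shape
  ax <- function(n) (seq_len(n) - (n + 1) / 2) / (n / 2)
  # brain semi-axes as fractions of the half-grid extent
  r2 <- outer(outer((ax(d[1]) / 0.80)^2, (ax(d[2]) / 0.85)^2, "+"),
              (ax(d[3]) / 0.75)^2, "+")
  r <- sqrt(r2)
  brain <- r <= 1
  gm <- brain & r > 0.88
  csf <- r <= 0.25
  wm <- brain & !gm & !csf
  eligible <- r >= params$lesion_margin[1] & r <= params$lesion_margin[2]
  tissue <- array(0L, d)
  tissue[wm] <- 1L
  tissue[gm] <- 2L
  tissue[csf] <- 3L
  list(dim = d, brain = brain, wm = wm, gm = gm, csf = csf,
       eligible = eligible, tissue = tissue,
       capacity_voxels = sum(eligible))
}

# Lesion-eligible capacity of the phantom in ml.
phantom_capacity_ml <- function(params, geometry = NULL) {
  geometry <- if (is.null(geometry)) phantom_geometry(params) else geometry
  geometry$capacity_voxels * prod(params$voxel_dims) / 1000
}

# Grow quasi-spherical lesion blobs voxel-by-voxel inside the eligible WM
# region until exactly `target_vox` new voxels are lesioned (or the region is
# exhausted). Each blob takes the free voxels nearest (in mm, with a small
# random jitter for irregular boundaries) to a random seed voxel. Consumes the
# caller's RNG stream.
grow_lesion_blobs <- function(lesion, target_vox, geometry, params) {
  free <- which(geometry$eligible & !lesion)
  remaining <- as.integer(target_vox)
  while (remaining > 0L) {
    if (length(free) == 0L)
      stop("lesion target volume exceeds white-matter capacity", call. = FALSE)
    seed_vox <- free[sample.int(length(free), 1L)]
    blob_n <- min(remaining, max(1L, rpois(1L, params$blob_mean_voxels)),
                  length(free))
    co <- arrayInd(free, geometry$dim)
    sc <- arrayInd(seed_vox, geometry$dim)
    dx <- sweep(co, 2, sc) * rep(params$voxel_dims, each = nrow(co))
    d2 <- rowSums(dx * dx) + runif(length(free), 0, 0.5)
    take <- order(d2)[seq_len(blob_n)]
    lesion[free[take]] <- TRUE
    free <- free[-take]
    remaining <- remaining - blob_n
  }
  lesion
}

# Logical array: voxels with at least one 6-neighbour inside `mask`.
neighbours6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sh <- function(i, lo) {
    idx <- if (lo) c(1L, seq_len(d[i] - 1L)) else c(seq_len(d[i] - 1L) + 1L, d[i])
    switch(i, mask[idx, , ], mask[, idx, ], mask[, , idx])
  }
  for (i in 1:3) out <- out | sh(i, TRUE) | sh(i, FALSE)
  out
}

# One-pass 6-neighbour box smoothing with edge replication (partial-volume
# emulation).
smooth6 <- function(a) {
  d <- dim(a)
  acc <- a
  sh <- function(i, lo) {
    idx <- if (lo) c(1L, seq_len(d[i] - 1L)) else c(seq_len(d[i] - 1L) + 1L, d[i])
    switch(i, a[idx, , ], a[, idx, ], a[, , idx])
  }
  for (i in 1:3) acc <- acc + sh(i, TRUE) + sh(i, FALSE)
  acc / 7
}

# Noiseless tissue image for one channel, then partial volume + noise.
# Outside-brain voxels are zeroed afterwards (brain-extracted images).
synth_channel <- function(channel, lesion, geometry, params) {
  mu <- params$tissue_means[[channel]]
  img <- array(mu[["background"]], geometry$dim)
  img[geometry$wm] <- mu[["wm"]]
  img[geometry$gm] <- mu[["gm"]]
  img[geometry$csf] <- mu[["csf"]]
  img[lesion] <- mu[["lesion"]]
  if (params$partial_volume) img <- smooth6(img)
  if (params$noise_sd > 0)
    img <- img + array(rnorm(prod(geometry$dim), 0, params$noise_sd),
                       geometry$dim)
  img[!geometry$brain] <- 0
  img
}

new_subject <- function(participant_id, timepoint, flair, t1, brain_mask,
                        manual_mask, voxel_dims) {
  stopifnot(identical(dim(flair), dim(t1)),
            identical(dim(flair), dim(brain_mask)),
            identical(dim(flair), dim(manual_mask)))
  if (any(manual_mask & !brain_mask))
    stop("manual mask must lie inside the brain mask", call. = FALSE)
  structure(
    list(participant_id = participant_id,
         timepoint = match.arg(timepoint, c("BL", "FU")),
         flair = flair, t1 = t1,
         brain_mask = brain_mask, manual_mask = manual_mask,
         voxel_dims = voxel_dims),
    class = "wmh_subject"
  )
}

#' @export
print.wmh_subject <- function(x, ...) {
  cat(sprintf("<wmh_subject> %s %s: grid %s, lesion volume %.3f ml\n",
              x$participant_id, x$timepoint,
              paste(dim(x$flair), collapse = "x"),
              mask_volume_ml(x$manual_mask, x$voxel_dims)))
  invisible(x)
}

#' Generate one phantom subject with a target lesion load
#'
#' Builds a co-registered FLAIR-like/T1-like volume pair with a ground-truth
#' lesion mask. Lesions are placed as randomly seeded quasi-spherical blobs
#' grown voxel-by-voxel inside the WM-eligible region until the realized mask
#' volume is the closest achievable to `target_volume` (within one voxel of
#' rounding, provided capacity allows).
#'
#' @param params a [phantom_params()].
#' @param target_volume target lesion volume in ml (`>= 0`).
#' @param participant_id identifier string.
#' @param timepoint `"BL"` or `"FU"`.
#' @param seed optional integer substream seed; when `NULL` the current RNG
#'   stream is consumed.
#' @param geometry optional precomputed [phantom_geometry()] (cohort-level
#'   cache); recomputed from `params` when `NULL`.
#' @return A `wmh_subject`: fields `participant_id`, `timepoint`, `flair`,
#'   `t1`, `brain_mask`, `manual_mask`, `voxel_dims`.
#' @examples
#' p <- phantom_params(grid_shape = c(24, 24, 24), n_paired = 1, n_external = 0)
#' s <- generate_subject(p, target_volume = 0.2, "P001", seed = 1)
#' mask_volume_ml(s$manual_mask, s$voxel_dims)
#' @export
generate_subject <- function(params, target_volume, participant_id,
                             timepoint = "BL", seed = NULL, geometry = NULL) {
  stopifnot(inherits(params, "wmh_phantom_params"))
  if (!is.numeric(target_volume) || target_volume < 0)
    stop("`target_volume` must be >= 0 ml", call. = FALSE)
  geometry <- if (is.null(geometry)) phantom_geometry(params) else geometry
  target_vox <- as.integer(round(target_volume * 1000 / prod(params$voxel_dims)))
  if (target_vox > geometry$capacity_voxels)
    stop(sprintf(
      "target volume %.2f ml exceeds white-matter capacity %.2f ml",
      target_volume, phantom_capacity_ml(params, geometry)), call. = FALSE)

  build <- function() {
    lesion <- array(FALSE, geometry$dim)
    if (target_vox > 0L)
      lesion <- grow_lesion_blobs(lesion, target_vox, geometry, params)
    flair <- synth_channel("flair", lesion, geometry, params)
    t1 <- synth_channel("t1", lesion, geometry, params)
    new_subject(participant_id, timepoint, flair, t1,
                geometry$brain, lesion, params$voxel_dims)
  }
  if (is.null(seed)) build() else with_substream(seed, build())
}

#' Derive a follow-up scan from a baseline subject
#'
#' Models intra-individual lesion progression: the baseline mask is grown
#' monotonically (never shrunk) by a sampled multiplicative factor, and
#' de-novo lesions are added with a Poisson count. Image intensities are
#' re-synthesized with fresh noise, emulating a second acquisition of the
#' same head. Follow-up lesion volume is therefore always `>=` baseline.
#'
#' @param bl a baseline `wmh_subject` (timepoint `"BL"`).
#' @param model a [lesion_volume_model()] supplying growth parameters.
#' @param params the [phantom_params()] used for `bl`.
#' @param seed optional substream seed.
#' @param geometry optional precomputed [phantom_geometry()].
#' @return A `wmh_subject` at timepoint `"FU"` on the same grid.
#' @export
make_followup <- function(bl, model, params, seed = NULL, geometry = NULL) {
  stopifnot(inherits(bl, "wmh_subject"), inherits(model, "wmh_lesion_model"),
            inherits(params, "wmh_phantom_params"))
  if (!identical(bl$timepoint, "BL"))
    stop("`bl` must be a baseline (BL) subject", call. = FALSE)
  geometry <- if (is.null(geometry)) phantom_geometry(params) else geometry

  build <- function() {
    lesion <- bl$manual_mask
    factor <- sample_growth_factor(model)
    target <- as.integer(round(sum(lesion) * factor))
    # grow the existing lesions outward, ring by ring, staying in eligible WM
    while (sum(lesion) < target) {
      boundary <- which(neighbours6(lesion) & geometry$eligible & !lesion)
      if (length(boundary) == 0L) break
      need <- target - sum(lesion)
      add <- if (need >= length(boundary)) boundary
             else boundary[sample.int(length(boundary), need)]
      lesion[add] <- TRUE
    }
    # de-novo lesions
    n_new <- rpois(1L, model$new_lesion_rate)
    for (j in seq_len(n_new)) {
      size <- max(3L, rpois(1L, params$blob_mean_voxels))
      size <- min(size, sum(geometry$eligible & !lesion))
      if (size > 0L) lesion <- grow_lesion_blobs(lesion, size, geometry, params)
    }
    flair <- synth_channel("flair", lesion, geometry, params)
    t1 <- synth_channel("t1", lesion, geometry, params)
    new_subject(bl$participant_id, "FU", flair, t1,
                geometry$brain, lesion, params$voxel_dims)
  }
  if (is.null(seed)) build() else with_substream(seed, build())
}
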