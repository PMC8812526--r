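#' Feature configuration for the voxel-wise classifier
#'
#' Each brain-mask voxel is described by its standardized intensity in every
#' modality (mean 0, SD 1 within the subject's own brain mask) followed by
#' its three grid coordinates normalized to `[0, 1]` per axis and multiplied
#' by the spatial weight. With `spatial_weight = 0` the classifier is a pure
#' intensity classifier.
#'
#' @param modalities ordered character vector of modality names (fields of a
#'   `wmh_subject`); at least one.
#' @param spatial_weight multiplier `>= 0` on the normalized coordinates.
#' @return An object of class `wmh_feature_config`.
#' @export
feature_config <- function(modalities = c("flair", "t1"), spatial_weight = 1) {
  if (length(modalities) < 1) stop("need at least one modality", call. = FALSE)
  if (spatial_weight < 0) stop("`spatial_weight` must be >= 0", call. = FALSE)
  structure(list(modalities = modalities,
                 spatial_weight = as.numeric(spatial_weight)),
            class = "wmh_feature_config")
}

#' Training-point subsampling policy
#'
#' Caps on the number of lesion and non-lesion reference voxels pooled from a
#' training set, sampled uniformly without replacement within each class.
#' Defaults follow the recommended operating point of trainable k-NN lesion
#' classifiers (2000 lesion / 10000 non-lesion points).
#'
#' @param max_lesion_points,max_nonlesion_points per-class caps (`>= 1`).
#' @return An object of class `wmh_point_policy`.
#' @export
training_point_policy <- function(max_lesion_points = 2000L,
                                  max_nonlesion_points = 10000L) {
  if (max_lesion_points < 1 || max_nonlesion_points < 1)
    stop("point caps must be >= 1", call. = FALSE)
  structure(list(max_lesion_points = as.integer(max_lesion_points),
                 max_nonlesion_points = as.integer(max_nonlesion_points)),
            class = "wmh_point_policy")
}

#' Extract per-voxel features from a subject
#'
#' @param subject a `wmh_subject`.
#' @param config a [feature_config()].
#' @return A list: `features`, a matrix with one row per brain-mask voxel and
#'   one column per modality plus three spatial columns (`x`, `y`, `z`);
#'   `voxels`, the linear indices of those voxels; `norm_stats`, the
#'   per-modality mean/SD used for standardization.
#' @export
extract_features <- function(subject, config = feature_config()) {
  stopifnot(inherits(subject, "wmh_subject"),
            inherits(config, "wmh_feature_config"))
  idx <- which(subject$brain_mask)
  if (length(idx) == 0L) stop("empty brain mask", call. = FALSE)

  cols <- list()
  norm_stats <- list()
  for (m in config$modalities) {
    vol <- subject[[m]]
    if (is.null(vol)) stop("subject has no modality `", m, "`", call. = FALSE)
    v <- vol[idx]
    mu <- mean(v)
    s <- sd(v)
    # zero-variance guard: a constant image standardizes to all zeros
    cols[[m]] <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mu) / s
    norm_stats[[m]] <- c(mean = mu, sd = if (is.na(s)) 0 else s)
  }
  d <- dim(subject$brain_mask)
  co <- arrayInd(idx, d)
  for (a in 1:3) {
    den <- max(1L, d[a] - 1L)
    cols[[c("x", "y", "z")[a]]] <- (co[, a] - 1) / den * config$spatial_weight
  }
  features <- do.call(cbind, cols)
  colnames(features) <- c(config$modalities, "x", "y", "z")
  list(features = features, voxels = idx, norm_stats = norm_stats)
}

#' Fit a voxel-wise k-NN lesion classifier
#'
#' Pools lesion voxels (label 1, from the ground-truth masks) and non-lesion
#' brain voxels (label 0) across the training subjects, subsamples each class
#' to the policy caps, and stores the reference feature matrix, labels and
#' `k`. Non-lesion points come from the whole brain mask; no white-matter
#' exclusion mask or minimum-cluster threshold is applied. A training set
#' with no lesion voxels at all yields a degenerate classifier (warning) that
#' predicts probability 0 everywhere.
#'
#' @param subjects list of `wmh_subject` with ground-truth `manual_mask`s.
#' @param k neighbour count; must not exceed the stored reference points.
#' @param policy a [training_point_policy()].
#' @param config a [feature_config()].
#' @param seed optional substream seed for the class subsampling.
#' @param draw_id optional identifier echoed into the model.
#' @return An object of class `wmh_classifier`: `features`, `labels`, `k`,
#'   `config`, `policy`, `normalization_stats` (per training subject),
#'   `degenerate`, `draw_id`.
#' @export
fit_wmh_classifier <- function(subjects, k = 40L,
                               policy = training_point_policy(),
                               config = feature_config(),
                               seed = NULL, draw_id = NULL) {
  if (length(subjects) < 1) stop("need at least one training subject",
                                 call. = FALSE)
  stopifnot(inherits(policy, "wmh_point_policy"),
            inherits(config, "wmh_feature_config"))

  feats <- vector("list", length(subjects))
  labs <- vector("list", length(subjects))
  norm_stats <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    fx <- extract_features(s, config)
    feats[[i]] <- fx$features
    labs[[i]] <- as.integer(s$manual_mask[fx$voxels])
    norm_stats[[i]] <- fx$norm_stats
    names(norm_stats)[i] <- paste(s$participant_id, s$timepoint, sep = "_")
  }
  features <- do.call(rbind, feats)
  labels <- unlist(labs)

  # per-class subsample (sorted, so reference order is stable)
  pick <- function(rows, cap) {
    if (length(rows) <= cap) rows else sort(sample(rows, cap))
  }
  subsample <- function() {
    lesion <- pick(which(labels == 1L), policy$max_lesion_points)
    nonles <- pick(which(labels == 0L), policy$max_nonlesion_points)
    c(lesion, nonles)
  }
  keep <- if (is.null(seed)) subsample() else with_substream(seed, subsample())
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]

  degenerate <- sum(labels == 1L) == 0L
  if (degenerate)
    warning("training set contains no lesion voxels; classifier will predict 0 everywhere",
            call. = FALSE)
  if (k > nrow(features))
    stop(sprintf("k = %d exceeds the %d stored reference points",
                 k, nrow(features)), call. = FALSE)

  structure(
    list(features = features, labels = labels, k = as.integer(k),
         config = config, policy = policy,
         normalization_stats = norm_stats,
         degenerate = degenerate, draw_id = draw_id),
    class = "wmh_classifier")
}

#' @export
print.wmh_classifier <- function(x, ...) {
  cat(sprintf("<wmh_classifier> %d reference points (%d lesion), k = %d%s\n",
              nrow(x$features), sum(x$labels == 1L), x$k,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Probabilities for an arbitrary feature matrix (internal fast path).
predict_probability_vector <- function(classifier, features) {
  if (ncol(features) != ncol(classifier$features))
    stop("feature dimension mismatch between classifier and subject",
         call. = FALSE)
  if (classifier$degenerate) return(rep(0, nrow(features)))
  knn_probability_cpp(classifier$features, classifier$labels, features,
                      classifier$k)
}

#' Predict a lesion-probability map for a subject
#'
#' For each brain-mask voxel, the probability is the number of
#' lesion-labelled points among the `k` nearest reference points (Euclidean
#' distance in standardized feature space) divided by `k`. The subject's
#' intensities are standardized with its own brain-mask statistics. Ties at
#' the k-th distance are broken by stable reference-point order. Voxels
#' outside the brain mask get probability 0.
#'
#' @param classifier a [fit_wmh_classifier()] model.
#' @param subject a `wmh_subject` (any grid, same modality count).
#' @return A `wmh_probmap`: `values` (3D array in `[0, 1]`),
#'   `participant_id`, `timepoint`, `draw_id`.
#' @export
predict_probability <- function(classifier, subject) {
  stopifnot(inherits(classifier, "wmh_classifier"),
            inherits(subject, "wmh_subject"))
  fx <- extract_features(subject, classifier$config)
  p <- predict_probability_vector(classifier, fx$features)
  values <- array(0, dim(subject$brain_mask))
  values[fx$voxels] <- p
  structure(list(values = values,
                 participant_id = subject$participant_id,
                 timepoint = subject$timepoint,
                 draw_id = classifier$draw_id),
            class = "wmh_probmap")
}

#' Threshold a probability map into a binary lesion mask
#'
#' A voxel is kept iff its probability is `>= t` for `t > 0`. At `t = 0` the
#' rule is probability `> 0`, so the zero threshold returns all voxels with
#' any lesion evidence rather than the whole brain mask. Comparisons use a
#' 1e-9 guard so grid thresholds (multiples of 0.1) match the rational
#' probabilities (multiples of 1/k) exactly.
#'
#' @param map a `wmh_probmap` or a numeric array of probabilities.
#' @param t threshold in `[0, 1]`.
#' @return A logical array (the binary lesion mask).
#' @export
binarize <- function(map, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1)
    stop("`t` must be a single number in [0, 1]", call. = FALSE)
  values <- if (inherits(map, "wmh_probmap")) map$values else map
  if (t == 0) values > 0 else values >= t - 1e-9
}

#' Save / load a trained classifier
#'
#' Models are archived one file per draw with R's native serialization
#' (version 3), containing the reference features, labels, `k`,
#' normalization statistics, feature configuration and draw id; the
#' round-trip is bit-exact.
#'
#' @param classifier a `wmh_classifier`.
#' @param path file path (conventionally `.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the `wmh_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "wmh_classifier"))
  saveRDS(classifier, path, version = 3)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "wmh_classifier"))
    stop("`path` does not contain a wmh_classifier", call. = FALSE)
  x
}
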