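test_that("feature rows are intensities plus weighted coordinates", {
  s <- generate_subject(clean_params(grid = 16), 0.05, "P001", seed = 1)
  fx <- extract_features(s, feature_config())
  expect_equal(ncol(fx$features), 5)  # 2 modalities + 3 coordinates
  expect_equal(colnames(fx$features), c("flair", "t1", "x", "y", "z"))
  expect_equal(nrow(fx$features), sum(s$brain_mask))
  # standardization within the brain mask
  expect_equal(mean(fx$features[, "flair"]), 0, tolerance = 1e-12)
  expect_equal(sd(fx$features[, "flair"]), 1, tolerance = 1e-12)
  # coordinates normalized to [0, 1]
  expect_true(all(fx$features[, 3:5] >= 0 & fx$features[, 3:5] <= 1))

  # spatial weight 0 silences the coordinate columns
  fx0 <- extract_features(s, feature_config(spatial_weight = 0))
  expect_true(all(fx0$features[, 3:5] == 0))
})

test_that("constant images standardize to zero under the variance guard", {
  s <- generate_subject(clean_params(grid = 16), 0, "P001", seed = 1)
  s$flair[] <- 7
  fx <- extract_features(s, feature_config())
  expect_true(all(fx$features[, "flair"] == 0))
})

test_that("class caps bound the stored reference points", {
  p <- clean_params(grid = 20)
  s <- generate_subject(p, 0.3, "P001", seed = 2)  # 300 lesion voxels
  cl <- fit_wmh_classifier(list(s), k = 10,
                           policy = training_point_policy(50, 200), seed = 3)
  expect_equal(nrow(cl$features), 250)
  expect_equal(sum(cl$labels == 1), 50)
  expect_equal(sum(cl$labels == 0), 200)

  # cap not binding: all lesion voxels kept
  s2 <- generate_subject(p, 0.01, "P002", seed = 4)  # 10 lesion voxels
  cl2 <- fit_wmh_classifier(list(s2), k = 10,
                            policy = training_point_policy(2000, 200), seed = 5)
  expect_equal(sum(cl2$labels == 1), 10)
})

test_that("a lesion-free training set degenerates to the zero predictor", {
  p <- clean_params(grid = 16)
  s <- generate_subject(p, 0, "P001", seed = 1)
  expect_warning(
    cl <- fit_wmh_classifier(list(s), k = 5,
                             policy = training_point_policy(10, 50), seed = 2),
    "no lesion voxels")
  pm <- predict_probability(cl, s)
  expect_true(all(pm$values == 0))
})

test_that("probabilities match the brute-force distance-sort oracle exactly", {
  set.seed(42)
  for (i in 1:120) {
    nr <- sample(5:60, 1)
    d <- sample(2:6, 1)
    k <- sample(seq_len(nr), 1)
    ref <- matrix(rnorm(nr * d), nr, d)
    # duplicated reference rows force exact distance ties
    if (nr > 6) ref[nr, ] <- ref[1, ]
    labels <- sample(0:1, nr, replace = TRUE)
    query <- matrix(rnorm(12 * d), 12, d)
    if (i %% 3 == 0) query[1, ] <- ref[2, ]  # zero-distance query
    got <- wmhresample:::knn_probability_cpp(ref, as.integer(labels), query,
                                             as.integer(k))
    expect_identical(got, knn_oracle(ref, labels, query, k))
  }
})

test_that("probabilities are multiples of 1/k with documented tie handling", {
  set.seed(7)
  ref <- matrix(rnorm(200 * 5), 200, 5)
  labels <- sample(0:1, 200, replace = TRUE)
  query <- matrix(rnorm(50 * 5), 50, 5)
  k <- 13
  p <- wmhresample:::knn_probability_cpp(ref, as.integer(labels), query, k)
  expect_true(all(abs(p * k - round(p * k)) < 1e-12))
  expect_true(all(p >= 0 & p <= 1))

  # a query duplicated in the reference set with lesion label, k = 1
  q <- matrix(ref[5, ], 1)
  labels1 <- labels
  labels1[5] <- 1L
  expect_equal(wmhresample:::knn_probability_cpp(ref, as.integer(labels1), q, 1L),
               1)

  # permuting reference order changes nothing away from exact ties
  perm <- sample(200)
  p2 <- wmhresample:::knn_probability_cpp(ref[perm, ],
                                          as.integer(labels[perm]), query, k)
  expect_equal(p2, p)
})

test_that("an all-lesion reference set predicts probability one in the mask", {
  p <- clean_params(grid = 16)
  s <- generate_subject(p, 0.05, "P001", seed = 1)
  cl <- fit_wmh_classifier(list(s), k = 3,
                           policy = training_point_policy(2000, 10000),
                           seed = 2)
  cl$features <- cl$features[cl$labels == 1, , drop = FALSE]
  cl$labels <- cl$labels[cl$labels == 1]
  pm <- predict_probability(cl, s)
  expect_true(all(pm$values[s$brain_mask] == 1))
  expect_true(all(pm$values[!s$brain_mask] == 0))
})

test_that("binarize respects boundaries, the t = 0 rule, and nesting", {
  m <- array(c(0, 0.5, 0.8, rep(0, 5)), c(2, 2, 2))
  expect_equal(sum(binarize(m, 0.8)), 1)   # boundary inclusion
  expect_equal(sum(binarize(m, 1)), 0)
  expect_equal(sum(binarize(m, 0)), 2)     # t = 0 keeps p > 0 only
  expect_error(binarize(m, 1.5), "\\[0, 1\\]")

  set.seed(3)
  k <- 11
  pm <- array(sample(0:k, 4^3, replace = TRUE) / k, c(4, 4, 4))
  grid <- seq(0, 1, by = 0.1)
  masks <- lapply(grid, function(t) binarize(pm, t))
  for (i in seq_len(length(grid) - 1))
    expect_true(all(masks[[i]][masks[[i + 1]]]))  # higher t is nested
})

test_that("a noiseless separable phantom is recovered exactly at t = 0.8", {
  p <- clean_params(grid = 20)
  train <- generate_subject(p, 0.25, "A", seed = 1)
  test <- generate_subject(p, 0.15, "B", seed = 2)
  cl <- fit_wmh_classifier(list(train), k = 5,
                           policy = training_point_policy(200, 1000),
                           config = feature_config(spatial_weight = 0),
                           seed = 3)
  pm <- predict_probability(cl, test)
  expect_identical(binarize(pm, 0.8), test$manual_mask)
})

test_that("saved classifiers round-trip bit-exactly", {
  s <- generate_subject(clean_params(grid = 16), 0.05, "P001", seed = 1)
  cl <- fit_wmh_classifier(list(s), k = 5,
                           policy = training_point_policy(20, 100), seed = 2,
                           draw_id = "n02_r001")
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(cl, path)
  expect_identical(load_classifier(path), cl)
})

test_that("modality mismatch between model and subject errors", {
  s <- generate_subject(clean_params(grid = 16), 0.05, "P001", seed = 1)
  cl <- fit_wmh_classifier(list(s), k = 5,
                           policy = training_point_policy(20, 100), seed = 2)
  s_flaironly <- fit_wmh_classifier(
    list(s), k = 5, policy = training_point_policy(20, 100),
    config = feature_config(modalities = "flair"), seed = 2)
  fx <- extract_features(s, feature_config(modalities = "flair"))
  expect_error(wmhresample:::predict_probability_vector(cl, fx$features),
               "dimension mismatch")
})
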