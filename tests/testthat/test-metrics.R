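test_that("mask volume converts voxel counts to ml", {
  expect_equal(mask_volume_ml(array(1, c(10, 10, 10)), c(1, 1, 1)), 1)
  expect_equal(mask_volume_ml(array(0, c(4, 4, 4)), c(1, 1, 1)), 0)
  m <- array(0, c(10, 10, 10)); m[1:100] <- 1
  expect_equal(mask_volume_ml(m, c(0.45, 0.45, 5)), 0.10125)
  expect_error(mask_volume_ml(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "binary")
})

test_that("signed errors follow the over/underestimation convention", {
  expect_equal(signed_error(0.5, 0.5), 0)
  expect_equal(signed_error(1.2, 1.0), 0.2)
  expect_equal(signed_error(0.0, 2.0), -2.0)
})

test_that("model summaries match a naive independent recomputation", {
  s <- summarize_model(c(-1, 0, 1))
  expect_equal(s$mean_error, 0)
  expect_equal(s$median_error, 0)
  expect_equal(s$sd_error, 1)

  one <- summarize_model(0.3)
  expect_equal(one$sd_error, 0)
  expect_false(one$sd_defined)
  expect_error(summarize_model(numeric(0)), "no records")

  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 2))
    s <- summarize_model(x)
    expect_equal(s$mean_error, sum(x) / length(x))
    expect_equal(s$sd_error, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
    expect_equal(s$median_error, sort(x)[ceiling(length(x) / 2)] / 2 +
                   sort(x)[floor(length(x) / 2) + 1] / 2)
    q <- quantile(x, c(0.25, 0.75), type = 7)
    expect_equal(s$iqr_error, unname(q[2] - q[1]))
  }

  # Monte-Carlo sanity: the mean estimator is unbiased
  set.seed(11)
  x <- rnorm(1000, mean = 0.1, sd = 0.3)
  expect_lt(abs(summarize_model(x)$mean_error - 0.1), 3 * 0.3 / sqrt(1000))
})

test_that("threshold selection takes the argmin with a conservative tie-break", {
  grid <- seq(0, 1, 0.1)
  mk <- function(errs) tibble::tibble(
    validation_set = "internal_bl", threshold = grid, mean_error = errs)
  errs <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.20, 0.05, 0.12, 0.3)
  sel <- select_threshold(mk(errs))
  expect_equal(sel$threshold, 0.8)

  # exact tie resolves to the larger threshold
  tie <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.05, 0.05, 0.12, 0.3)
  expect_equal(select_threshold(mk(tie))$threshold, 0.8)

  # magnitude (default) vs signed selection
  signed <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, -0.02, 0.5, 0.6, 0.7)
  expect_equal(select_threshold(mk(signed))$threshold, 0.7)
  expect_equal(select_threshold(mk(signed), use_magnitude = FALSE)$threshold,
               0.7)

  expect_error(select_threshold(mk(errs)[1:5, ]), "incomplete")
})

test_that("Dice follows the overlap formula with documented empty-mask rules", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:10] <- TRUE; b[1:10] <- TRUE
  expect_equal(dice_si(a, b), 1)

  b[] <- FALSE; b[11:20] <- TRUE  # disjoint
  expect_equal(dice_si(a, b), 0)

  b[] <- FALSE; b[6:15] <- TRUE   # |A|=10, |B|=10, |A n B|=5
  expect_equal(dice_si(a, b), 0.5)

  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(dice_si(empty, b), 0)            # manual empty, predicted not
  expect_true(is.na(dice_si(empty, empty)))     # both empty: undefined
  expect_equal(dice_si(empty, empty, both_empty = "one"), 1)
  expect_error(dice_si(a, array(FALSE, c(2, 2, 2))), "grid")

  # bounds and identity on random masks, against a naive voxel-count oracle
  set.seed(12)
  for (i in 1:25) {
    x <- array(runif(64) < 0.4, c(4, 4, 4))
    y <- array(runif(64) < 0.4, c(4, 4, 4))
    d <- dice_si(x, y)
    if (!is.na(d)) {
      expect_gte(d, 0); expect_lte(d, 1)
      expect_equal(d, 2 * sum(x & y) / (sum(x) + sum(y)))
      if (d == 1) expect_identical(x, y)
    }
  }
})

test_that("composition proportions count low-volume training members", {
  members <- tibble::tibble(
    draw_id = rep(c("a", "b"), c(4, 3)),
    participant_id = c("P1", "P2", "P3", "P4", "P1", "P2", "P5"),
    timepoint = c("BL", "BL", "FU", "BL", "FU", "BL", "BL"))
  volumes <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P4", "P1", "P5"),
    timepoint = c("BL", "BL", "FU", "BL", "FU", "BL"),
    manual_ml = c(0, 0.05, 0.3, 2.0, 0.2, 0))
  errs <- tibble::tibble(draw_id = c("a", "b"), mean_error = c(0.2, -0.1))
  comp <- composition_analysis(members, volumes, errs)
  a <- comp$records[comp$records$draw_id == "a", ]
  expect_equal(a$prop_low1, 0.5)   # {0, 0.05} of 4
  expect_equal(a$prop_low2, 0.75)  # {0, 0.05, 0.3} of 4
  b <- comp$records[comp$records$draw_id == "b", ]
  expect_equal(b$prop_low1, 2 / 3)
  expect_true(all(comp$records$prop_low1 <= comp$records$prop_low2))

  # all-zero draw has both proportions 1
  mz <- tibble::tibble(draw_id = "z", participant_id = c("P1", "P5"),
                       timepoint = "BL")
  vz <- tibble::tibble(participant_id = c("P1", "P5"), timepoint = "BL",
                       manual_ml = c(0, 0))
  cz <- composition_analysis(mz, vz,
                             tibble::tibble(draw_id = "z", mean_error = 0))
  expect_equal(cz$records$prop_low1, 1)
  expect_equal(cz$records$prop_low2, 1)
})

test_that("stratified errors bin by ground-truth volume with a non-negative zero bin", {
  rec <- tibble::tibble(
    manual_ml = c(0, 0, 0.05, 0.3, 1, 5),
    error_ml = c(0.1, 0, -0.02, 0.05, -0.3, -1.2),
    dice = c(NA, 0, 0.2, 0.5, 0.7, 0.6))
  out <- stratified_errors(rec)
  expect_equal(as.character(out$bin),
               c("0", "(0,0.1]", "(0.1,0.5]", "(0.5,2]", ">2"))
  zero_bin <- out[out$bin == "0", ]
  expect_gte(zero_bin$mean_error, 0)  # zero volume cannot be underestimated
  expect_equal(out$mean_error[out$bin == ">2"], -1.2)

  single <- stratified_errors(tibble::tibble(manual_ml = c(1, 1.5),
                                             error_ml = c(0.1, -0.1)))
  expect_equal(nrow(single), 1)
})
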