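# The toy profile (8 paired + 4 external, 24^3 grids, sizes {2, 4}, 5 draws)
# runs the full pipeline in seconds; one run is shared across the blocks.
toy_run <- function() {
  if (is.null(.run_cache$toy)) {
    dir <- file.path(tempdir(), "wmh_toy_run")
    .run_cache$toy <- list(
      dir = dir,
      res = run_experiment(experiment_profile("toy", seed = 3), dir,
                           quiet = TRUE))
  }
  .run_cache$toy
}

test_that("the full pipeline completes with design-consistent record counts", {
  run <- toy_run()
  res <- run$res
  expect_true(file.exists(file.path(run$dir, "raw_records.csv")))
  expect_true(file.exists(file.path(run$dir, "manifest.json")))

  # per (draw, threshold): 2 (8 - n) + 4 predictions
  design <- read.csv(file.path(run$dir, "design.csv"))
  expect_equal(design$per_model, 2 * (8 - c(2, 4)) + 4)
  counts <- dplyr::count(res$records, .data$draw_id, .data$sample_size,
                         .data$threshold)
  expect_true(all(counts$n == (2 * (8 - counts$sample_size) + 4)))
  # grand total: overall column x 11 thresholds
  expect_equal(nrow(res$records), sum(design$overall) * 11)

  # every summary table came out
  for (f in c("summaries.csv", "threshold_selection.csv", "error_by_size.csv",
              "composition.csv", "composition_binned.csv", "stratified.csv"))
    expect_true(file.exists(file.path(run$dir, f)))
  expect_equal(nrow(res$error_by_size), 2 * 3)  # sizes x validation sets
})

test_that("predicted volume is non-increasing in the threshold", {
  res <- toy_run()$res
  viol <- dplyr::summarise(
    dplyr::group_by(res$records, .data$draw_id, .data$participant_id,
                    .data$timepoint),
    ok = all(diff(.data$predicted_ml[order(.data$threshold)]) <= 1e-12),
    .groups = "drop")
  expect_true(all(viol$ok))
})

test_that("identical configurations give byte-identical raw records", {
  run <- toy_run()
  dir2 <- withr::local_tempdir()
  run_experiment(experiment_profile("toy", seed = 3), dir2, quiet = TRUE)
  f1 <- file.path(run$dir, "raw_records.csv")
  f2 <- file.path(dir2, "raw_records.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("summaries are recomputed exactly from raw records (stage isolation)", {
  run <- toy_run()
  before <- tools::md5sum(file.path(run$dir, c("summaries.csv",
                                               "error_by_size.csv",
                                               "stratified.csv",
                                               "composition.csv")))
  file.remove(names(before))
  report_experiment(run$dir, plots = FALSE)
  after <- tools::md5sum(names(before))
  expect_identical(unname(before), unname(after))

  # aggregation oracle: summaries equal a naive recomputation from records
  recs <- read.csv(file.path(run$dir, "raw_records.csv"))
  summ <- read.csv(file.path(run$dir, "summaries.csv"))
  one <- summ[17, ]
  sub <- recs[recs$draw_id == one$draw_id &
                recs$validation_set == one$validation_set &
                recs$threshold == one$threshold, ]
  expect_equal(one$mean_error, mean(sub$error_ml))
  expect_equal(one$sd_error, sd(sub$error_ml))
  expect_equal(one$median_error, median(sub$error_ml))
  expect_equal(one$n_observations, nrow(sub))
})

test_that("a populated outdir is refused without resume, and resume completes it", {
  run <- toy_run()
  expect_error(run_experiment(experiment_profile("toy", seed = 3), run$dir),
               "resume")

  # drop one unit; resume should redo just that unit and reproduce the run
  dir3 <- withr::local_tempdir()
  cfg <- experiment_profile("toy", seed = 3)
  run_experiment(cfg, dir3, quiet = TRUE)
  removed <- file.path(dir3, "records",
                       c("n02_r003.csv", "n02_r003_members.csv"))
  file.remove(removed)
  run_experiment(cfg, dir3, resume = TRUE, quiet = TRUE)
  expect_identical(
    unname(tools::md5sum(file.path(run$dir, "raw_records.csv"))),
    unname(tools::md5sum(file.path(dir3, "raw_records.csv"))))
})

test_that("report errors on an incomplete run directory", {
  dir <- withr::local_tempdir()
  expect_error(report_experiment(dir), "not a completed run")
})

test_that("a YAML configuration reproduces the constructor defaults it sets", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "phantom: {grid_shape: [16, 16, 16], n_paired: 4, n_external: 2}",
    "design: {sample_sizes: [2], n_draws: 3}",
    "policy: {max_lesion_points: 50, max_nonlesion_points: 200}",
    "k: 7",
    "seed: 12"), path)
  cfg <- experiment_config_from_yaml(path)
  expect_s3_class(cfg, "wmh_experiment_config")
  expect_equal(cfg$phantom$n_paired, 4L)
  expect_equal(cfg$design$n_draws, 3L)
  expect_equal(cfg$k, 7)
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$thresholds, seq(0, 1, 0.1))  # default preserved
})
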