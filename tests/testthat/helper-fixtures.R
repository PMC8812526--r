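# Shared fixtures, all generated in code at test time.

# Small, fast phantom configurations
tiny_params <- function(grid = 20, n_paired = 2L, n_external = 1L, seed = 11L,
                        ...) {
  phantom_params(grid_shape = rep(grid, 3), n_paired = n_paired,
                 n_external = n_external, seed = seed, ...)
}

# Noiseless, unsmoothed phantom: tissue classes are exactly separable
clean_params <- function(grid = 20, ...) {
  tiny_params(grid = grid, noise_sd = 0, partial_volume = FALSE, ...)
}

# An id-only cohort stand-in for design-level tests: subjects carry the
# minimal fields the sampling operations touch, so an 80-participant cohort
# costs nothing to build.
id_cohort <- function(n_paired, n_external) {
  stub <- function(pid, tp) structure(
    list(participant_id = pid, timepoint = tp), class = "wmh_subject")
  resampling <- list()
  for (i in seq_len(n_paired)) {
    pid <- sprintf("P%03d", i)
    resampling <- c(resampling, list(stub(pid, "BL"), stub(pid, "FU")))
  }
  external <- lapply(seq_len(n_external),
                     function(i) stub(sprintf("E%03d", i), "FU"))
  structure(list(resampling = resampling, external = external),
            class = "wmh_cohort")
}

# Brute-force k-NN probability oracle: full distance sort with stable index
# tie-break, independent of the compiled path.
knn_oracle <- function(ref, labels, query, k) {
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(ref) - query[i, ])^2)
    sum(labels[order(d2, seq_along(d2))[seq_len(k)]]) / k
  }, 0)
}

# The scaled convergence experiment is shared by several acceptance checks;
# run it once per test session.
.run_cache <- new.env(parent = emptyenv())
scaled_run <- function() {
  if (is.null(.run_cache$scaled)) {
    dir <- file.path(tempdir(), "wmh_scaled_run")
    .run_cache$scaled <- run_experiment(experiment_profile("scaled", seed = 1),
                                        dir, quiet = TRUE)
  }
  .run_cache$scaled
}
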