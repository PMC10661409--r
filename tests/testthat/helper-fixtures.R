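# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small, fast cohort for structural tests (not the study conditions).
tiny_cohort <- function() memo("tiny_cohort", {
  specs <- default_cohort_specs(n_cn = 2, n_ad = 2, duration_s = 12,
                                fs = 200)
  generate_cohort(specs$cn, specs$ad, seed = 101)
})

tiny_features <- function() memo("tiny_features", {
  suppressMessages(suppressWarnings(
    extract_features(lapply(tiny_cohort(), preprocess), seed = 5)))
})

# The default study cohort (10 CN + 10 AD, 2-min recordings at 500 Hz) and
# its feature table; used by the cohort-level statistical and
# classification checks.
study_features <- function() memo("study_features", {
  specs <- default_cohort_specs()
  coh <- generate_cohort(specs$cn, specs$ad, seed = 20240901)
  suppressMessages(
    extract_features(lapply(coh, preprocess), seed = 20240901))
})

# Gaussian feature table with a controllable group shift on a subset of
# features; cheap stand-in for classifier mechanics tests.
gaussian_table <- function(n_subj_per_group = 6, epochs_per_subj = 10,
                           shift = 2, n_shifted = 6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("CN", "AD")) {
    for (s in seq_len(n_subj_per_group)) {
      id <- sprintf("%s%02d", g, s)
      subj_off <- rnorm(length(feature_names), sd = 0.3)
      for (e in seq_len(epochs_per_subj)) {
        x <- rnorm(length(feature_names)) + subj_off
        if (g == "AD") x[seq_len(n_shifted)] <- x[seq_len(n_shifted)] + shift
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, epoch_index = e - 1L, group = g,
          as.list(stats::setNames(x, feature_names)),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Epoch container built directly from a matrix, bypassing preprocessing.
epochs_from_matrix <- function(m, fs, subject = "S1", group = "CN") {
  arr <- array(m, dim = c(nrow(m), ncol(m), 1))
  structure(list(data = arr, fs = fs, subject_id = subject, group = group,
                 epoch_index = 0L, retained = TRUE),
            class = "eeg_epochs")
}
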