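test_that("group_spec enforces its invariants", {
  expect_error(group_spec("CN", 1, band_power_profile = c(delta = 0.5,
    theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.1)), "sum to 1")
  expect_error(group_spec("CN", 1, duration_s = -3), "positive")
  expect_error(group_spec("CN", 1, fs = 80), "90 Hz")
  expect_error(group_spec("CN", 1, regularity = 1), "regularity")
  expect_error(group_spec("CN", 1, coupling = 1.2), "coupling")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- group_spec("CN", 1, duration_s = 4, fs = 200,
                     channel_labels = c("C3", "C4", "Cz"))
  set.seed(99); before <- rnorm(1)
  r1 <- generate_recording(spec, "S1", seed = 7)
  r2 <- generate_recording(spec, "S1", seed = 7)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data,
                         generate_recording(spec, "S1", seed = 8)$data))
  set.seed(99)
  expect_identical(before, rnorm(1))  # with_seed restored the state
  expect_true(all(is.finite(r1$data)))
  expect_identical(rownames(r1$data), c("C3", "C4", "Cz"))
})

test_that("full coupling with no noise duplicates channels exactly", {
  spec <- group_spec("CN", 1, duration_s = 4, fs = 200, coupling = 1,
                     noise_sd = 0, channel_labels = c("C3", "C4", "O1"))
  rec <- generate_recording(spec, "S1", seed = 3)
  cc <- cor(t(rec$data))
  expect_equal(unname(cc), matrix(1, 3, 3), tolerance = 1e-12)
})

test_that("zero coupling gives near-independent channels", {
  spec <- group_spec("CN", 1, duration_s = 60, fs = 500, coupling = 0,
                     noise_sd = 0, channel_labels = c("C3", "C4"))
  rs <- vapply(1:20, function(s) {
    rec <- generate_recording(spec, "S", seed = 1000 + s)
    cor(rec$data[1, ], rec$data[2, ])
  }, 0)
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("an alpha-dominated profile yields dominant alpha band power", {
  spec <- group_spec("CN", 1, duration_s = 20, fs = 500,
                     band_power_profile = c(delta = 0.05, theta = 0.05,
                                            alpha = 0.8, beta = 0.05,
                                            gamma = 0.05),
                     channel_labels = c("O1", "O2"))
  rec <- generate_recording(spec, "S1", seed = 5)
  sf <- spectral_features(rec$data[1, ], rec$fs)
  rbp <- sf[paste0("rbp_", c("delta", "theta", "alpha", "beta", "gamma"))]
  expect_identical(names(which.max(rbp)), "rbp_alpha")
  expect_gt(sf[["rbp_alpha"]], max(rbp[names(rbp) != "rbp_alpha"]))
})

test_that("realized band powers track the target profile", {
  for (sd_seed in 1:2) {
    prof <- if (sd_seed == 1)
      c(delta = 0.20, theta = 0.15, alpha = 0.35, beta = 0.20, gamma = 0.10)
    else
      c(delta = 0.35, theta = 0.25, alpha = 0.20, beta = 0.12, gamma = 0.08)
    spec <- group_spec("X", 1, duration_s = 60, fs = 500, noise_sd = 0,
                       band_power_profile = prof,
                       channel_labels = c("Cz", "Pz"))
    rec <- generate_recording(spec, "S", seed = 40 + sd_seed)
    psd <- welch_psd(rec$data[1, ], rec$fs)
    rbp <- relative_band_power(psd$freq, psd$density)$rbp
    expect_true(all(abs(rbp - prof) < 0.1))
  }
})

test_that("cohorts have the right size, labels, ids, and determinism", {
  mini <- function(label, n) group_spec(label, n, duration_s = 1, fs = 100,
                                        channel_labels = c("C3", "C4"))
  coh <- generate_cohort(mini("CN", 29), mini("AD", 36), seed = 1)
  expect_length(coh, 65)
  subj <- summary(coh)
  expect_identical(sum(subj$group == "AD"), 36L)
  expect_identical(anyDuplicated(subj$subject_id), 0L)

  empty <- generate_cohort(mini("CN", 0), mini("AD", 0), seed = 1)
  expect_length(empty, 0)

  c1 <- generate_cohort(mini("CN", 2), mini("AD", 2), seed = 9)
  c2 <- generate_cohort(mini("CN", 2), mini("AD", 2), seed = 9)
  expect_identical(lapply(c1, `[[`, "data"), lapply(c2, `[[`, "data"))

  expect_error(generate_cohort(mini("CN", 2), mini("CN", 2), seed = 1),
               "labels must differ")
})

test_that("mean inter-channel correlation is non-decreasing in coupling", {
  grid <- c(0, 0.3, 0.6, 0.9)
  mean_abs_r <- vapply(grid, function(cp) {
    spec <- group_spec("X", 1, duration_s = 5, fs = 200, coupling = cp,
                       channel_labels = c("F3", "F4", "C3", "C4"))
    mean(vapply(1:10, function(s) {
      rec <- generate_recording(spec, "S", seed = 2000 + s)
      cm <- abs(cor(t(rec$data)))
      mean(cm[upper.tri(cm)])
    }, 0))
  }, 0)
  expect_true(all(diff(mean_abs_r) > 0))
})

test_that("higher regularity lowers downstream sample entropy", {
  grid <- c(0, 0.5, 0.9)
  se <- vapply(grid, function(rg) {
    spec <- group_spec("X", 1, duration_s = 5, fs = 200, regularity = rg,
                       channel_labels = c("Cz"))
    mean(vapply(1:10, function(s) {
      rec <- generate_recording(spec, "S", seed = 3000 + s)
      sampen(rec$data[1, ])
    }, 0))
  }, 0)
  expect_true(all(diff(se) < 0))
})

test_that("cohort text round-trip preserves data and metadata", {
  coh <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(names(back), names(coh))
  expect_identical(back[["AD01"]]$group, "AD")
  expect_equal(back[["CN01"]]$data, coh[["CN01"]]$data, tolerance = 1e-10)
  expect_identical(back[["CN01"]]$fs, coh[["CN01"]]$fs)
})
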