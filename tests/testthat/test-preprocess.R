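make_rec <- function(data, fs = 500, labels = NULL, subject = "S1") {
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, channel_labels = labels,
                 subject_id = subject, group = "CN",
                 reference = "as-recorded"),
            class = "eeg_recording")
}

test_that("rereference subtracts the mastoid mean and drops the refs", {
  n <- 100
  scalp <- matrix(rnorm(2 * n), 2, n)
  # constant refs a = 2, b = 4 -> scalp minus 3
  data <- rbind(scalp, rep(2, n), rep(4, n))
  rec <- make_rec(data, labels = c("C3", "C4", "A1", "A2"))
  out <- rereference(rec)
  expect_identical(out$channel_labels, c("C3", "C4"))
  expect_equal(out$data[1, ], scalp[1, ] - 3, ignore_attr = TRUE)
  expect_identical(out$reference, "A1-A2")

  # identically zero references leave scalp channels untouched
  rec0 <- make_rec(rbind(scalp, 0, 0), labels = c("C3", "C4", "a1", "a2"))
  expect_equal(rereference(rec0)$data[2, ], scalp[2, ], ignore_attr = TRUE)
})

test_that("a 21-channel montage re-references to 19 channels", {
  data <- matrix(rnorm(21 * 50), 21, 50)
  rec <- make_rec(data, labels = c(channels_1020, "A1", "A2"))
  out <- rereference(rec)
  expect_identical(nrow(out$data), 19L)
  expect_identical(out$channel_labels, channels_1020)
})

test_that("missing refs are an identity with a notice; one ref is an error", {
  rec <- make_rec(matrix(rnorm(40), 2, 20), labels = c("C3", "C4"))
  expect_message(out <- rereference(rec), "left as-is")
  expect_identical(out$data, rec$data)
  rec1 <- make_rec(matrix(rnorm(60), 3, 20), labels = c("C3", "C4", "A1"))
  expect_error(rereference(rec1), "ambiguous montage")
})

test_that("band-pass attenuates stop-band and preserves pass-band tones", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  hum <- sin(2 * pi * 60 * t)        # stop band
  alpha <- sin(2 * pi * 10 * t)      # pass band
  rec <- make_rec(rbind(hum, alpha), fs = fs)
  out <- bandpass(rec)
  # oracle: the designed filter's magnitude response, squared because the
  # filter runs forward and backward
  bt <- signal::butter(4, c(0.5, 45) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 60 / fs * (seq_along(bt$b) - 1))
  gain60 <- Mod(sum(bt$b * z) / sum(bt$a * z))^2
  # finite-length edge effects of filtfilt leave a few percent slack
  expect_equal(rms(out$data[1, ]) / rms(hum), as.numeric(gain60),
               tolerance = 0.05)
  expect_lt(rms(out$data[1, ]), 0.1 * rms(hum))
  expect_lt(abs(rms(out$data[2, ]) - rms(alpha)) / rms(alpha), 0.05)

  zero <- make_rec(matrix(0, 1, 2000), fs = fs)
  expect_equal(max(abs(bandpass(zero)$data)), 0)

  slow <- make_rec(matrix(0, 1, 2000), fs = 80)
  expect_error(bandpass(slow), "Nyquist")
})

test_that("window rejection removes exactly the over-threshold windows", {
  fs <- 100
  rec <- make_rec(matrix(1, 2, 10 * fs), fs = fs)   # constant: SD = 0
  out <- reject_windows(rec)
  expect_identical(ncol(out$data), ncol(rec$data))
  expect_false(any(attr(out, "rejection_mask")))

  # one 0.5-s window with SD 20 on one channel
  data <- matrix(rnorm(2 * 10 * fs), 2, 10 * fs)
  w <- 0.5 * fs
  bad_cols <- (3 * w + 1):(4 * w)
  data[2, bad_cols] <- data[2, bad_cols] / sd(data[2, bad_cols]) * 20
  rec2 <- make_rec(data, fs = fs)
  out2 <- reject_windows(rec2)
  mask <- attr(out2, "rejection_mask")
  expect_identical(which(mask), 4L)
  expect_identical(ncol(out2$data), ncol(data) - as.integer(w))
  expect_equal(out2$data[, 1:(3 * w)], data[, 1:(3 * w)],
               ignore_attr = TRUE)

  # infinite threshold is a vacuous filter
  cfg <- preprocess_config(artifact_sd_threshold = Inf)
  expect_equal(reject_windows(rec2, cfg)$data, data, ignore_attr = TRUE)
})

test_that("window rejection is idempotent", {
  fs <- 200
  set.seed(4)
  data <- matrix(rnorm(3 * 8 * fs, sd = 12), 3, 8 * fs)
  data[1, 401:500] <- data[1, 401:500] * 4
  rec <- make_rec(data, fs = fs)
  once <- reject_windows(rec)
  twice <- reject_windows(once)
  expect_identical(twice$data, once$data)
  expect_false(any(attr(twice, "rejection_mask")))
})

test_that("epoch counts follow the floor formula", {
  fs <- 500
  rec <- make_rec(matrix(rnorm(19 * 60 * fs), 19, 60 * fs), fs = fs)
  es <- make_epochs(rec)
  expect_identical(dim(es$data)[3], 29L)   # floor((30000-2000)/1000)+1
  expect_identical(es$epoch_index, 0:28)

  exact <- make_rec(matrix(rnorm(2 * 4 * fs), 2, 4 * fs), fs = fs)
  expect_identical(dim(make_epochs(exact)$data)[3], 1L)

  five <- make_rec(matrix(rnorm(2 * 5 * fs), 2, 5 * fs), fs = fs)
  expect_identical(dim(make_epochs(five)$data)[3], 1L)  # partial discarded

  short <- make_rec(matrix(rnorm(2 * fs), 2, fs), fs = fs)
  expect_warning(es0 <- make_epochs(short), "shorter than one epoch")
  expect_identical(dim(es0$data)[3], 0L)
})

test_that("epoch grid matches direct enumeration for random lengths", {
  set.seed(11)
  for (i in 1:25) {
    fs <- sample(c(100, 250, 500), 1)
    len_s <- runif(1, 4, 30)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    n <- round(len_s * fs)
    rec <- make_rec(matrix(0, 1, n), fs = fs)
    cfg <- preprocess_config(overlap_fraction = ov)
    L <- 4 * fs
    step <- round(L * (1 - ov))
    expected <- length(seq(1, n - L + 1, by = step))
    es <- suppressWarnings(make_epochs(rec, cfg))
    expect_identical(dim(es$data)[3], as.integer(expected))
  }
})

test_that("epoch content matches the recording at the right offsets", {
  fs <- 100
  n <- 10 * fs
  rec <- make_rec(matrix(as.numeric(seq_len(2 * n)), 2, n), fs = fs)
  es <- make_epochs(rec)
  L <- 4 * fs; step <- 2 * fs
  for (k in c(1, 3)) {
    expect_identical(unname(es$data[, , k]),
                     unname(rec$data[, ((k - 1) * step + 1):((k - 1) * step + L)]))
  }
})
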