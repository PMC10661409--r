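#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain re-reference -> band-pass ->
#' artifact-window rejection -> epoching. Defaults follow standard clinical
#' resting-state practice: 0.5-45 Hz zero-phase Butterworth, a 0.5-s
#' window whose per-channel sample SD may not exceed 17 (microvolts of the
#' calibrated signal), and 4-s epochs with 50% overlap.
#'
#' @param low_hz,high_hz Band-pass corner frequencies (Hz).
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective roll-off is doubled).
#' @param artifact_window_s Length of the artifact screening window (s).
#' @param artifact_sd_threshold Per-channel sample-SD limit above which a
#'   window is excised; units of the signal (microvolts).
#' @param epoch_length_s Epoch length (s).
#' @param overlap_fraction Fractional overlap between consecutive epochs,
#'   in `[0, 1)`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(low_hz = 0.5, high_hz = 45, filter_order = 4,
                              artifact_window_s = 0.5,
                              artifact_sd_threshold = 17,
                              epoch_length_s = 4, overlap_fraction = 0.5) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (filter_order < 1) stop("filter_order must be >= 1")
  if (artifact_window_s <= 0) stop("artifact_window_s must be positive")
  if (epoch_length_s <= 0) stop("epoch_length_s must be positive")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 filter_order = filter_order,
                 artifact_window_s = artifact_window_s,
                 artifact_sd_threshold = artifact_sd_threshold,
                 epoch_length_s = epoch_length_s,
                 overlap_fraction = overlap_fraction),
            class = "preprocess_config")
}

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the two reference channels (default A1/A2) from
#' every scalp channel and drops the reference channels. Matching is
#' case-insensitive. If the recording carries neither reference channel
#' (the synthetic default), the recording is returned unchanged with a
#' notice; exactly one of the two present is an error (ambiguous montage).
#'
#' @param rec An `eeg_recording`.
#' @param ref_labels Character pair of reference channel names.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, ref_labels = c("A1", "A2")) {
  stopifnot(length(ref_labels) == 2)
  idx <- match(tolower(ref_labels), tolower(rec$channel_labels))
  if (all(is.na(idx))) {
    message("rereference: no ", paste(ref_labels, collapse = "/"),
            " channels found; recording left as-is")
    return(rec)
  }
  if (any(is.na(idx)))
    stop("ambiguous montage: only one of ",
         paste(ref_labels, collapse = "/"), " present")
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$data)), idx)
  data <- sweep(rec$data[keep, , drop = FALSE], 2, ref)
  new_eeg_recording(data, rec$fs, rec$channel_labels[keep],
                    rec$subject_id, rec$group,
                    reference = paste(ref_labels, collapse = "-"))
}

# Zero-phase Butterworth band-pass, designed once per (order, band, fs).
butter_sos <- function(order, low_hz, high_hz, fs) {
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`filter_order` Butterworth band-pass forward and
#' backward ([signal::filtfilt()]) to every channel, so the output is free
#' of phase distortion (which would otherwise bias the entropy features).
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return Filtered `eeg_recording` of identical dimensions.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  if (rec$fs <= 2 * cfg$high_hz)
    stop("sampling rate ", rec$fs, " Hz violates the Nyquist constraint: ",
         "need fs > ", 2 * cfg$high_hz, " Hz for a ", cfg$high_hz,
         " Hz band edge")
  bt <- butter_sos(cfg$filter_order, cfg$low_hz, cfg$high_hz, rec$fs)
  data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bt, x)))
  dimnames(data) <- dimnames(rec$data)
  new_eeg_recording(data, rec$fs, rec$channel_labels, rec$subject_id,
                    rec$group, rec$reference)
}

#' Excise high-variance artifact windows
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `artifact_window_s` seconds; a window is bad when any channel's sample
#' standard deviation within it exceeds `artifact_sd_threshold`. Bad
#' windows are removed and the remaining data concatenated. A trailing
#' partial window is kept untested. This window-SD exclusion rule is a
#' deliberately simple, fully reproducible artifact screen; it does not
#' attempt component-based artifact removal.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return The cleaned `eeg_recording`, with attribute `rejection_mask`
#'   (logical, `TRUE` = window removed) for audit.
#' @export
reject_windows <- function(rec, cfg = preprocess_config()) {
  w <- round(cfg$artifact_window_s * rec$fs)
  n <- ncol(rec$data)
  if (n < w) stop("recording shorter than one artifact window")
  nw <- n %/% w
  bad <- logical(nw)
  for (k in seq_len(nw)) {
    cols <- ((k - 1) * w + 1):(k * w)
    sds <- apply(rec$data[, cols, drop = FALSE], 1, sd)
    bad[k] <- any(sds > cfg$artifact_sd_threshold)
  }
  keep_cols <- c(unlist(lapply(which(!bad),
                               function(k) ((k - 1) * w + 1):(k * w)),
                        use.names = FALSE),
                 if (nw * w < n) (nw * w + 1):n)
  out <- new_eeg_recording(rec$data[, keep_cols, drop = FALSE], rec$fs,
                           rec$channel_labels, rec$subject_id, rec$group,
                           rec$reference)
  attr(out, "rejection_mask") <- bad
  out
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Epochs of `epoch_length_s` seconds start every
#' `epoch_length_s * (1 - overlap_fraction)` seconds, anchored at the first
#' sample; a trailing partial epoch is discarded. The epoch count is
#' `floor((n_samples - L) / step) + 1`.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return An `eeg_epochs` object: 3-D array `channels x L x n_epochs` plus
#'   metadata (`fs`, `subject_id`, `group`, 0-based `epoch_index`).
#' @export
make_epochs <- function(rec, cfg = preprocess_config()) {
  L <- round(cfg$epoch_length_s * rec$fs)
  step <- max(1L, round(L * (1 - cfg$overlap_fraction)))
  n <- ncol(rec$data)
  if (n < L) {
    warning("recording shorter than one epoch for subject ",
            rec$subject_id, "; empty epoch set")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n - L + 1L, by = step)
  }
  arr <- array(0, dim = c(nrow(rec$data), L, length(starts)),
               dimnames = list(rec$channel_labels, NULL, NULL))
  for (i in seq_along(starts))
    arr[, , i] <- rec$data[, starts[i]:(starts[i] + L - 1L)]
  structure(list(data = arr, fs = rec$fs, subject_id = rec$subject_id,
                 group = rec$group,
                 epoch_index = seq_along(starts) - 1L,
                 retained = rep(TRUE, length(starts))),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> subject %s (%s): %d epochs of %d samples x %d channels @ %g Hz\n",
              x$subject_id, x$group, dim(x$data)[3], dim(x$data)[2],
              dim(x$data)[1], x$fs))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order and exactly once each: [rereference()], [bandpass()],
#' [reject_windows()], [make_epochs()].
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @param ref_labels Reference channel pair passed to [rereference()].
#' @return An `eeg_epochs` object.
#' @export
preprocess <- function(rec, cfg = preprocess_config(),
                       ref_labels = c("A1", "A2")) {
  rec <- suppressMessages(rereference(rec, ref_labels))
  rec <- bandpass(rec, cfg)
  rec <- reject_windows(rec, cfg)
  make_epochs(rec, cfg)
}
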