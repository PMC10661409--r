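#' Specify one synthetic EEG group
#'
#' Bundles the generative parameters for one diagnostic group (CN or AD) of
#' the synthetic cohort. Three knobs map onto the three resting-state EEG
#' effect families reported for Alzheimer's disease: the band-power profile
#' (spectral slowing), the AR(1) regularity coefficient (reduced signal
#' complexity), and the shared-source coupling fraction (decreased
#' inter-channel synchrony).
#'
#' Each rhythm source is built as white noise passed through an AR(1)
#' recursion with coefficient `regularity`, restricted to the rhythm's
#' frequency range, and scaled so its variance fraction equals the profile
#' entry. A channel is `coupling` times the sum of shared (cohort-latent)
#' sources plus `1 - coupling` times an independently drawn per-channel sum
#' built the same way, plus `noise_sd` times white noise; the composite is
#' scaled to `amplitude_uv` microvolts RMS before the noise term is added on
#' the same normalized scale.
#'
#' @param label Group name, `"CN"` or `"AD"`.
#' @param n_subjects Number of subjects to generate.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz; must exceed 90 Hz (twice the 45 Hz upper
#'   analysis edge).
#' @param band_power_profile Named non-negative vector over
#'   `delta, theta, alpha, beta, gamma` summing to 1: the target relative
#'   band power of each rhythm.
#' @param regularity AR(1) coefficient in `[0, 0.99)` applied to every band
#'   source; higher values give smoother, more regular signals and hence
#'   lower entropy.
#' @param coupling Fraction in `[0, 1]` of each channel drawn from the
#'   shared latent sources; higher values give stronger inter-channel
#'   correlation.
#' @param noise_sd Scale of channel-independent white noise, on the
#'   normalized (unit-RMS composite) scale.
#' @param amplitude_uv Nominal RMS amplitude of the composite in microvolts.
#' @param channel_labels Channel names; defaults to the 19 scalp electrodes
#'   of the 10-20 montage ([channels_1020]).
#' @return A `group_spec` object (validated list).
#' @seealso [generate_recording()], [generate_cohort()],
#'   [default_cohort_specs()]
#' @export
group_spec <- function(label,
                       n_subjects,
                       duration_s = 120,
                       fs = 500,
                       band_power_profile = c(delta = 0.20, theta = 0.15,
                                              alpha = 0.35, beta = 0.20,
                                              gamma = 0.10),
                       regularity = 0.3,
                       coupling = 0.5,
                       noise_sd = 0.1,
                       amplitude_uv = 10,
                       channel_labels = channels_1020) {
  spec <- structure(
    list(label = as.character(label), n_subjects = as.integer(n_subjects),
         duration_s = duration_s, fs = fs,
         band_power_profile = band_power_profile,
         regularity = regularity, coupling = coupling, noise_sd = noise_sd,
         amplitude_uv = amplitude_uv, channel_labels = channel_labels),
    class = "group_spec")
  validate_group_spec(spec)
  spec
}

validate_group_spec <- function(spec) {
  bp <- spec$band_power_profile
  rhythms <- c("delta", "theta", "alpha", "beta", "gamma")
  if (!setequal(names(bp), rhythms))
    stop("band_power_profile must be named over: ",
         paste(rhythms, collapse = ", "))
  if (any(bp < 0))
    stop("band_power_profile values must be non-negative")
  if (abs(sum(bp) - 1) > 1e-9)
    stop("band_power_profile must sum to 1 (got ", format(sum(bp)), ")")
  if (spec$duration_s <= 0) stop("duration_s must be positive")
  if (spec$fs <= 0) stop("fs must be positive")
  if (spec$fs <= 2 * 45)
    stop("fs must exceed 90 Hz (twice the 45 Hz analysis band edge)")
  if (spec$regularity < 0 || spec$regularity >= 1)
    stop("regularity must lie in [0, 1)")
  if (spec$coupling < 0 || spec$coupling > 1)
    stop("coupling must lie in [0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  if (spec$n_subjects < 0) stop("n_subjects must be non-negative")
  invisible(spec)
}

#' Default CN and AD group specifications
#'
#' The cohort conditions used throughout the package's examples and tests:
#' `n_cn` control and `n_ad` patient subjects, 2-minute recordings at
#' 500 Hz. Relative to controls, the AD group has elevated delta/theta and
#' attenuated alpha/beta/gamma power, a higher AR(1) regularity (lower
#' entropy), and weaker shared-source coupling (lower synchrony).
#'
#' @param n_cn,n_ad Subject counts per group.
#' @param duration_s,fs Recording length (s) and sampling rate (Hz).
#' @return Named list with elements `cn` and `ad`, each a [group_spec()].
#' @export
default_cohort_specs <- function(n_cn = 10, n_ad = 10,
                                 duration_s = 120, fs = 500) {
  list(
    cn = group_spec("CN", n_cn, duration_s, fs,
                    band_power_profile = c(delta = 0.20, theta = 0.15,
                                           alpha = 0.35, beta = 0.20,
                                           gamma = 0.10),
                    regularity = 0.30, coupling = 0.62, noise_sd = 0.10),
    ad = group_spec("AD", n_ad, duration_s, fs,
                    band_power_profile = c(delta = 0.35, theta = 0.25,
                                           alpha = 0.20, beta = 0.12,
                                           gamma = 0.08),
                    regularity = 0.65, coupling = 0.60, noise_sd = 0.10))
}

# Ideal (FFT-mask) band restriction: zero all Fourier components outside
# [lo, hi) Hz. Disjoint band supports make the five rhythm sources exactly
# orthogonal, so their variances add and the realized band-power profile
# tracks the target closely.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  keep <- f >= lo & f < hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

rhythm_edges <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                     beta = c(13, 25), gamma = c(25, 45))

# One summed multi-rhythm source of length n: per rhythm, white noise ->
# AR(1) -> band restriction -> variance scaled to the profile fraction.
make_source_sum <- function(n, fs, profile, regularity) {
  out <- numeric(n)
  for (rh in names(rhythm_edges)) {
    w <- rnorm(n)
    if (regularity > 0)
      w <- as.numeric(stats::filter(w, regularity, method = "recursive"))
    b <- fft_bandpass(w, fs, rhythm_edges[[rh]][1], rhythm_edges[[rh]][2])
    s <- sd(b)
    if (s > 0) out <- out + b * sqrt(profile[[rh]]) / s
  }
  out
}

#' Generate one synthetic EEG recording
#'
#' Draws a multichannel recording under a [group_spec()]. For each rhythm a
#' shared latent source is built (white noise, AR(1) with the spec's
#' `regularity`, band restriction, variance scaled to the band-power
#' profile); each channel mixes `coupling` times the summed shared sources
#' with `1 - coupling` times per-channel sources built the same way, plus
#' independent white noise. The same `(spec, subject_id, seed)` always
#' yields bit-identical data; the caller's RNG state is left untouched.
#'
#' @param spec A [group_spec()].
#' @param subject_id Subject identifier stored in the recording.
#' @param seed Integer seed for this recording.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts, rownames = channel labels), `fs`, `channel_labels`,
#'   `subject_id`, `group` and `reference`.
#' @examples
#' spec <- group_spec("CN", 1, duration_s = 10, fs = 200)
#' rec <- generate_recording(spec, "CN01", seed = 1)
#' dim(rec$data)
#' @export
generate_recording <- function(spec, subject_id, seed) {
  validate_group_spec(spec)
  n <- round(spec$duration_s * spec$fs)
  nch <- length(spec$channel_labels)
  with_seed(as.integer(seed), {
    shared <- make_source_sum(n, spec$fs, spec$band_power_profile,
                              spec$regularity)
    data <- matrix(0, nrow = nch, ncol = n,
                   dimnames = list(spec$channel_labels, NULL))
    for (ch in seq_len(nch)) {
      indiv <- make_source_sum(n, spec$fs, spec$band_power_profile,
                               spec$regularity)
      data[ch, ] <- spec$amplitude_uv *
        (spec$coupling * shared + (1 - spec$coupling) * indiv +
           spec$noise_sd * rnorm(n))
    }
    stopifnot(all(is.finite(data)))
    new_eeg_recording(data, spec$fs, spec$channel_labels,
                      subject_id, spec$label, reference = "none (synthetic)")
  })
}

new_eeg_recording <- function(data, fs, channel_labels, subject_id, group,
                              reference) {
  stopifnot(nrow(data) == length(channel_labels))
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, group = group,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s), %d channels x %d samples @ %g Hz, ref: %s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              x$reference))
  invisible(x)
}

#' Generate a two-group synthetic cohort
#'
#' Generates `cn$n_subjects + ad$n_subjects` recordings with unique subject
#' ids (`<label><index>`), one deterministic per-subject seed derived from
#' the master seed, and correct group labels.
#'
#' @param cn,ad [group_spec()] objects for the two groups; their labels must
#'   differ.
#' @param seed Master integer seed.
#' @return An `eeg_cohort`: list of `eeg_recording`s with a `subjects`
#'   attribute (data frame of `subject_id`, `group`, `seed`).
#' @examples
#' specs <- default_cohort_specs(n_cn = 2, n_ad = 2, duration_s = 8, fs = 200)
#' coh <- generate_cohort(specs$cn, specs$ad, seed = 42)
#' length(coh)
#' @export
generate_cohort <- function(cn, ad, seed) {
  validate_group_spec(cn)
  validate_group_spec(ad)
  if (identical(cn$label, ad$label))
    stop("the two group labels must differ (duplicate subject ids)")
  specs <- c(rep(list(cn), cn$n_subjects), rep(list(ad), ad$n_subjects))
  ids <- c(sprintf("%s%02d", cn$label, seq_len(cn$n_subjects)),
           sprintf("%s%02d", ad$label, seq_len(ad$n_subjects)))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  recs <- vector("list", length(ids))
  seeds <- integer(length(ids))
  for (i in seq_along(ids)) {
    seeds[i] <- derive_seed(seed, i)
    recs[[i]] <- generate_recording(specs[[i]], ids[i], seeds[i])
  }
  structure(recs, names = ids, class = "eeg_cohort",
            subjects = data.frame(subject_id = ids,
                                  group = vapply(specs, `[[`, "", "label"),
                                  seed = seeds,
                                  stringsAsFactors = FALSE))
}

#' @export
print.eeg_cohort <- function(x, ...) {
  subj <- attr(x, "subjects")
  cat(sprintf("<eeg_cohort> %d recordings (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(subj$group)),
                            as.integer(table(subj$group))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.eeg_cohort <- function(object, ...) {
  attr(object, "subjects")
}
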