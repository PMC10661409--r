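#' Canonical EEG rhythm band definitions
#'
#' Half-open bands `[lo, hi)` jointly covering 0.5-45 Hz: delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-25, gamma 25-45 Hz.
#'
#' @return Data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo_hz = c(0.5, 4, 8, 13, 25),
             hi_hz = c(4, 8, 13, 25, 45),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(all(c("name", "lo_hz", "hi_hz") %in% names(bands)))
  if (any(bands$lo_hz >= bands$hi_hz)) stop("bands must have lo_hz < hi_hz")
  o <- order(bands$lo_hz)
  if (any(bands$hi_hz[o][-nrow(bands)] > bands$lo_hz[o][-1] + 1e-12))
    stop("bands must be non-overlapping")
  invisible(bands)
}

#' Time-domain statistics of one epoch channel
#'
#' Mean, variance (denominator `N - 1`) and interquartile range
#' (`Q3 - Q1`, linear-interpolation quantiles, i.e. [stats::quantile()]
#' type 7 — stated because IQR differs across quantile conventions).
#'
#' @param x Numeric sample series of length >= 2.
#' @return Named numeric vector `c(mean, variance, iqr)`.
#' @export
time_domain <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples (variance undefined)")
  c(mean = mean(x), variance = var(x),
    iqr = unname(diff(quantile(x, c(0.25, 0.75), type = 7))))
}

#' Welch power spectral density of one epoch channel
#'
#' One-sided PSD by Welch's method: the series is split into
#' `segment_s`-second segments with `overlap` fractional overlap, each
#' Hamming-tapered, and the modified periodograms are averaged. With the
#' defaults a 4-s epoch at 500 Hz yields 7 averaged 1-s segments and ~1 Hz
#' resolution. The density integrates (rectangle rule over bins) to the
#' signal's mean power.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param segment_s Welch segment length in seconds.
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `density` (power per Hz, >= 0).
#' @export
welch_psd <- function(x, fs, segment_s = 1, overlap = 0.5) {
  nseg <- round(segment_s * fs)
  if (length(x) < nseg)
    stop("series shorter than one Welch segment (", nseg, " samples)")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  u <- sum(w^2)                      # window power normalization
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- Mod(fft(seg))^2 / (fs * u)
    half <- p[seq_len(nfreq)]
    # fold negative frequencies into the one-sided density
    half[2:(nfreq - if (nseg %% 2 == 0) 1 else 0)] <-
      2 * half[2:(nfreq - if (nseg %% 2 == 0) 1 else 0)]
    acc <- acc + half
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nseg,
       density = acc / length(starts))
}

# Trapezoidal integral of density over [lo, hi], with ordinates linearly
# interpolated at the interval edges so adjacent bands partition the total
# exactly.
band_energy <- function(freq, density, lo, hi) {
  lo <- max(lo, min(freq)); hi <- min(hi, max(freq))
  if (hi <= lo) return(0)
  inner <- freq > lo & freq < hi
  f <- c(lo, freq[inner], hi)
  d <- c(stats::approx(freq, density, lo)$y, density[inner],
         stats::approx(freq, density, hi)$y)
  sum(diff(f) * (head(d, -1) + d[-1]) / 2)
}

#' Relative band power from a PSD
#'
#' `Energy_i` is the trapezoidal integral of the density over band `i`;
#' the relative band power is `Energy_i / sum(Energy_i)` and `total_power`
#' is the integral over the full analysis range (0.5-45 Hz with the default
#' bands).
#'
#' @param freq,density A PSD as returned by [welch_psd()].
#' @param bands Band definition table ([eeg_bands()]).
#' @return List with `rbp` (named fractions summing to 1) and
#'   `total_power`.
#' @export
relative_band_power <- function(freq, density, bands = eeg_bands()) {
  validate_bands(bands)
  e <- vapply(seq_len(nrow(bands)), function(i)
    band_energy(freq, density, bands$lo_hz[i], bands$hi_hz[i]), 0)
  names(e) <- bands$name
  tot <- sum(e)
  if (tot <= 0)
    stop(errorCondition("degenerate epoch: zero spectral power, RBP undefined",
                        class = "adeeg_degenerate_epoch"))
  list(rbp = e / tot, total_power = tot)
}

#' All spectral features of one epoch channel
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param bands Band definition table.
#' @param segment_s,overlap Welch settings, see [welch_psd()].
#' @return Named numeric vector: `mean`, `variance`, `iqr`, `rbp_<band>`
#'   for each band, `total_power`.
#' @export
spectral_features <- function(x, fs, bands = eeg_bands(),
                              segment_s = 1, overlap = 0.5) {
  td <- time_domain(x)
  psd <- welch_psd(x, fs, segment_s, overlap)
  rb <- relative_band_power(psd$freq, psd$density, bands)
  c(td, stats::setNames(rb$rbp, paste0("rbp_", names(rb$rbp))),
    total_power = rb$total_power)
}
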