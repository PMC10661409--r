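#' Entropy configuration
#'
#' Parameters of the four per-channel complexity features. The tolerance
#' `r` is always `r_factor` times the sample SD of the series the entropy
#' is computed on (for multiscale entropy, the SD of the original series by
#' default; see `mse_r_on_coarse`).
#'
#' @param apen_m,apen_r_factor Approximate entropy: template length (1) and
#'   similarity factor (0.2).
#' @param permen_order Ordinal pattern length for permutation entropy (3).
#' @param sampen_m,sampen_r_factor Sample entropy: template length (2) and
#'   similarity factor (0.15).
#' @param mse_m,mse_r_factor,mse_tau Multiscale entropy: sample-entropy
#'   parameters applied to the coarse-grained series at scale `tau` (5).
#' @param mse_scales `"single"` (default) computes sample entropy at scale
#'   `tau` only; `"average"` averages scales `1..tau`.
#' @param mse_r_on_coarse If `TRUE`, recompute `r` from the coarse-grained
#'   series instead of the original.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(apen_m = 1, apen_r_factor = 0.2,
                           permen_order = 3,
                           sampen_m = 2, sampen_r_factor = 0.15,
                           mse_m = 2, mse_r_factor = 0.15, mse_tau = 5,
                           mse_scales = c("single", "average"),
                           mse_r_on_coarse = FALSE) {
  stopifnot(apen_m >= 1, sampen_m >= 1, mse_m >= 1, permen_order >= 2,
            mse_tau >= 1,
            apen_r_factor > 0, apen_r_factor < 1,
            sampen_r_factor > 0, sampen_r_factor < 1,
            mse_r_factor > 0, mse_r_factor < 1)
  structure(list(apen_m = as.integer(apen_m),
                 apen_r_factor = apen_r_factor,
                 permen_order = as.integer(permen_order),
                 sampen_m = as.integer(sampen_m),
                 sampen_r_factor = sampen_r_factor,
                 mse_m = as.integer(mse_m), mse_r_factor = mse_r_factor,
                 mse_tau = as.integer(mse_tau),
                 mse_scales = match.arg(mse_scales),
                 mse_r_on_coarse = isTRUE(mse_r_on_coarse)),
            class = "entropy_config")
}

#' Approximate entropy
#'
#' `ApEn(m, r, N) = phi^m(r) - phi^{m+1}(r)` with templates compared under
#' the Chebyshev (maximum-coordinate) distance and self-matches included
#' (the Pincus convention). A constant series (tolerance `r <= 0` when `r`
#' is SD-relative) is perfectly regular and returns 0 with a notice.
#'
#' @param x Numeric series, length > `m + 1`.
#' @param m Template length.
#' @param r Absolute tolerance; if `NULL`, `r_factor * sd(x)`.
#' @param r_factor Tolerance as a fraction of the series SD.
#' @return Non-negative scalar (up to floating tolerance).
#' @export
apen <- function(x, m = 1, r = NULL, r_factor = 0.2) {
  if (length(x) <= m + 1) stop("series too short for ApEn")
  r <- r %||% (r_factor * sd(x))
  if (r <= 0) {
    message("apen: zero tolerance (constant series); returning 0")
    return(0)
  }
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Permutation entropy
#'
#' Shannon entropy (natural log, unnormalized) of the ordinal patterns of
#' length `n` in a sliding window: each window maps to the permutation that
#' sorts it, with ties broken by the earlier index first. Lies in
#' `[0, log(factorial(n))]`. An all-equal series has a single ordinal
#' pattern and returns 0 with a notice.
#'
#' @param x Numeric series, length >= `n`.
#' @param n Ordinal pattern (embedding) length.
#' @return Scalar in `[0, log(factorial(n))]`.
#' @export
permen <- function(x, n = 3) {
  if (length(x) < n) stop("series shorter than the pattern length")
  if (length(unique(x)) == 1L) {
    message("permen: all-equal series; returning 0")
    return(0)
  }
  .permen_cpp(as.numeric(x), as.integer(n))
}

#' Sample entropy
#'
#' `-log(B_{m+1} / B_m)` where `B_m` and `B_{m+1}` count ordered template
#' pairs (`i != j`) within Chebyshev distance `r` at lengths `m` and
#' `m + 1`, both over the `N - m` templates of the Richman-Moorman
#' construction; self-matches are excluded. When no `(m+1)`-length pair
#' matches the value is undefined and `NA` is returned (callers drop such
#' epochs with a logged count).
#'
#' @inheritParams apen
#' @param r_factor Tolerance as a fraction of the series SD (default 0.15).
#' @return Non-negative scalar, or `NA` if undefined.
#' @export
sampen <- function(x, m = 2, r = NULL, r_factor = 0.15) {
  if (length(x) <= m + 1) stop("series too short for SampEn")
  r <- r %||% (r_factor * sd(x))
  if (r < 0) stop("r must be non-negative")
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

# Non-overlapping block means of tau consecutive samples.
coarse_grain <- function(x, tau) {
  n <- length(x) %/% tau
  if (n < 1) stop("series too short to coarse-grain at scale ", tau)
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Multiscale entropy at one scale
#'
#' Sample entropy of the coarse-grained series (non-overlapping means of
#' `tau` consecutive samples). The tolerance is anchored to the SD of the
#' ORIGINAL series by default (`r_on_coarse = FALSE`), the common practice;
#' with `scales = "average"` the mean sample entropy over scales `1..tau`
#' is returned instead of the single scale-`tau` value.
#'
#' @param x Numeric series with `floor(length(x)/tau) > m + 2`.
#' @param m,r_factor Sample-entropy parameters.
#' @param tau Coarse-graining scale.
#' @param scales `"single"` or `"average"`, see above.
#' @param r_on_coarse Recompute the tolerance from each coarse series.
#' @return Scalar, or `NA` if the underlying sample entropy is undefined.
#' @export
mse <- function(x, m = 2, r_factor = 0.15, tau = 5,
                scales = c("single", "average"), r_on_coarse = FALSE) {
  scales <- match.arg(scales)
  # a coarse series of m + 2 samples holds only one template pair; require
  # strictly more so the match ratio is not vacuous
  if (length(x) %/% tau <= m + 2)
    stop("coarse-grained series too short (floor(N/tau) must exceed m + 2)")
  r0 <- r_factor * sd(x)
  one <- function(t) {
    y <- coarse_grain(x, t)
    sampen(y, m, r = if (r_on_coarse) r_factor * sd(y) else r0)
  }
  if (scales == "single") one(tau) else mean(vapply(seq_len(tau), one, 0))
}

#' All complexity features of one epoch channel
#'
#' @param x Numeric sample series.
#' @param cfg An [entropy_config()].
#' @return Named numeric vector `c(apen, permen, sampen, mse)`; entries may
#'   be `NA` when sample entropy is undefined.
#' @export
complexity_features <- function(x, cfg = entropy_config()) {
  c(apen = suppressMessages(apen(x, cfg$apen_m, r_factor = cfg$apen_r_factor)),
    permen = suppressMessages(permen(x, cfg$permen_order)),
    sampen = sampen(x, cfg$sampen_m, r_factor = cfg$sampen_r_factor),
    mse = mse(x, cfg$mse_m, r_factor = cfg$mse_r_factor, tau = cfg$mse_tau,
              scales = cfg$mse_scales, r_on_coarse = cfg$mse_r_on_coarse))
}
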