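#' Assemble the 18-feature table from epoched data
#'
#' For every retained epoch, the scalar feature families (time-domain,
#' spectral, complexity) are computed per channel and averaged across
#' channels (`channel_aggregate = "feature_mean"`, the default) or computed
#' once on the across-channel mean signal (`"signal_mean"`); the five
#' synchronization features are computed once per epoch from the all-channel
#' correlation graph. Epochs with any undefined feature (e.g. sample
#' entropy without a template match, or an edgeless graph) are dropped with
#' a logged count.
#'
#' @param epochs An `eeg_epochs` object ([make_epochs()]) or a list of them
#'   (one per subject).
#' @param entropy_cfg An [entropy_config()].
#' @param bands Band definition table ([eeg_bands()]).
#' @param threshold Graph binarization threshold ([binarize()]).
#' @param n_random Null-graph count for [small_worldness()].
#' @param seed Integer seed for the null models (per-epoch seeds are derived
#'   deterministically from it).
#' @param channel_aggregate Scalar-feature aggregation mode, see above.
#' @param welch_segment_s,welch_overlap Welch settings ([welch_psd()]).
#' @return A `feature_table` data frame: `subject_id`, `epoch_index`,
#'   `group`, then the 18 columns of [feature_names].
#' @export
extract_features <- function(epochs,
                             entropy_cfg = entropy_config(),
                             bands = eeg_bands(),
                             threshold = 0.7,
                             n_random = 20,
                             seed = 1,
                             channel_aggregate = c("feature_mean",
                                                   "signal_mean"),
                             welch_segment_s = 1, welch_overlap = 0.5) {
  channel_aggregate <- match.arg(channel_aggregate)
  if (inherits(epochs, "eeg_epochs")) epochs <- list(epochs)
  if (length(epochs) == 0 || all(vapply(epochs, function(e)
    dim(e$data)[3], 0L) == 0L)) {
    warning("no epochs to extract features from; empty table")
    return(empty_feature_table())
  }

  rows <- list()
  dropped <- 0L
  for (es in epochs) {
    ne <- dim(es$data)[3]
    for (k in seq_len(ne)) {
      if (!es$retained[k]) next
      ep <- es$data[, , k]
      scal <- tryCatch(
        epoch_scalar_features(ep, es$fs, entropy_cfg, bands,
                              channel_aggregate,
                              welch_segment_s, welch_overlap),
        adeeg_degenerate_epoch = function(e) NA_real_)
      net <- network_features(ep, threshold = threshold,
                              n_random = n_random,
                              seed = derive_seed(seed, length(rows) + 1L))
      fv <- c(scal, net)[feature_names]
      if (anyNA(fv)) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = es$subject_id,
                   epoch_index = es$epoch_index[k],
                   group = es$group,
                   as.list(fv), stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message("extract_features: dropped ", dropped,
            " epoch(s) with undefined features")
  if (length(rows) == 0) {
    warning("all epochs dropped; empty table")
    return(empty_feature_table())
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", "data.frame")
  tab
}

epoch_scalar_features <- function(ep, fs, entropy_cfg, bands,
                                  channel_aggregate,
                                  welch_segment_s, welch_overlap) {
  one <- function(x)
    c(spectral_features(x, fs, bands, welch_segment_s, welch_overlap),
      suppressMessages(complexity_features(x, entropy_cfg)))
  if (channel_aggregate == "signal_mean") return(one(colMeans(ep)))
  per_ch <- vapply(seq_len(nrow(ep)), function(i) one(ep[i, ]),
                   numeric(13))
  rowMeans(per_ch)
}

empty_feature_table <- function() {
  tab <- data.frame(subject_id = character(0), epoch_index = integer(0),
                    group = character(0))
  for (f in feature_names) tab[[f]] <- numeric(0)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Write / read a feature table as CSV
#'
#' Fixed 21-column layout: `subject_id`, `epoch_index`, `group`, then the
#' 18 features in the order of [feature_names].
#'
#' @param tab A `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(tab, path) {
  write.csv(tab[, c("subject_id", "epoch_index", "group", feature_names)],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "epoch_index", "group", feature_names),
                     names(tab))
  if (length(missing))
    stop("feature table is missing columns: ",
         paste(missing, collapse = ", "))
  class(tab) <- c("feature_table", "data.frame")
  tab
}
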