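#' Write a cohort to delimited text files
#'
#' One tab-separated file per subject (`<subject_id>.txt`, samples as rows,
#' channels as columns, header row of channel labels) plus a
#' `subjects.csv` sidecar (`subject_id`, `group`, `fs`).
#'
#' @param cohort An `eeg_cohort` (or list of `eeg_recording`s).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- data.frame(subject_id = character(0), group = character(0),
                     fs = numeric(0))
  for (rec in cohort) {
    p <- file.path(dir, paste0(rec$subject_id, ".txt"))
    write_recording(rec, p)
    paths <- c(paths, p)
    meta <- rbind(meta, data.frame(subject_id = rec$subject_id,
                                   group = rec$group, fs = rec$fs))
  }
  mp <- file.path(dir, "subjects.csv")
  write.csv(meta, mp, row.names = FALSE)
  invisible(c(paths, mp))
}

#' Write one recording as a delimited text matrix
#'
#' @param rec An `eeg_recording`.
#' @param path Output file; tab-separated, channels as columns with a header
#'   row of channel labels.
#' @return Invisibly `path`.
#' @export
write_recording <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read one recording from a delimited text matrix
#'
#' Accepts the format written by [write_recording()]: a header row of
#' channel labels, samples as rows. Channel-label matching elsewhere in the
#' package is case-insensitive.
#'
#' @param path Input file (any whitespace/tab/comma separated matrix with a
#'   header).
#' @param fs Sampling rate in Hz (not stored in the text format).
#' @param subject_id,group Metadata to attach; `subject_id` defaults to the
#'   file name without extension.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, fs, subject_id = NULL, group = NA_character_) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  m <- as.matrix(read.csv(path, sep = sep, check.names = FALSE))
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite samples in ", path)
  labels <- colnames(m)
  new_eeg_recording(t(m), fs = fs, channel_labels = labels,
                    subject_id = subject_id %||%
                      sub("\\.[^.]*$", "", basename(path)),
                    group = group, reference = "as-recorded")
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding `<subject_id>.txt` files and `subjects.csv`.
#' @return An `eeg_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- read.csv(file.path(dir, "subjects.csv"),
                   stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    read_recording(file.path(dir, paste0(meta$subject_id[i], ".txt")),
                   fs = as.numeric(meta$fs[i]),
                   subject_id = meta$subject_id[i],
                   group = meta$group[i])
  })
  structure(recs, names = meta$subject_id, class = "eeg_cohort",
            subjects = meta)
}
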