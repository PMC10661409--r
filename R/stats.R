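#' Per-feature group comparison (Welch t-tests)
#'
#' For each of the 18 features, computes group means and SDs, a Welch
#' (unequal-variance) two-sample t-test between the case and control
#' groups, the effect direction `sign(mean_case - mean_control)`, and
#' significance stars at 0.05 / 0.01 / 0.001. No multiple-testing
#' correction is applied: the stars are per-feature descriptives, not a
#' family-wise inference. A feature constant in both groups has an
#' undefined t statistic and is flagged and excluded from testing.
#'
#' @param tab A `feature_table` ([extract_features()]).
#' @param case,control Group labels compared (direction is
#'   case minus control).
#' @return A `group_stats` data frame with one row per feature: means, SDs,
#'   `t`, `df`, `p`, `direction`, `stars`.
#' @export
group_stats <- function(tab, case = "AD", control = "CN") {
  g <- tab$group
  if (!all(c(case, control) %in% g))
    stop("both groups must be present in the table")
  if (sum(g == case) < 2 || sum(g == control) < 2)
    stop("need at least 2 rows per group")
  out <- lapply(feature_names, function(f) {
    xc <- tab[[f]][g == case]
    x0 <- tab[[f]][g == control]
    res <- data.frame(feature = f,
                      mean_case = mean(xc), sd_case = sd(xc),
                      mean_control = mean(x0), sd_control = sd(x0),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      direction = sign(mean(xc) - mean(x0)),
                      stars = "", excluded = FALSE,
                      stringsAsFactors = FALSE)
    tt <- tryCatch(t.test(xc, x0, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      res$excluded <- TRUE
      return(res)
    }
    res$t <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p <- tt$p.value
    res$stars <- if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
      else if (res$p < 0.05) "*" else ""
    res
  })
  out <- do.call(rbind, out)
  attr(out, "case") <- case
  attr(out, "control") <- control
  class(out) <- c("group_stats", "data.frame")
  out
}

#' @export
print.group_stats <- function(x, digits = 3, ...) {
  cat(sprintf("Welch two-sample t-tests, %s vs %s (direction = sign(%s - %s))\n\n",
              attr(x, "case"), attr(x, "control"),
              attr(x, "case"), attr(x, "control")))
  df <- data.frame(feature = x$feature,
                   mean_case = signif(x$mean_case, digits),
                   mean_control = signif(x$mean_control, digits),
                   t = round(x$t, 2),
                   p = signif(x$p, 2),
                   dir = ifelse(x$excluded, "excl",
                                c("-", "0", "+")[x$direction + 2]),
                   sig = x$stars)
  print(df, row.names = FALSE)
  invisible(x)
}
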