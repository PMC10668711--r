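#' Validation metrics from confusion counts
#'
#' Computes the spot-validation metric set, in percent:
#' accuracy = (CP + CN) / total, error = (FP + FN) / total,
#' sensitivity = CP / (CP + FN), specificity = CN / (CN + FP),
#' precision = CP / (CP + FP), and the share of correct positives
#' CP / total. Undefined ratios (zero denominator) are reported as `NA`,
#' never as 0. Values are kept at full precision; rounding to one decimal
#' (half-up, as in field reports) happens only in [print()] /
#' [metrics_report()] via `round_half_up()`.
#'
#' @param counts a [confusion_counts()]
#' @return object of class `fc_metrics`: named list of percentages
#' @examples
#' m <- compute_metrics(confusion_counts(CP = 1509, FP = 10751,
#'                                       FN = 1823, CN = 1582))
#' round_half_up(m$accuracy, 1)
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "fc_counts"))
  tot <- counts$total
  if (tot <= 0) stop("total count must be positive")
  ratio <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  structure(list(
    accuracy = ratio(counts$CP + counts$CN, tot),
    error_pct = ratio(counts$FP + counts$FN, tot),
    sensitivity = ratio(counts$CP, counts$CP + counts$FN),
    specificity = ratio(counts$CN, counts$CN + counts$FP),
    precision = ratio(counts$CP, counts$CP + counts$FP),
    pct_correct_positive = ratio(counts$CP, tot),
    counts = counts
  ), class = "fc_metrics")
}

#' Round half away from zero
#'
#' Presentation rounding used in field tables (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.fc_metrics <- function(x, ...) {
  cat("Validation metrics (%):\n")
  for (nm in c("accuracy", "error_pct", "sensitivity", "specificity",
               "precision", "pct_correct_positive")) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.na(v)) "undefined" else
                  format(round_half_up(v, 1), nsmall = 1)))
  }
  invisible(x)
}

#' Tabulate metrics for several count sets
#'
#' One row per confusion-count set (for example per reference mode and
#' location policy), with all six metrics. Row order follows the input.
#'
#' @param counts_list named list of [confusion_counts()] (or
#'   [match_events()] results, whose counts are used)
#' @param digits decimal places for presentation (`NULL` for full
#'   precision)
#' @return data frame with one row per input
#' @export
metrics_report <- function(counts_list, digits = 1) {
  if (inherits(counts_list, c("fc_counts", "fc_match")))
    counts_list <- list(counts_list)
  rows <- lapply(seq_along(counts_list), function(i) {
    x <- counts_list[[i]]
    cnt <- if (inherits(x, "fc_match")) x$counts else x
    m <- compute_metrics(cnt)
    nm <- names(counts_list)[i]
    data.frame(
      set = if (!is.null(nm) && nzchar(nm)) nm else paste0("set", i),
      CP = cnt$CP, FP = cnt$FP, FN = cnt$FN, CN = cnt$CN,
      accuracy = m$accuracy, error_pct = m$error_pct,
      sensitivity = m$sensitivity, specificity = m$specificity,
      precision = m$precision, pct_correct_positive = m$pct_correct_positive,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- c("accuracy", "error_pct", "sensitivity", "specificity",
             "precision", "pct_correct_positive")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  rownames(out) <- NULL
  out
}
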