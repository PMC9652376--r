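## Correct classification rate (CCR) reporting: per-group tables,
## confusion matrices, and side-by-side system comparison.

round2 <- function(x) floor(x * 100 + 0.5) / 100  # round half-up, 2 dp

#' Correct classification rate
#'
#' 100 x (number of matches) / n, rounded half-up to two decimals as
#' printed in the report tables.
#'
#' @param predicted,actual Equal-length label vectors.
#' @return CCR percentage.
#' @export
ccr <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) == 0L) {
    stop("predicted and actual must be equal-length, non-empty", call. = FALSE)
  }
  round2(100 * sum(predicted == actual) / length(actual))
}

#' Per-group classification report
#'
#' Group-wise test counts, correct counts and CCRs, the totals row, and
#' the full confusion matrix. A group with no test samples gets an
#' undefined (NA) CCR rather than zero.
#'
#' @param predicted,actual Label vectors with values in 0..(n_groups-1).
#' @param n_groups Number of groups (default 8).
#' @param group_names Optional group names (default [age_group_labels()]
#'   for 8 groups).
#' @return Object of class `"evaluation_report"`: `per_group` data.frame
#'   (group, n, correct, ccr), `total` (n, correct, ccr), `confusion`
#'   (n_groups x n_groups, rows = actual).
#' @export
per_group_report <- function(predicted, actual, n_groups = 8L,
                             group_names = NULL) {
  if (length(predicted) != length(actual) || length(predicted) == 0L) {
    stop("predicted and actual must be equal-length, non-empty", call. = FALSE)
  }
  if (any(actual < 0 | actual >= n_groups | predicted < 0 |
            predicted >= n_groups)) {
    stop("labels out of range", call. = FALSE)
  }
  if (is.null(group_names)) {
    group_names <- if (n_groups == 8L) age_group_labels() else
      paste0("group", seq_len(n_groups) - 1L)
  }
  confusion <- matrix(0L, n_groups, n_groups,
                      dimnames = list(actual = group_names,
                                      predicted = group_names))
  for (i in seq_along(actual)) {
    confusion[actual[i] + 1L, predicted[i] + 1L] <-
      confusion[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  n_g <- rowSums(confusion)
  correct_g <- diag(confusion)
  per_group <- data.frame(
    group = group_names,
    n = as.integer(n_g),
    correct = as.integer(correct_g),
    ccr = ifelse(n_g > 0, round2(100 * correct_g / pmax(n_g, 1L)), NA_real_))
  total <- list(n = length(actual), correct = sum(correct_g),
                ccr = ccr(predicted, actual))
  structure(list(per_group = per_group, total = total, confusion = confusion),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  tab <- x$per_group
  tab$ccr <- sprintf("%.2f", tab$ccr)
  tab <- rbind(tab, data.frame(group = "Total", n = x$total$n,
                               correct = x$total$correct,
                               ccr = sprintf("%.2f", x$total$ccr)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare two classification reports
#'
#' Side-by-side per-group CCR table with deltas (system A minus system B),
#' plus the totals row.
#'
#' @param report_a,report_b `"evaluation_report"` objects over the same
#'   group set.
#' @return data.frame with columns group, n_a, n_b, ccr_a, ccr_b, delta;
#'   the last row is the totals.
#' @export
compare_systems <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "evaluation_report"),
            inherits(report_b, "evaluation_report"))
  a <- report_a$per_group; b <- report_b$per_group
  if (!identical(a$group, b$group)) {
    stop("reports cover different group sets", call. = FALSE)
  }
  out <- data.frame(group = a$group, n_a = a$n, n_b = b$n,
                    ccr_a = a$ccr, ccr_b = b$ccr,
                    delta = round2(a$ccr - b$ccr))
  rbind(out, data.frame(group = "Total", n_a = report_a$total$n,
                        n_b = report_b$total$n,
                        ccr_a = report_a$total$ccr,
                        ccr_b = report_b$total$ccr,
                        delta = round2(report_a$total$ccr -
                                         report_b$total$ccr)))
}

#' Write an evaluation report to CSV files
#'
#' @param report An `"evaluation_report"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$per_group
  tab <- rbind(tab, data.frame(group = "Total", n = report$total$n,
                               correct = report$total$correct,
                               ccr = report$total$ccr))
  utils::write.csv(tab, file.path(dir, "ccr_per_group.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion_matrix.csv"))
  invisible(dir)
}
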