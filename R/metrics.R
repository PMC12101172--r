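# Evaluation statistics: line-assignment accuracy against ground truth,
# multi-rater per-fixation agreement, ICC(3,1), and the two-group accuracy
# comparison.

#' Line-assignment accuracy against ground truth
#'
#' The fraction of fixations whose assigned line matches the line they
#' occupied before distortion. Comparison is on 0-based line indices, so no
#' algorithm is penalized for how a line's y-position is represented.
#'
#' @param result A `correction_result` (or a bare integer vector of 0-based
#'   line assignments).
#' @param ground_truth_line Integer vector of 0-based true line indices.
#' @param trial_id Optional label carried into the report.
#' @return An `accuracy_report` list: `trial_id`, `algorithm`,
#'   `n_fixations`, `n_correct`, `accuracy` (fraction in `[0, 1]`).
#' @export
line_accuracy <- function(result, ground_truth_line, trial_id = NULL) {
  if (inherits(result, "correction_result")) {
    assignment <- result$line_assignment
    algorithm <- result$algorithm
  } else {
    assignment <- as.integer(result)
    algorithm <- NA_character_
  }
  gt <- as.integer(ground_truth_line)
  if (length(assignment) != length(gt)) {
    stop("assignment and ground truth must have equal length")
  }
  n <- length(gt)
  n_correct <- sum(assignment == gt)
  structure(list(trial_id = trial_id, algorithm = algorithm,
                 n_fixations = n, n_correct = n_correct,
                 accuracy = n_correct / n),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy%s%s: %d/%d fixations on their true line (%.1f%%)\n",
              if (is.null(x$trial_id)) "" else paste0(" [", x$trial_id, "]"),
              if (is.na(x$algorithm)) "" else paste0(" (", x$algorithm, ")"),
              x$n_correct, x$n_fixations, 100 * x$accuracy))
  invisible(x)
}

#' Per-fixation agreement among raters
#'
#' For each fixation, agreement is the fraction of raters who chose its
#' modal line: if three of four raters put a fixation on the same line, the
#' agreement for that fixation is 75%. Overall agreement is the arithmetic
#' mean over fixations. Missing cells are excluded per fixation; fixations
#' rated by fewer than two raters are dropped with a warning.
#'
#' @param matrix A [rater_matrix()].
#' @return An `agreement_report` list: `per_fixation_agreement` (named),
#'   `overall_agreement`, `n_raters`.
#' @export
per_fixation_agreement <- function(matrix) {
  stopifnot(inherits(matrix, "rater_matrix"))
  rated <- rowSums(!is.na(matrix))
  if (any(rated < 2L)) {
    warning(sum(rated < 2L),
            " fixation(s) rated by fewer than 2 raters were excluded")
  }
  keep <- which(rated >= 2L)
  if (length(keep) == 0L) stop("no fixation was rated by at least 2 raters")
  agree <- vapply(keep, function(i) {
    ratings <- matrix[i, ]
    ratings <- ratings[!is.na(ratings)]
    max(table(ratings)) / length(ratings)
  }, numeric(1))
  names(agree) <- rownames(matrix)[keep]
  structure(list(per_fixation_agreement = agree,
                 overall_agreement = mean(agree),
                 n_raters = ncol(matrix)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement among %d raters over %d fixations: %.1f%% overall\n",
              x$n_raters, length(x$per_fixation_agreement),
              100 * x$overall_agreement))
  invisible(x)
}

#' Intra-class correlation ICC(3,1)
#'
#' Single-rater consistency ICC from the two-way mixed model with a fixed
#' rater set, computed from the two-way ANOVA decomposition without
#' interaction: `(MS_subjects - MS_error) / (MS_subjects + (k - 1) *
#' MS_error)`, with `F = MS_subjects / MS_error` on `n - 1` and
#' `(n - 1)(k - 1)` degrees of freedom. Rows with any missing rating are
#' dropped (listwise deletion).
#'
#' @param matrix A [rater_matrix()] (or plain numeric matrix), subjects x
#'   raters.
#' @return An `icc_report` list: `icc3`, `F`, `df1`, `df2`, `p_value`,
#'   `n_subjects`, `n_raters`.
#' @export
icc3 <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  storage.mode(m) <- "double"
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("ICC needs at least 2 complete subjects and 2 raters")
  }
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) stop("ICC is undefined when all ratings are identical")
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_rows <- ss_rows / df1
  ms_err <- max(ss_err, 0) / df2
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1L) * ms_err)
  f_stat <- if (ms_err > 0) ms_rows / ms_err else Inf
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(list(icc3 = icc, F = f_stat, df1 = df1, df2 = df2,
                 p_value = p, n_subjects = n, n_raters = k),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f  (F = %.3f, df1 = %d, df2 = %d, p = %.3g)\n",
              x$icc3, x$F, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' Compare correction accuracy between two groups
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction) plus Cohen's d from the pooled standard deviation,
#' conventionally reported for novice-vs-expert accuracy comparisons.
#'
#' @param acc_a,acc_b Numeric accuracy vectors (e.g. per-trial accuracies
#'   of each group). `U` counts pairs where `acc_a` exceeds `acc_b`;
#'   `cohens_d` is `(mean(acc_a) - mean(acc_b)) / pooled SD`.
#' @return A list with `U`, `p_value`, `cohens_d`, `n_a`, `n_b`. `cohens_d`
#'   is `NA` (with a warning) when both groups are constant.
#' @export
compare_groups <- function(acc_a, acc_b) {
  if (length(acc_a) == 0L || length(acc_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(acc_a, acc_b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  na <- length(acc_a); nb <- length(acc_b)
  pooled_var <- (sum((acc_a - mean(acc_a))^2) + sum((acc_b - mean(acc_b))^2)) /
    (na + nb - 2)
  if (pooled_var == 0) {
    warning("pooled SD is zero; Cohen's d is undefined")
    d <- NA_real_
  } else {
    d <- (mean(acc_a) - mean(acc_b)) / sqrt(pooled_var)
  }
  list(U = unname(wt$statistic), p_value = wt$p.value, cohens_d = d,
       n_a = na, n_b = nb)
}
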