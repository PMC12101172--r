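# End-to-end benchmark: generate the synthetic suite, correct every trial
# with all nine algorithms, score accuracy against ground truth, and emit a
# reproducible summary table plus a manifest.

#' Run the full correction benchmark
#'
#' Generates the 18-trial synthetic suite (four distortion kinds and two
#' regression kinds, each at three magnitudes), corrects every trial with
#' all nine algorithms, and tabulates line-assignment accuracy.
#'
#' @param layout A [text_layout()]; defaults to a 5-line demo page.
#' @param magnitudes Distortion magnitudes, see [default_magnitudes()].
#' @param seed Master seed; the whole run is a pure function of it.
#' @param params Base [generator_params()] for the suite.
#' @param config Algorithm configuration passed to [run_all_corrections()].
#' @return A `benchmark_result` list:
#'   * `accuracy`: 9 x 18 matrix of accuracies (fractions), algorithms in
#'     rows, trials in columns;
#'   * `summary`: data frame with per-algorithm mean/median/sd accuracy;
#'   * `trials`: the generated `synthetic_trial` list;
#'   * `manifest`: seeds, magnitudes and parameters of the run.
#' @export
run_benchmark <- function(layout = grid_layout(n_lines = 5),
                          magnitudes = default_magnitudes(layout),
                          seed = 1L,
                          params = generator_params(skip_enabled = TRUE),
                          config = list()) {
  trials <- generate_suite(layout, magnitudes, seed = seed, params = params)
  algos <- correction_algorithms()
  acc <- matrix(NA_real_, nrow = length(algos), ncol = length(trials),
                dimnames = list(algos, names(trials)))
  for (tn in names(trials)) {
    trial <- trials[[tn]]
    results <- run_all_corrections(trial$fixations, layout, config)
    for (a in algos) {
      res <- results[[a]]
      if (!inherits(res, "correction_failure")) {
        acc[a, tn] <- line_accuracy(res, trial$ground_truth_line)$accuracy
      }
    }
  }
  summary <- data.frame(
    algorithm = algos,
    mean_accuracy = apply(acc, 1L, mean, na.rm = TRUE),
    median_accuracy = apply(acc, 1L, stats::median, na.rm = TRUE),
    sd_accuracy = apply(acc, 1L, stats::sd, na.rm = TRUE),
    row.names = NULL)
  manifest <- list(seed = seed, magnitudes = magnitudes,
                   generator = params[setdiff(names(params), "seed")],
                   n_lines = length(layout$line_ys),
                   n_words = nrow(layout$aois),
                   algorithms = algos)
  structure(list(accuracy = acc, summary = summary,
                 trials = trials, manifest = manifest),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d algorithms x %d trials\n",
              nrow(x$accuracy), ncol(x$accuracy)))
  s <- x$summary
  s[-1L] <- lapply(s[-1L], function(v) round(100 * v, 1))
  names(s) <- c("algorithm", "mean_%", "median_%", "sd_%")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark's accuracy table and manifest to disk
#'
#' The CSV holds one row per algorithm: the 18 per-trial accuracies
#' followed by mean/median/sd, all as percentages with fixed formatting so
#' identical runs produce byte-identical files. The manifest is JSON.
#'
#' @param bench A `benchmark_result`.
#' @param csv_path Output CSV path.
#' @param manifest_path Optional JSON manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_benchmark <- function(bench, csv_path, manifest_path = NULL) {
  acc <- bench$accuracy * 100
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  header <- paste(c("algorithm", colnames(acc), "mean", "median", "sd"),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(acc)), function(i) {
    paste(c(rownames(acc)[i], fmt(acc[i, ]),
            fmt(mean(acc[i, ], na.rm = TRUE)),
            fmt(stats::median(acc[i, ], na.rm = TRUE)),
            fmt(stats::sd(acc[i, ], na.rm = TRUE))),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), csv_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(bench$manifest, manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Dot-and-whisker accuracy plot for a benchmark
#'
#' One row per algorithm: mean accuracy (point), median (vertical tick)
#' and +/- one SD (whiskers). Base graphics; safe on headless devices when
#' drawn into `png()`/`pdf()`.
#'
#' @param bench A `benchmark_result`.
#' @param ... Passed to [graphics::plot()].
#' @return The benchmark, invisibly.
#' @export
plot_benchmark <- function(bench, ...) {
  s <- bench$summary
  n <- nrow(s)
  ord <- order(s$mean_accuracy)
  graphics::plot(100 * s$mean_accuracy[ord], seq_len(n), xlim = c(0, 100),
                 yaxt = "n", xlab = "line-assignment accuracy (%)",
                 ylab = "", pch = 19, col = "darkgreen",
                 panel.first = graphics::grid(), ...)
  graphics::axis(2, at = seq_len(n), labels = s$algorithm[ord], las = 1)
  graphics::segments(100 * (s$mean_accuracy[ord] - s$sd_accuracy[ord]),
                     seq_len(n),
                     100 * (s$mean_accuracy[ord] + s$sd_accuracy[ord]),
                     seq_len(n))
  graphics::points(100 * s$median_accuracy[ord], seq_len(n), pch = "|")
  invisible(bench)
}

#' Agreement study over a set of rater matrices
#'
#' Computes ICC(3,1) per trial plus the mean ICC across trials, mirroring
#' the usual per-trial reliability table (columns ICC, F, df1, df2,
#' p-value). Matrices that cannot be scored (too few complete rows, zero
#' variance) are skipped with a warning.
#'
#' @param matrices Named list of [rater_matrix()] objects, or a character
#'   vector of CSV paths readable by [read_rater_matrix()].
#' @return A list with `table` (one data-frame row per scored trial) and
#'   `mean_icc`.
#' @export
agreement_study <- function(matrices) {
  if (is.character(matrices)) {
    paths <- matrices
    matrices <- lapply(paths, read_rater_matrix)
    names(matrices) <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(matrices) == 0L) stop("at least one rater matrix is required")
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("trial", seq_along(matrices))
  }
  rows <- list()
  for (tn in names(matrices)) {
    rep <- tryCatch(icc3(matrices[[tn]]), error = function(e) {
      warning("skipping '", tn, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep)) {
      rows[[tn]] <- data.frame(trial = tn, icc = rep$icc3, F = rep$F,
                               df1 = rep$df1, df2 = rep$df2,
                               p_value = rep$p_value)
    }
  }
  if (length(rows) == 0L) stop("no rater matrix could be scored")
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(table = tab, mean_icc = mean(tab$icc))
}
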