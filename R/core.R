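# Core domain types and I/O.
#
# Conventions used throughout the package:
#   * pixel coordinates, origin top-left, y grows downward;
#   * line indices are 0-based, both internally and in CSV files;
#   * durations are milliseconds, carried as doubles.

#' Construct a fixation sequence
#'
#' A fixation sequence is an ordered record of one trial's gaze samples,
#' each fixation a triplet (x, y, duration): pixel position plus dwell time
#' in milliseconds. It is represented as a `data.frame` with columns `x`,
#' `y`, `duration` and class `fixation_sequence`.
#'
#' @param x,y Numeric vectors of pixel coordinates (y grows downward).
#' @param duration Numeric vector of fixation durations in milliseconds;
#'   must be strictly positive.
#' @param trial_id Optional identifier stored as an attribute.
#' @return A `fixation_sequence` data frame.
#' @examples
#' fixation_sequence(x = c(100, 160), y = c(50, 50), duration = c(180, 220))
#' @export
fixation_sequence <- function(x, y, duration, trial_id = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); duration <- as.numeric(duration)
  n <- length(x)
  if (length(y) != n || length(duration) != n) {
    stop("x, y and duration must have equal length")
  }
  if (n > 0L) {
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("fixation coordinates must be finite")
    }
    if (any(!is.finite(duration)) || any(duration <= 0)) {
      stop("fixation durations must be finite and positive")
    }
  }
  out <- data.frame(x = x, y = y, duration = duration)
  class(out) <- c("fixation_sequence", "data.frame")
  attr(out, "trial_id") <- trial_id
  out
}

#' @export
print.fixation_sequence <- function(x, ...) {
  id <- attr(x, "trial_id")
  cat(sprintf("Fixation sequence%s: %d fixations\n",
              if (is.null(id)) "" else paste0(" '", id, "'"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more\n", nrow(x) - 10L))
  invisible(x)
}

as_fixseq <- function(df, trial_id = NULL) {
  fixation_sequence(df$x, df$y, df$duration, trial_id = trial_id)
}

#' Construct a text layout from word areas of interest
#'
#' A text layout describes the stimulus: one rectangular area of interest
#' (AOI) per word, in reading order, each carrying its top-left corner,
#' extent, and 0-based line index. From the AOIs the constructor derives
#' `line_ys` (the y-coordinate of each line, strictly increasing, indexed by
#' line number) and `word_centers` (per-AOI rectangle centers, used by the
#' warp corrector).
#'
#' @param aois A data frame with columns `x`, `y`, `width`, `height`,
#'   `line` (0-based) and optionally `token` (the word itself).
#' @return A `text_layout` object: a list with elements `aois`, `line_ys`
#'   and `word_centers`.
#' @details AOIs that claim the same line must share the same `y`; line
#'   indices must be `0 .. n_lines - 1` with y increasing in line index.
#' @examples
#' layout <- text_layout(data.frame(
#'   x = c(0, 70, 0, 70), y = c(50, 50, 100, 100),
#'   width = 60, height = 20, line = c(0, 0, 1, 1)))
#' layout$line_ys
#' @export
text_layout <- function(aois) {
  req <- c("x", "y", "width", "height", "line")
  miss <- setdiff(req, names(aois))
  if (length(miss) > 0L) {
    stop("AOI table is missing column(s): ", paste(miss, collapse = ", "))
  }
  aois <- as.data.frame(aois)
  for (col in req) aois[[col]] <- as.numeric(aois[[col]])
  if (nrow(aois) == 0L) stop("layout must contain at least one AOI")
  if (any(!is.finite(as.matrix(aois[req])))) stop("AOI fields must be finite")
  if (any(aois$width <= 0) || any(aois$height <= 0)) {
    stop("AOI width and height must be positive")
  }
  if (any(aois$line != floor(aois$line)) || any(aois$line < 0)) {
    stop("line indices must be non-negative integers")
  }
  aois$line <- as.integer(aois$line)

  lines <- sort(unique(aois$line))
  if (!identical(lines, seq_along(lines) - 1L)) {
    stop("line indices must be contiguous starting at 0")
  }
  line_ys <- vapply(lines, function(l) {
    ys <- unique(aois$y[aois$line == l])
    if (length(ys) != 1L) {
      stop(sprintf("AOIs on line %d have inconsistent y values (%s)",
                   l, paste(ys, collapse = ", ")))
    }
    ys
  }, numeric(1))
  if (length(line_ys) > 1L && any(diff(line_ys) <= 0)) {
    stop("line y-positions must be strictly increasing in line index")
  }

  word_centers <- data.frame(cx = aois$x + aois$width / 2,
                             cy = aois$y + aois$height / 2,
                             line = aois$line)
  structure(list(aois = aois, line_ys = line_ys,
                 word_centers = word_centers),
            class = "text_layout")
}

#' @export
print.text_layout <- function(x, ...) {
  cat(sprintf("Text layout: %d words on %d lines (line spacing %s px)\n",
              nrow(x$aois), length(x$line_ys),
              if (length(x$line_ys) > 1L)
                format(signif(mean(diff(x$line_ys)), 4)) else "NA"))
  invisible(x)
}

#' Line spacing of a layout
#'
#' Vertical distance between the first two lines, the natural scale for
#' distortion magnitudes.
#'
#' @param layout A `text_layout`.
#' @return Line spacing in pixels.
#' @export
line_spacing <- function(layout) {
  if (length(layout$line_ys) < 2L) {
    stop("line spacing is undefined for a single-line layout")
  }
  layout$line_ys[2L] - layout$line_ys[1L]
}

#' Map y-coordinates to the nearest text line
#'
#' For each y, returns the 0-based index of the closest value in `line_ys`.
#' The search is a binary search (via `findInterval`) followed by a single
#' neighbor comparison, so it runs in O(log m) per query; exact ties between
#' two lines resolve to the lower (topmost) index.
#'
#' @param y Numeric vector of y-coordinates (pixels).
#' @param line_ys Sorted (ascending) numeric vector of line y-positions.
#' @return Integer vector of 0-based line indices, same length as `y`.
#' @examples
#' nearest_line(c(50, 75, 76), line_ys = c(50, 100))
#' @export
nearest_line <- function(y, line_ys) {
  if (length(line_ys) == 0L) stop("line_ys must be non-empty")
  if (is.unsorted(line_ys, strictly = TRUE)) {
    stop("line_ys must be sorted strictly ascending")
  }
  if (any(!is.finite(y))) stop("y must be finite")
  lo <- findInterval(y, line_ys)            # binary search: largest i with line_ys[i] <= y
  lo[lo == 0L] <- 1L
  hi <- pmin(lo + 1L, length(line_ys))
  # ties (equidistant neighbors) go to the lower index
  pick_hi <- (line_ys[hi] - y) < (y - line_ys[lo])
  idx <- ifelse(pick_hi, hi, lo)
  as.integer(idx - 1L)
}

line_y_at <- function(line_ys, index0) line_ys[index0 + 1L]

# ---------------------------------------------------------------------------
# I/O

num_or_stop <- function(chr, col, rows_label) {
  suppressWarnings(v <- as.numeric(chr))
  bad <- which(is.na(v) & !is.na(chr) | is.na(chr))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                 col, bad[1L], rows_label))
  }
  v
}

#' Read a fixation sequence from CSV or JSON
#'
#' CSV files must have a header with columns `x,y,duration` (an optional
#' `ground_truth_line` column is read into the `"ground_truth_line"`
#' attribute). JSON files hold a list of `[x, y, duration]` triplets.
#'
#' @param path File path; format chosen by extension (`.json` vs anything
#'   else treated as CSV) unless `format` is given.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return A [fixation_sequence()].
#' @export
read_fixations <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    raw <- as.matrix(raw)
    if (ncol(raw) != 3L) stop("JSON fixation list must hold [x,y,duration] triplets")
    return(fixation_sequence(raw[, 1L], raw[, 2L], raw[, 3L],
                             trial_id = sub("\\.[^.]*$", "", basename(path))))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("x", "y", "duration"), names(df))
  if (length(miss) > 0L) {
    stop("fixation CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  x <- num_or_stop(df$x, "x", path)
  y <- num_or_stop(df$y, "y", path)
  dur <- num_or_stop(df$duration, "duration", path)
  bad <- which(dur <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive duration at data row %d of %s", bad[1L], path))
  }
  seq <- fixation_sequence(x, y, dur,
                           trial_id = sub("\\.[^.]*$", "", basename(path)))
  if ("ground_truth_line" %in% names(df)) {
    attr(seq, "ground_truth_line") <-
      as.integer(num_or_stop(df$ground_truth_line, "ground_truth_line", path))
  }
  seq
}

fmt_full <- function(v) sprintf("%.17g", v)

#' Write a fixation sequence to CSV or JSON
#'
#' Values are written with 17 significant digits so that write-then-read is
#' an exact round trip for doubles.
#'
#' @param seq A [fixation_sequence()].
#' @param path Output path; `.json` writes the JSON triplet form.
#' @param ground_truth_line Optional 0-based integer vector appended as a
#'   `ground_truth_line` column (CSV only).
#' @return `path`, invisibly.
#' @export
write_fixations <- function(seq, path, ground_truth_line = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    mat <- unname(as.matrix(as.data.frame(seq)[, c("x", "y", "duration")]))
    jsonlite::write_json(mat, path, digits = NA)
    return(invisible(path))
  }
  header <- c("x", "y", "duration")
  cols <- list(fmt_full(seq$x), fmt_full(seq$y), fmt_full(seq$duration))
  if (!is.null(ground_truth_line)) {
    stopifnot(length(ground_truth_line) == nrow(seq))
    header <- c(header, "ground_truth_line")
    cols <- c(cols, list(as.character(as.integer(ground_truth_line))))
  }
  lines <- c(paste(header, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a text layout from an AOI CSV
#'
#' Expects columns `x,y,width,height,line` and optionally `token`.
#'
#' @param path CSV file path.
#' @return A [text_layout()].
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("x", "y", "width", "height", "line"), names(df))
  if (length(miss) > 0L) {
    stop("AOI CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  text_layout(df)
}

#' Write a text layout's AOI table to CSV
#'
#' @param layout A [text_layout()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout$aois, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a rater matrix of line assignments
#'
#' Rows are fixations (identified by `fixation_ids`), columns are raters;
#' cells hold 0-based line indices, `NA` where a rater did not assign the
#' fixation.
#'
#' @param assignments Numeric matrix or data frame, fixations x raters.
#' @param fixation_ids Optional unique row identifiers (default `f1..fn`).
#' @param rater_ids Optional column identifiers (default `r1..rk`).
#' @return A `rater_matrix` object.
#' @export
rater_matrix <- function(assignments, fixation_ids = NULL, rater_ids = NULL) {
  m <- as.matrix(assignments)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("a rater matrix needs at least 2 raters")
  if (any(!is.na(m) & (m < 0 | m != floor(m)))) {
    stop("rater matrix cells must be non-negative line indices or NA")
  }
  if (is.null(fixation_ids)) fixation_ids <- paste0("f", seq_len(nrow(m)))
  if (anyDuplicated(fixation_ids)) stop("fixation_ids must be unique")
  if (is.null(rater_ids)) rater_ids <- paste0("r", seq_len(ncol(m)))
  dimnames(m) <- list(as.character(fixation_ids), as.character(rater_ids))
  structure(m, class = c("rater_matrix", "matrix", "array"))
}

#' Read a rater matrix from wide CSV
#'
#' First column is `fixation_id`; every remaining column is one rater's
#' 0-based line assignments (empty cells allowed).
#'
#' @param path CSV file path.
#' @return A [rater_matrix()].
#' @export
read_rater_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "fixation_id") {
    stop("rater matrix CSV must have 'fixation_id' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rater_matrix(m, fixation_ids = df$fixation_id, rater_ids = names(df)[-1L])
}

#' Write a rater matrix to wide CSV
#'
#' @param matrix A [rater_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rater_matrix <- function(matrix, path) {
  df <- data.frame(fixation_id = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# evaluate `code` with a temporarily seeded RNG, restoring caller state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
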