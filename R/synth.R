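# Synthetic reading-trial generation.
#
# A trial walks the word AOIs in reading order, landing one fixation per
# (non-skipped) word slightly left of the word center — near the optimal
# viewing position — and vertically centered on the line, with Gaussian
# jitter. Durations scale with word width. Regression variants jump back to
# earlier words (same line or a previous line) and re-read from there.
# Ground-truth line labels are recorded at generation time.

#' Parameters for the synthetic trial generators
#'
#' @param regression_probability Per-eligible-position probability of
#'   starting a regression, in `[0, 1]`. The first three positions of the
#'   walk are never regression origins.
#' @param jitter_sd_x,jitter_sd_y Standard deviation (pixels) of the
#'   Gaussian landing-site jitter on each axis. Defaults of 2 px are small
#'   relative to typical line spacing, so undistorted trials remain
#'   perfectly recoverable.
#' @param skip_enabled Whether short words may be skipped.
#' @param skip_base Skip probability of a 1-character word.
#' @param skip_decay Per-character decrement of the skip probability; the
#'   probability is clamped to `[0, skip_base]`, so long words are never
#'   skipped.
#' @param char_width Assumed character width (px) used to estimate word
#'   length when an AOI has no token.
#' @param max_regression_retries Attempts at drawing a valid regression
#'   target before falling back / giving up.
#' @param seed Optional integer; fixes generator output exactly.
#' @return A `generator_params` list.
#' @export
generator_params <- function(regression_probability = 0,
                             jitter_sd_x = 2, jitter_sd_y = 2,
                             skip_enabled = FALSE,
                             skip_base = 0.5, skip_decay = 0.08,
                             char_width = 10,
                             max_regression_retries = 10L,
                             seed = NULL) {
  stopifnot(regression_probability >= 0, regression_probability <= 1,
            jitter_sd_x >= 0, jitter_sd_y >= 0,
            skip_base >= 0, skip_base <= 1, skip_decay >= 0,
            char_width > 0, max_regression_retries >= 1)
  structure(list(regression_probability = regression_probability,
                 jitter_sd_x = jitter_sd_x, jitter_sd_y = jitter_sd_y,
                 skip_enabled = skip_enabled, skip_base = skip_base,
                 skip_decay = skip_decay, char_width = char_width,
                 max_regression_retries = as.integer(max_regression_retries),
                 seed = seed),
            class = "generator_params")
}

#' Fixation landing site and duration for one word
#'
#' Places the fixation at one third of the word width from the left edge
#' (near the optimal viewing position) and at the vertical center of the
#' line, plus Gaussian jitter, and assigns a duration that grows linearly
#' with word width: `100 + (width / 15) * 40` ms.
#'
#' @param aoi A single-row AOI data frame (`x,y,width,height,line`).
#' @param params A [generator_params()]; jitter draws use the current RNG
#'   state.
#' @return A list with elements `x`, `y`, `duration`, `line`.
#' @examples
#' aoi <- data.frame(x = 0, y = 40, width = 60, height = 20, line = 0)
#' p <- generator_params(jitter_sd_x = 0, jitter_sd_y = 0)
#' base_fixation(aoi, p)   # x = 20, y = 50, duration = 260
#' @export
base_fixation <- function(aoi, params = generator_params()) {
  jx <- if (params$jitter_sd_x > 0) stats::rnorm(1, 0, params$jitter_sd_x) else 0
  jy <- if (params$jitter_sd_y > 0) stats::rnorm(1, 0, params$jitter_sd_y) else 0
  list(x = aoi$x + aoi$width / 3 + jx,
       y = aoi$y + aoi$height / 2 + jy,
       duration = 100 + (aoi$width / 15) * 40,
       line = as.integer(aoi$line))
}

#' Select regression origin positions along a walk
#'
#' Each walk position after the third is independently selected with
#' probability `regression_probability`; if the draw comes up empty and the
#' probability is positive, one eligible position is added uniformly at
#' random so that every regression trial contains at least one regression.
#'
#' @param n_aois Number of positions in the walk.
#' @param regression_probability Probability in `[0, 1]`.
#' @return Sorted integer vector of 1-based positions (all `> 3`).
#' @export
select_regression_indexes <- function(n_aois, regression_probability) {
  stopifnot(regression_probability >= 0, regression_probability <= 1)
  eligible <- if (n_aois >= 4L) seq(4L, n_aois) else integer(0)
  if (regression_probability <= 0 || length(eligible) == 0L) return(integer(0))
  hits <- eligible[stats::runif(length(eligible)) < regression_probability]
  if (length(hits) == 0L) {
    hits <- eligible[sample.int(length(eligible), 1L)]
  }
  sort(as.integer(hits))
}

skip_probability <- function(n_chars, skip_base, skip_decay) {
  pmin(pmax(skip_base - skip_decay * (n_chars - 1), 0), skip_base)
}

#' Word-skipping filter over an AOI walk
#'
#' Short words are skipped with a probability that decays linearly with
#' word length: `clamp(skip_base - skip_decay * (n_chars - 1), 0,
#' skip_base)`. Word length comes from the `token` column when present,
#' otherwise it is estimated as `width / char_width`. The first word of
#' each line is never skipped, so every line keeps at least one fixation.
#'
#' @param layout A [text_layout()].
#' @param params A [generator_params()]; draws use the current RNG state.
#' @return Integer vector of retained AOI row positions, in reading order.
#' @export
apply_skipping <- function(layout, params = generator_params()) {
  aois <- layout$aois
  n <- nrow(aois)
  if (!params$skip_enabled || params$skip_base <= 0) return(seq_len(n))
  n_chars <- if (!is.null(aois$token)) {
    nchar(as.character(aois$token))
  } else {
    pmax(1, round(aois$width / params$char_width))
  }
  p_skip <- skip_probability(n_chars, params$skip_base, params$skip_decay)
  first_of_line <- !duplicated(aois$line)
  skipped <- stats::runif(n) < p_skip & !first_of_line
  which(!skipped)
}

# core walk shared by both regression generators. `same_line` selects the
# regression-target rule. Returns NULL ground truth lists if walk fails.
walk_trial <- function(aw, params, reg_set, same_line) {
  n <- nrow(aw)
  xs <- numeric(0); ys <- numeric(0); durs <- numeric(0); gt <- integer(0)
  pending <- reg_set
  executed <- 0L
  i <- 1L
  while (i <= n) {
    f <- base_fixation(aw[i, ], params)
    xs <- c(xs, f$x); ys <- c(ys, f$y); durs <- c(durs, f$duration)
    gt <- c(gt, f$line)
    if (i %in% pending) {
      pending <- setdiff(pending, i)
      valid <- which(if (same_line) aw$line[seq_len(i - 1L)] == aw$line[i]
                     else aw$line[seq_len(i - 1L)] != aw$line[i])
      target <- NA_integer_
      for (try in seq_len(params$max_regression_retries)) {
        j <- sample.int(i - 1L, 1L)
        ok <- if (same_line) aw$line[j] == aw$line[i] else aw$line[j] != aw$line[i]
        if (ok) { target <- j; break }
      }
      # bounded random retries exhausted: take any valid target if one
      # exists, otherwise skip the regression at this position
      if (is.na(target) && length(valid) > 0L) {
        target <- valid[sample.int(length(valid), 1L)]
      }
      if (!is.na(target)) {
        executed <- executed + 1L
        i <- target
        next
      }
    }
    i <- i + 1L
  }
  list(x = xs, y = ys, duration = durs, gt = gt, executed = executed)
}

generate_regression_trial <- function(layout, params, same_line, trial_id) {
  with_seed(params$seed, {
    keep <- apply_skipping(layout, params)
    aw <- layout$aois[keep, , drop = FALSE]
    n <- nrow(aw)
    reg_set <- select_regression_indexes(n, params$regression_probability)
    res <- walk_trial(aw, params, reg_set, same_line)
    if (res$executed == 0L && params$regression_probability > 0) {
      # guarantee at least one executed regression when a target exists:
      # force a single regression at a random position that has one
      valid_origin <- Filter(function(i) {
        prior <- aw$line[seq_len(i - 1L)]
        any(if (same_line) prior == aw$line[i] else prior != aw$line[i])
      }, if (n >= 4L) seq(4L, n) else integer(0))
      if (length(valid_origin) > 0L) {
        forced <- valid_origin[[sample.int(length(valid_origin), 1L)]]
        res <- walk_trial(aw, params, forced, same_line)
      }
    }
    seq <- fixation_sequence(res$x, res$y, res$duration, trial_id = trial_id)
    structure(list(fixations = seq,
                   ground_truth_line = res$gt,
                   layout = layout, params = params,
                   distortions = list()),
              class = "synthetic_trial")
  })
}

#' Generate a trial with between-line regressions
#'
#' Walks the layout in reading order; at each selected regression position
#' the gaze jumps back to a random earlier word **on a different line** and
#' re-reads forward from there. With a positive regression probability at
#' least one between-line regression is guaranteed whenever a valid target
#' exists.
#'
#' @param layout A [text_layout()] with at least two lines when
#'   `regression_probability > 0`.
#' @param params A [generator_params()].
#' @param trial_id Optional trial identifier.
#' @return A `synthetic_trial`: list with `fixations`, `ground_truth_line`
#'   (0-based), `layout`, `params`, `distortions`.
#' @export
generate_between_line <- function(layout, params = generator_params(),
                                  trial_id = "between_line") {
  if (params$regression_probability > 0 && length(layout$line_ys) < 2L) {
    stop("between-line regressions need at least two lines")
  }
  generate_regression_trial(layout, params, same_line = FALSE, trial_id)
}

#' Generate a trial with within-line regressions
#'
#' Identical to [generate_between_line()] except that regression targets
#' must lie on the **same line** as the origin; positions where no such
#' target exists simply continue forward.
#'
#' @inheritParams generate_between_line
#' @return A `synthetic_trial`.
#' @export
generate_within_line <- function(layout, params = generator_params(),
                                 trial_id = "within_line") {
  generate_regression_trial(layout, params, same_line = TRUE, trial_id)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial '%s': %d fixations over %d lines; %d distortion(s)\n",
              attr(x$fixations, "trial_id") %||% "?", nrow(x$fixations),
              length(x$layout$line_ys), length(x$distortions)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default distortion magnitudes for a layout
#'
#' Low/medium/high magnitudes expressed relative to the layout's line
#' spacing `L`: noise SD `{0.1, 0.25, 0.4} L`; slope and shift scaled so
#' the maximum displacement (at the right edge / last line) is
#' `{0.25, 0.5, 0.75} L`; offset `{0.3, 0.6, 0.9} L` vertically; regression
#' probabilities `{0.1, 0.2, 0.3}`.
#'
#' @param layout A [text_layout()] with at least two lines.
#' @return Named list of 3-vectors: `noise`, `slope`, `shift`, `offset`,
#'   `regression`.
#' @export
default_magnitudes <- function(layout) {
  L <- line_spacing(layout)
  aois <- layout$aois
  x_range <- max(aois$x + aois$width) - min(aois$x)
  n_lines <- length(layout$line_ys)
  list(
    noise  = c(0.1, 0.25, 0.4) * L,
    # slope_factor is px of drift per 100 px of x
    slope  = c(0.25, 0.5, 0.75) * L * 100 / x_range,
    # shift factor is px of drift per line of distance from line 1
    shift  = c(0.25, 0.5, 0.75) * L / max(n_lines - 1, 1),
    offset = c(0.3, 0.6, 0.9) * L,
    regression = c(0.1, 0.2, 0.3)
  )
}

#' Generate the full synthetic trial suite
#'
#' Emits the 6-condition x 3-level design: noise, slope, shift and offset
#' distortions at low/medium/high magnitude applied to regression-free base
#' trials, plus within-line and between-line regression trials at three
#' regression probabilities (18 trials in total, each with ground truth).
#' Distortion and regression conditions are disjoint: regression trials
#' carry no distortion.
#'
#' @param layout A [text_layout()] with at least two lines.
#' @param magnitudes Named list as returned by [default_magnitudes()].
#' @param seed Master seed; every trial's sub-seed derives from it.
#' @param params Base [generator_params()] (jitter, skipping); the
#'   regression probability and seed fields are overridden per trial.
#' @return Named list of `synthetic_trial` objects, e.g. `noise_low`,
#'   `between_high`; each distortion trial records its spec in
#'   `$distortions`.
#' @export
generate_suite <- function(layout, magnitudes = default_magnitudes(layout),
                           seed = 1L, params = generator_params()) {
  stopifnot(all(c("noise", "slope", "shift", "offset", "regression")
                %in% names(magnitudes)))
  levels <- c("low", "medium", "high")
  trials <- list()
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 18L))
  k <- 0L
  for (kind in c("noise", "slope", "shift", "offset")) {
    for (li in 1:3) {
      k <- k + 1L
      id <- paste0(kind, "_", levels[li])
      p <- params; p$regression_probability <- 0; p$seed <- sub_seeds[k]
      trial <- generate_between_line(layout, p, trial_id = id)
      mag <- magnitudes[[kind]][li]
      spec <- switch(kind,
        noise  = distortion_spec("noise", ynoise = mag, seed = sub_seeds[k] + 1L),
        slope  = distortion_spec("slope", slope_factor = mag),
        shift  = distortion_spec("shift", y_shift_factor = mag),
        offset = distortion_spec("offset", x_offset = 0, y_offset = mag))
      trial$fixations <- apply_distortion(trial$fixations, spec, layout)
      trial$distortions <- list(spec)
      trials[[id]] <- trial
    }
  }
  for (kind in c("within", "between")) {
    for (li in 1:3) {
      k <- k + 1L
      id <- paste0(kind, "_", levels[li])
      p <- params
      p$regression_probability <- magnitudes$regression[li]
      p$seed <- sub_seeds[k]
      trials[[id]] <- if (kind == "within") {
        generate_within_line(layout, p, trial_id = id)
      } else {
        generate_between_line(layout, p, trial_id = id)
      }
    }
  }
  trials
}

#' A simple rectangular demo layout
#'
#' Uniform grid of word AOIs: `n_lines` lines of `words_per_line` words,
#' constant word width and line spacing. Convenient for simulations and
#' examples.
#'
#' @param n_lines Number of text lines (>= 1).
#' @param words_per_line Words per line.
#' @param word_width,word_gap Word box width and inter-word gap, px.
#' @param line_height AOI box height, px.
#' @param spacing Vertical distance between consecutive lines, px.
#' @param x0,y0 Top-left corner of the first word, px.
#' @return A [text_layout()].
#' @export
grid_layout <- function(n_lines = 3, words_per_line = 5,
                        word_width = 60, word_gap = 10,
                        line_height = 20, spacing = 50,
                        x0 = 0, y0 = 50) {
  stopifnot(n_lines >= 1, words_per_line >= 1)
  aois <- expand.grid(word = seq_len(words_per_line) - 1L,
                      line = seq_len(n_lines) - 1L)
  text_layout(data.frame(
    x = x0 + aois$word * (word_width + word_gap),
    y = y0 + aois$line * spacing,
    width = word_width, height = line_height,
    line = aois$line))
}
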