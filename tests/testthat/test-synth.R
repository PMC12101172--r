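test_that("base fixation lands near the optimal viewing position", {
  aoi <- data.frame(x = 0, y = 40, width = 60, height = 20, line = 0)
  p0 <- generator_params(jitter_sd_x = 0, jitter_sd_y = 0)
  f <- base_fixation(aoi, p0)
  expect_equal(f$x, 20)          # one third into the word
  expect_equal(f$y, 50)          # vertical line center
  expect_equal(f$duration, 260)  # 100 + (60/15)*40
  expect_identical(f$line, 0L)

  # duration grows strictly with word width
  widths <- seq(15, 150, by = 15)
  durs <- vapply(widths, function(w) {
    base_fixation(data.frame(x = 0, y = 0, width = w, height = 20, line = 0),
                  p0)$duration
  }, numeric(1))
  expect_true(all(diff(durs) > 0))
})

test_that("regression origin selection follows the Bernoulli-plus-floor rule", {
  set.seed(1)
  expect_identical(select_regression_indexes(10, 0), integer(0))
  set.seed(1)
  expect_identical(select_regression_indexes(6, 1), c(4L, 5L, 6L))
  set.seed(1)
  expect_identical(select_regression_indexes(3, 0.5), integer(0))

  # per-position inclusion frequency ~ p, and the floor rule forbids empties
  p <- 0.2; n <- 50; reps <- 5000
  counts <- integer(n)
  set.seed(99)
  for (r in seq_len(reps)) {
    idx <- select_regression_indexes(n, p)
    expect_gt(length(idx), 0)
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts[4:n] / reps
  se <- sqrt(p * (1 - p) / reps)
  # the floor rule adds a tiny upward bias (< (1-p)^47 per index), well
  # inside 3 standard errors
  expect_true(all(abs(freq - p) < 3 * se + 1e-3))
  expect_identical(counts[1:3], c(0L, 0L, 0L))
})

test_that("word skipping is clamped, length-dependent and line-safe", {
  lay <- grid_layout(n_lines = 2, words_per_line = 6)
  p_off <- generator_params(skip_enabled = TRUE, skip_base = 0)
  expect_identical(apply_skipping(lay, p_off), seq_len(12L))

  # clamped linear decay at the defaults
  sp <- driftlab:::skip_probability
  expect_equal(sp(2, 0.5, 0.08), 0.42)
  expect_equal(sp(10, 0.5, 0.08), 0)
  expect_equal(sp(1, 0.5, 0.08), 0.5)

  # short words are skipped more often than long ones
  short <- grid_layout(n_lines = 1, words_per_line = 30, word_width = 20)
  long <- grid_layout(n_lines = 1, words_per_line = 30, word_width = 80)
  p_on <- generator_params(skip_enabled = TRUE)
  set.seed(5)
  rate <- function(lay) {
    mean(replicate(400, 1 - length(apply_skipping(lay, p_on)) / 30))
  }
  expect_gt(rate(short), rate(long))

  # the first word of every line survives
  tiny <- grid_layout(n_lines = 3, words_per_line = 4, word_width = 10)
  set.seed(6)
  for (r in 1:50) {
    kept <- apply_skipping(tiny, generator_params(skip_enabled = TRUE,
                                                  skip_base = 1,
                                                  skip_decay = 0))
    expect_true(all(c(1L, 5L, 9L) %in% kept))
  }
})

test_that("regression-free generation walks the layout once in order", {
  lay <- grid_layout(n_lines = 2, words_per_line = 3)
  p <- generator_params(jitter_sd_x = 0, jitter_sd_y = 0, seed = 3)
  tr <- generate_between_line(lay, p)
  expect_equal(nrow(tr$fixations), 6L)
  expect_identical(tr$ground_truth_line, c(0L, 0L, 0L, 1L, 1L, 1L))
  # zero-jitter fixations sit exactly on their line's vertical center
  expect_equal(tr$fixations$y,
               lay$line_ys[tr$ground_truth_line + 1L] + 10)
  # and nearest_line recovers the ground truth exactly
  expect_identical(nearest_line(tr$fixations$y, lay$line_ys),
                   tr$ground_truth_line)
})

test_that("between-line trials contain a cross-line backward jump", {
  lay <- grid_layout(n_lines = 2, words_per_line = 5)
  p <- generator_params(regression_probability = 0.3, seed = 11)
  tr <- generate_between_line(lay, p)
  expect_gt(nrow(tr$fixations), 10L)   # re-read segment was emitted
  expect_true(any(diff(tr$ground_truth_line) < 0))

  # every seed yields at least one executed between-line regression
  for (s in 1:20) {
    tr <- generate_between_line(lay, generator_params(
      regression_probability = 0.15, seed = s))
    expect_true(any(diff(tr$ground_truth_line) < 0),
                info = paste("seed", s))
  }
  expect_error(
    generate_between_line(grid_layout(n_lines = 1),
                          generator_params(regression_probability = 0.5)),
    "two lines")
})

test_that("within-line regressions stay on their line", {
  lay1 <- grid_layout(n_lines = 1, words_per_line = 5)
  tr <- generate_within_line(lay1, generator_params(
    regression_probability = 1, seed = 2))
  dx <- diff(tr$fixations$x)
  expect_true(any(dx < 0))
  expect_true(all(tr$ground_truth_line == 0L))

  # multi-line: every backward jump keeps the line label
  lay <- grid_layout(n_lines = 3, words_per_line = 5)
  for (s in 1:20) {
    tr <- generate_within_line(lay, generator_params(
      regression_probability = 0.3, seed = s, jitter_sd_x = 0))
    jumps <- which(diff(tr$fixations$x) < 0 &
                   diff(tr$ground_truth_line) == 0)
    backs <- which(diff(tr$ground_truth_line) < 0)
    expect_length(backs, 0)   # never jumps to a previous line
  }

  # with probability zero the two generators coincide seed-for-seed
  p0 <- generator_params(regression_probability = 0, seed = 42)
  expect_identical(generate_within_line(lay, p0, trial_id = "t")$fixations,
                   generate_between_line(lay, p0, trial_id = "t")$fixations)
})

test_that("the suite has 18 deterministic, disjoint condition trials", {
  lay <- grid_layout(n_lines = 4, words_per_line = 5)
  suite <- generate_suite(lay, seed = 123)
  expect_length(suite, 18L)
  expect_setequal(
    names(suite),
    paste0(rep(c("noise", "slope", "shift", "offset", "within", "between"),
               each = 3),
           "_", c("low", "medium", "high")))

  # regression trials carry no distortion; distortion trials carry one
  for (tn in names(suite)) {
    n_dist <- length(suite[[tn]]$distortions)
    if (grepl("^(within|between)", tn)) expect_identical(n_dist, 0L)
    else expect_identical(n_dist, 1L)
  }

  # byte-identical regeneration under the same master seed
  suite2 <- generate_suite(lay, seed = 123)
  expect_identical(suite, suite2)
  suite3 <- generate_suite(lay, seed = 124)
  expect_false(identical(suite, suite3))
})

test_that("fixation count matches the walk unless regressions re-read", {
  lay <- grid_layout(n_lines = 3, words_per_line = 4)
  p0 <- generator_params(seed = 9)
  tr0 <- generate_between_line(lay, p0)
  expect_equal(nrow(tr0$fixations), nrow(lay$aois))
  p1 <- generator_params(regression_probability = 0.2, seed = 9)
  tr1 <- generate_between_line(lay, p1)
  expect_gt(nrow(tr1$fixations), nrow(lay$aois))
  expect_equal(length(tr1$ground_truth_line), nrow(tr1$fixations))
})
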