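expect_contract <- function(res, seq, line_ys) {
  expect_s3_class(res, "correction_result")
  expect_equal(nrow(res$corrected), nrow(seq))
  expect_identical(res$corrected$x, seq$x)
  expect_identical(res$corrected$duration, seq$duration)
  expect_true(all(res$corrected$y %in% line_ys))
  expect_identical(res$corrected$y, line_ys[res$line_assignment + 1L])
}

test_that("attach snaps to the nearest line and matches the naive scan", {
  line_ys <- c(50, 100)
  s <- fixation_sequence(c(0, 0), c(50, 100), c(1, 1))
  expect_equal(correct_attach(s, line_ys)$corrected$y, c(50, 100))

  set.seed(1)
  for (r in 1:200) {
    line_ys <- sort(sample(20:400, sample(2:10, 1)))
    s <- random_seq(sample(2:60, 1))
    res <- correct_attach(s, line_ys)
    expect_contract(res, s, line_ys)
    expect_identical(res$line_assignment, naive_attach(s, line_ys))
  }
})

test_that("chain groups nearby fixations and matches the naive scan", {
  line_ys <- c(10, 50)
  s <- fixation_sequence(c(0, 10), c(48, 52), c(1, 1))
  expect_equal(correct_chain(s, line_ys)$corrected$y, c(50, 50))
  # a large vertical gap breaks the chain
  s2 <- fixation_sequence(c(0, 10), c(10, 52), c(1, 1))
  expect_equal(correct_chain(s2, line_ys)$corrected$y, c(10, 50))

  set.seed(2)
  for (r in 1:200) {
    line_ys <- sort(sample(20:400, sample(2:8, 1)))
    s <- random_seq(sample(2:60, 1), y_range = c(0, 420))
    pars <- chain_params(x_thresh = sample(c(50, 192, 400), 1),
                         y_thresh = sample(c(20, 32, 60), 1))
    res <- correct_chain(s, line_ys, pars)
    expect_contract(res, s, line_ys)
    expect_identical(res$line_assignment,
                     naive_chain(s, line_ys, pars$x_thresh, pars$y_thresh))
  }
})

test_that("cluster separates clean vertical groups deterministically", {
  line_ys <- c(10, 50)
  s <- fixation_sequence(c(0, 10, 20, 30), c(10, 11, 50, 51), rep(1, 4))
  res <- correct_cluster(s, line_ys, seed = 1)
  expect_equal(res$corrected$y, c(10, 10, 50, 50))
  expect_identical(correct_cluster(s, line_ys, seed = 1)$line_assignment,
                   res$line_assignment)
  expect_error(correct_cluster(fixation_sequence(0, 10, 1), line_ys),
               "cluster needs")

  tr <- linear_trial(n_lines = 3)
  res <- correct_cluster(tr$fixations, tr$layout$line_ys, seed = 5)
  expect_equal(line_accuracy(res, tr$ground_truth_line)$accuracy, 1)
})

test_that("merge reduces runs to lines and recovers clean trials", {
  tr <- linear_trial(n_lines = 3)
  res <- correct_merge(tr$fixations, tr$layout$line_ys)
  expect_contract(res, tr$fixations, tr$layout$line_ys)
  expect_equal(line_accuracy(res, tr$ground_truth_line)$accuracy, 1)

  # single-line reading against a multi-line layout ends up on line 0
  line_ys <- c(50, 100, 150)
  s <- fixation_sequence(seq(0, 300, by = 60), rep(51, 6), rep(1, 6))
  expect_true(all(correct_merge(s, line_ys)$line_assignment == 0L))
})

test_that("regress recovers offsets and slopes within its bounds", {
  line_ys <- c(50, 100, 150)
  gt <- rep(0:2, each = 5)
  x <- rep(seq(0, 280, by = 70), 3)
  s0 <- fixation_sequence(x, line_ys[gt + 1], rep(100, 15))
  for (off in c(-20, 0, 15)) {
    res <- correct_regress(error_offset(s0, 0, off), line_ys)
    expect_equal(line_accuracy(res, gt)$accuracy, 1, info = paste("off", off))
  }
  # slope distortion within the bounds is undone
  d <- error_slope(s0, 2)    # 2 px per 100 px of x, max 5.6 px
  expect_equal(line_accuracy(correct_regress(d, line_ys), gt)$accuracy, 1)
  expect_contract(correct_regress(d, line_ys), d, line_ys)
})

test_that("segment cuts at the largest return sweeps, lines non-decreasing", {
  line_ys <- c(50, 100)
  # two-line linear read with one return sweep
  s <- fixation_sequence(c(0, 60, 120, 5, 65, 125), rep(0, 6), rep(1, 6))
  res <- correct_segment(s, line_ys)
  expect_identical(res$line_assignment, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(diff(res$line_assignment) >= 0))

  # single line: everything on line 0
  res1 <- correct_segment(s, 50)
  expect_true(all(res1$line_assignment == 0L))
  expect_error(correct_segment(fixation_sequence(0, 0, 1), line_ys),
               "at least")

  tr <- linear_trial(n_lines = 4)
  expect_equal(line_accuracy(correct_segment(tr$fixations,
                                             tr$layout$line_ys),
                             tr$ground_truth_line)$accuracy, 1)
})

test_that("split finds sweep saccades by 2-means and snaps segments", {
  line_ys <- c(50, 100)
  s <- fixation_sequence(c(0, 20, 40, -360, -340, -320) + 400,
                         c(50, 50, 50, 100, 100, 100), rep(1, 6))
  res <- correct_split(s, line_ys, seed = 1)
  expect_identical(res$line_assignment, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(correct_split(s, line_ys, seed = 1)$line_assignment,
                   res$line_assignment)
  expect_error(correct_split(fixation_sequence(c(0, 10, 20), c(1, 2, 3),
                                               rep(1, 3)), line_ys),
               "identical")

  tr <- linear_trial(n_lines = 3)
  expect_equal(line_accuracy(correct_split(tr$fixations, tr$layout$line_ys),
                             tr$ground_truth_line)$accuracy, 1)
})

test_that("stretch finds a zero-cost transform when one exists", {
  line_ys <- c(50, 100, 150)
  gt <- rep(0:2, each = 4)
  s0 <- fixation_sequence(rep(seq(0, 210, by = 70), 3), line_ys[gt + 1],
                          rep(100, 12))
  res0 <- correct_stretch(s0, line_ys)
  expect_equal(res0$params$fit$cost, 0)
  expect_equal(res0$corrected$y, s0$y)

  for (off in c(-20, 12)) {
    res <- correct_stretch(error_offset(s0, 0, off), line_ys)
    expect_equal(line_accuracy(res, gt)$accuracy, 1)
    expect_equal(res$params$fit$cost, 0, tolerance = 1e-6)
  }
  # the optimizer never does worse than the identity transform
  set.seed(3)
  s <- random_seq(30, y_range = c(40, 160))
  res <- correct_stretch(s, line_ys)
  id_cost <- sum(abs(s$y - line_ys[nearest_line(s$y, line_ys) + 1L]))
  expect_lte(res$params$fit$cost, id_cost + 1e-9)
})

test_that("warp aligns by DTW and matches brute-force path enumeration", {
  lay1 <- text_layout(data.frame(x = 0, y = 40, width = 60, height = 20,
                                 line = 0))
  s1 <- fixation_sequence(500, 500, 100)
  expect_equal(correct_warp(s1, lay1)$corrected$y, 40)

  set.seed(4)
  for (r in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- cbind(runif(n, 0, 300), runif(n, 0, 200))
    b <- cbind(runif(m, 0, 300), runif(m, 0, 200))
    got <- driftlab:::dtw_align(a, b)
    expect_equal(got$cost, brute_dtw_cost(a, b), tolerance = 1e-10)
    # the path itself realizes the reported cost and is monotone
    d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
    expect_equal(sum(d[got$path]), got$cost, tolerance = 1e-10)
    expect_true(all(diff(got$path[, 1]) >= 0))
    expect_true(all(diff(got$path[, 2]) >= 0))
  }

  tr <- linear_trial(n_lines = 4)
  expect_equal(line_accuracy(correct_warp(tr$fixations, tr$layout),
                             tr$ground_truth_line)$accuracy, 1)
})

test_that("attach, chain, cluster and stretch are idempotent", {
  tr <- linear_trial(n_lines = 3)
  d <- error_noise(tr$fixations, 8, seed = 5)
  line_ys <- tr$layout$line_ys
  once <- correct_attach(d, line_ys)
  expect_identical(correct_attach(once$corrected, line_ys)$corrected$y,
                   once$corrected$y)
  once <- correct_chain(d, line_ys)
  expect_identical(correct_chain(once$corrected, line_ys)$corrected$y,
                   once$corrected$y)
  once <- correct_cluster(d, line_ys, seed = 2)
  expect_identical(correct_cluster(once$corrected, line_ys,
                                   seed = 2)$corrected$y,
                   once$corrected$y)
  once <- correct_stretch(d, line_ys)
  expect_identical(correct_stretch(once$corrected, line_ys)$corrected$y,
                   once$corrected$y)
})

test_that("attach accuracy decays with offset magnitude", {
  tr <- linear_trial(n_lines = 4)
  L <- line_spacing(tr$layout)
  accs <- vapply(seq(0, 1.2, by = 0.2) * L, function(off) {
    d <- error_offset(tr$fixations, 0, off)
    line_accuracy(correct_attach(d, tr$layout$line_ys),
                  tr$ground_truth_line)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
})

test_that("run_all_corrections returns nine contract-satisfying results", {
  tr <- linear_trial(n_lines = 3)
  d <- error_noise(tr$fixations, 10, seed = 6)
  res <- run_all_corrections(d, tr$layout, config = list(seed = 1))
  expect_named(res, correction_algorithms())
  expect_length(res, 9L)
  for (a in names(res)) {
    expect_s3_class(res[[a]], "correction_result")
    expect_contract(res[[a]], d, tr$layout$line_ys)
  }
  res2 <- run_all_corrections(d, tr$layout, config = list(seed = 1))
  expect_identical(lapply(res, function(r) r$line_assignment),
                   lapply(res2, function(r) r$line_assignment))

  # individual failures are recorded, other algorithms proceed
  tiny <- fixation_sequence(c(0, 10), c(50, 51), c(1, 1))
  res3 <- run_all_corrections(tiny, tr$layout)
  expect_s3_class(res3$cluster, "correction_failure")  # n < m lines
  expect_s3_class(res3$attach, "correction_result")
})
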