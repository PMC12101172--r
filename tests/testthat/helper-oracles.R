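# Fixture builders and independent oracles used across the test files.

# a clean linear reading trial: zero jitter, no skipping, no regressions
linear_trial <- function(n_lines = 3, words_per_line = 5, seed = 1, ...) {
  layout <- grid_layout(n_lines = n_lines, words_per_line = words_per_line, ...)
  params <- generator_params(jitter_sd_x = 0, jitter_sd_y = 0,
                             regression_probability = 0, seed = seed)
  trial <- generate_between_line(layout, params, trial_id = "linear")
  trial
}

random_seq <- function(n, x_range = c(0, 800), y_range = c(0, 400)) {
  fixation_sequence(stats::runif(n, x_range[1], x_range[2]),
                    stats::runif(n, y_range[1], y_range[2]),
                    stats::runif(n, 50, 500))
}

# --- oracles ---------------------------------------------------------------

# exhaustive linear-scan nearest line, ties to the lower index
scan_nearest_line <- function(y, line_ys) {
  vapply(y, function(yi) which.min(abs(line_ys - yi)) - 1L, integer(1))
}

# naive O(n*m) attach
naive_attach <- function(seq, line_ys) {
  scan_nearest_line(seq$y, line_ys)
}

# naive chain: explicit loop building chains, linear-scan line lookup
naive_chain <- function(seq, line_ys, x_thresh = 192, y_thresh = 32) {
  n <- nrow(seq)
  chain_id <- integer(n)
  cur <- 1L
  chain_id[1L] <- cur
  if (n > 1L) {
    for (i in 2:n) {
      if (abs(seq$x[i] - seq$x[i - 1L]) > x_thresh ||
          abs(seq$y[i] - seq$y[i - 1L]) > y_thresh) cur <- cur + 1L
      chain_id[i] <- cur
    }
  }
  assignment <- integer(n)
  for (c in unique(chain_id)) {
    idx <- which(chain_id == c)
    assignment[idx] <- which.min(abs(line_ys - mean(seq$y[idx]))) - 1L
  }
  assignment
}

# brute-force DTW: enumerate every monotone path through the cost matrix
brute_dtw_cost <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- outer(seq_len(n), seq_len(m), function(i, j) {
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
  })
  best <- Inf
  recurse <- function(i, j, cost) {
    cost <- cost + d[i, j]
    if (cost >= best) return(invisible())
    if (i == n && j == m) { best <<- cost; return(invisible()) }
    if (i < n && j < m) recurse(i + 1, j + 1, cost)
    if (i < n) recurse(i + 1, j, cost)
    if (j < m) recurse(i, j + 1, cost)
  }
  recurse(1L, 1L, 0)
  best
}

# ICC(3,1) from an aov() two-way decomposition (independent of the
# closed-form sums used by the implementation)
aov_icc3 <- function(m) {
  df <- data.frame(rating = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(rating ~ subject + rater, data = df))[[1]]
  ms_subj <- tab["subject", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}
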