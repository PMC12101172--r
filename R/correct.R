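# The nine automated drift-correction algorithms. Each maps a fixation
# sequence plus text layout onto a correction_result: y-values snapped to
# line positions, a 0-based line assignment per fixation, and parameter
# provenance. None of them touches x or duration.

correction_result <- function(seq, assignment, line_ys, algorithm, params = list()) {
  out <- seq
  out$y <- line_y_at(line_ys, assignment)
  structure(list(corrected = out,
                 line_assignment = as.integer(assignment),
                 algorithm = algorithm,
                 params = params),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("Correction '%s': %d fixations over %d assigned line(s)\n",
              x$algorithm, length(x$line_assignment),
              length(unique(x$line_assignment))))
  invisible(x)
}

check_correct_input <- function(seq, line_ys) {
  if (nrow(seq) == 0L) stop("fixation sequence is empty")
  if (length(line_ys) == 0L) stop("line_ys must be non-empty")
}

#' Attach: snap each fixation to its closest line
#'
#' The simplest positional corrector: each fixation's y becomes the y of
#' the nearest text line, located by binary search in O(log m) per
#' fixation.
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions.
#' @return A `correction_result`.
#' @export
correct_attach <- function(seq, line_ys) {
  check_correct_input(seq, line_ys)
  correction_result(seq, nearest_line(seq$y, line_ys), line_ys, "attach")
}

#' Parameters for the chain corrector
#'
#' @param x_thresh,y_thresh Consecutive fixations further apart than either
#'   threshold (pixels) start a new chain.
#' @return A `chain_params` list.
#' @export
chain_params <- function(x_thresh = 192, y_thresh = 32) {
  stopifnot(x_thresh > 0, y_thresh > 0)
  list(x_thresh = x_thresh, y_thresh = y_thresh)
}

#' Chain: snap runs of nearby fixations to a common line
#'
#' Consecutive fixations whose x and y displacements both stay within the
#' thresholds are grouped into a chain; each chain's mean y is snapped to
#' the nearest line (binary search) and all members adopt that line.
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions.
#' @param params A [chain_params()].
#' @return A `correction_result`.
#' @export
correct_chain <- function(seq, line_ys, params = chain_params()) {
  check_correct_input(seq, line_ys)
  n <- nrow(seq)
  if (n == 1L) {
    ends <- 1L
  } else {
    dist_x <- abs(diff(seq$x))
    dist_y <- abs(diff(seq$y))
    breaks <- which(dist_x > params$x_thresh | dist_y > params$y_thresh)
    ends <- c(breaks, n)   # chain i spans (prev end + 1) .. ends[i]
  }
  assignment <- integer(n)
  start <- 1L
  for (end in ends) {
    mean_y <- mean(seq$y[start:end])
    assignment[start:end] <- nearest_line(mean_y, line_ys)
    start <- end + 1L
  }
  correction_result(seq, assignment, line_ys, "chain", params)
}

# deterministic k-means on a 1-d vector: exact centers when the data have
# exactly k distinct values, otherwise seeded multi-start stats::kmeans
kmeans_1d <- function(v, k, seed, nstart = 10L) {
  u <- sort(unique(v))
  if (length(u) < k) {
    stop(sprintf("cannot form %d clusters from %d distinct values", k, length(u)))
  }
  if (length(u) == k) {
    km <- stats::kmeans(v, centers = matrix(u, ncol = 1))
  } else {
    km <- with_seed(seed, stats::kmeans(v, centers = k, nstart = nstart,
                                        iter.max = 100L))
  }
  km
}

#' Cluster: k-means on fixation y-values
#'
#' Clusters the y-values into as many groups as there are text lines,
#' orders the clusters by mean y, and matches them top-to-bottom with the
#' lines. Being based only on relative vertical position, it is invariant
#' to any constant vertical offset.
#'
#' @param seq A [fixation_sequence()]; needs at least as many fixations as
#'   lines.
#' @param line_ys Sorted line y-positions.
#' @param seed Integer seed for the k-means restarts (deterministic).
#' @return A `correction_result`.
#' @export
correct_cluster <- function(seq, line_ys, seed = 1L) {
  check_correct_input(seq, line_ys)
  m <- length(line_ys)
  if (nrow(seq) < m) {
    stop(sprintf("cluster needs >= %d fixations to form %d clusters", m, m))
  }
  km <- kmeans_1d(seq$y, m, seed)
  ord <- order(km$centers[, 1L])                 # clusters top to bottom
  line_of_cluster <- integer(m)
  line_of_cluster[ord] <- seq_len(m) - 1L
  correction_result(seq, line_of_cluster[km$cluster], line_ys,
                    "cluster", list(seed = seed))
}

# slope and RMS residual of the least-squares line through (x, y)
line_fit <- function(x, y) {
  if (length(unique(x)) < 2L) {
    return(list(gradient = Inf, error = sqrt(mean((y - mean(y))^2))))
  }
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  resid <- y - (my + slope * (x - mx))
  list(gradient = slope, error = sqrt(mean(resid^2)))
}

#' Merge: progressive merging of fixation runs into lines
#'
#' Splits the sequence at x-backtracks and large vertical jumps into short
#' runs, then merges pairs of runs over four phases with progressively
#' relaxed constraints on the regression line through the merged points:
#' phase 1 requires both a flat gradient and a small residual error, phase
#' 2 only the gradient, phase 3 only the error, and the final phase is
#' unconstrained. Merging stops once the number of runs matches the number
#' of lines; runs are then ordered by mean y and mapped to the lines
#' top-to-bottom (or to their nearest line if fewer runs than lines
#' remain).
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions.
#' @param gradient_thresh Maximum |slope| of an acceptable merged fit.
#' @param error_thresh Maximum RMS residual (pixels) of an acceptable
#'   merged fit.
#' @param split_params A [chain_params()]; a new run starts where x drops
#'   by more than `x_thresh` or |dy| exceeds `y_thresh`.
#' @return A `correction_result`.
#' @export
correct_merge <- function(seq, line_ys, gradient_thresh = 0.1,
                          error_thresh = 20, split_params = chain_params()) {
  check_correct_input(seq, line_ys)
  n <- nrow(seq)
  m <- length(line_ys)
  if (n == 1L) {
    return(correction_result(seq, nearest_line(seq$y, line_ys), line_ys,
                             "merge", list(gradient_thresh = gradient_thresh,
                                           error_thresh = error_thresh)))
  }
  dx <- diff(seq$x); dy <- diff(seq$y)
  breaks <- which(dx < -split_params$x_thresh | abs(dy) > split_params$y_thresh)
  bounds <- c(0L, breaks, n)
  runs <- lapply(seq_len(length(bounds) - 1L),
                 function(i) (bounds[i] + 1L):bounds[i + 1L])

  phases <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  for (ph in phases) {
    repeat {
      if (length(runs) <= m) break
      k <- length(runs)
      best <- NULL; best_err <- Inf
      for (i in seq_len(k - 1L)) {
        for (j in seq(i + 1L, k)) {
          idx <- c(runs[[i]], runs[[j]])
          fit <- line_fit(seq$x[idx], seq$y[idx])
          ok <- (!ph[1L] || abs(fit$gradient) <= gradient_thresh) &&
                (!ph[2L] || fit$error <= error_thresh)
          if (ok && fit$error < best_err) {
            best <- c(i, j); best_err <- fit$error
          }
        }
      }
      if (is.null(best)) break
      runs[[best[1L]]] <- sort(c(runs[[best[1L]]], runs[[best[2L]]]))
      runs[[best[2L]]] <- NULL
    }
  }

  mean_ys <- vapply(runs, function(idx) mean(seq$y[idx]), numeric(1))
  assignment <- integer(n)
  if (length(runs) == m) {
    line_of_run <- integer(m)
    line_of_run[order(mean_ys)] <- seq_len(m) - 1L
  } else {
    line_of_run <- nearest_line(mean_ys, line_ys)
  }
  for (r in seq_along(runs)) assignment[runs[[r]]] <- line_of_run[r]
  correction_result(seq, assignment, line_ys, "merge",
                    list(gradient_thresh = gradient_thresh,
                         error_thresh = error_thresh))
}

#' Parameters for the regress corrector
#'
#' Bounds for the linear-transform parameters: `slope` (vertical px of
#' drift per px of x), `offset` (px) and `sd` (Gaussian spread, px).
#'
#' @param slope_bounds,offset_bounds,sd_bounds Length-2 `(lo, hi)` pairs.
#' @return A `regress_params` list.
#' @export
regress_params <- function(slope_bounds = c(-0.1, 0.1),
                           offset_bounds = c(-25, 25),
                           sd_bounds = c(1, 20)) {
  for (b in list(slope_bounds, offset_bounds, sd_bounds)) {
    stopifnot(length(b) == 2L, b[1L] < b[2L])
  }
  list(slope_bounds = slope_bounds, offset_bounds = offset_bounds,
       sd_bounds = sd_bounds)
}

#' Regress: maximum-likelihood linear drift model
#'
#' Models each fixation's observed y as Gaussian around a per-line
#' prediction `line_y + slope * x + offset` and fits `(slope, offset, sd)`
#' by bounded quasi-Newton minimization of the negative log-likelihood,
#' where each fixation contributes its best (highest-density) line. After
#' fitting, each fixation is assigned to its maximum-probability line.
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions.
#' @param params A [regress_params()].
#' @return A `correction_result`.
#' @export
correct_regress <- function(seq, line_ys, params = regress_params()) {
  check_correct_input(seq, line_ys)
  x <- seq$x; y <- seq$y
  pred_base <- outer(y, line_ys, "-")          # n x m: y - line_y

  best_seen <- list(value = Inf, par = NULL)
  nll <- function(par) {
    # residuals of y against line_y + slope*x + offset, per line
    resid <- pred_base - (par[1L] * x + par[2L])
    lp <- stats::dnorm(resid, mean = 0, sd = par[3L], log = TRUE)
    val <- -sum(apply(lp, 1L, max))
    if (is.finite(val) && val < best_seen$value) {
      best_seen$value <<- val; best_seen$par <<- par
    }
    val
  }
  lower <- c(params$slope_bounds[1L], params$offset_bounds[1L], params$sd_bounds[1L])
  upper <- c(params$slope_bounds[2L], params$offset_bounds[2L], params$sd_bounds[2L])
  start <- c(0, 0, mean(params$sd_bounds))
  start <- pmin(pmax(start, lower), upper)
  fit <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper),
    error = function(e) {
      warning("regress optimizer failed (", conditionMessage(e),
              "); using best evaluated parameters")
      NULL
    })
  par <- if (!is.null(fit)) fit$par else best_seen$par
  if (is.null(par)) par <- start
  resid <- pred_base - (par[1L] * x + par[2L])
  lp <- stats::dnorm(resid, mean = 0, sd = par[3L], log = TRUE)
  assignment <- max.col(lp, ties.method = "first") - 1L
  correction_result(seq, assignment, line_ys, "regress",
                    c(params, list(fit = list(slope = par[1L], offset = par[2L],
                                              sd = par[3L]))))
}

#' Segment: split the walk at the largest return sweeps
#'
#' Treats the `m - 1` most negative consecutive x-displacements as the
#' return sweeps between the `m` text lines, and assigns fixations to lines
#' 0..m-1 in order, incrementing the line at each sweep. Assumes strictly
#' linear reading (top to bottom, no regressions).
#'
#' @param seq A [fixation_sequence()] with at least `m` fixations.
#' @param line_ys Sorted line y-positions.
#' @return A `correction_result` with non-decreasing line assignment.
#' @export
correct_segment <- function(seq, line_ys) {
  check_correct_input(seq, line_ys)
  n <- nrow(seq)
  m <- length(line_ys)
  if (m - 1L > n - 1L) {
    stop(sprintf("segment needs at least %d fixations for %d lines", m, m))
  }
  assignment <- integer(n)
  if (m > 1L) {
    dx <- diff(seq$x)
    sweeps <- sort(order(dx)[seq_len(m - 1L)])   # most negative displacements
    line <- 0L
    pos <- 1L
    for (s in c(sweeps, n)) {
      assignment[pos:s] <- line
      if (line < m - 1L) line <- line + 1L
      pos <- s + 1L
    }
    if (pos <= n) assignment[pos:n] <- m - 1L
  }
  correction_result(seq, assignment, line_ys, "segment")
}

#' Split: 2-means clustering of saccades into sweeps and within-line moves
#'
#' Clusters the consecutive x-displacements into two groups with k-means;
#' the group with the lower mean (the large leftward sweeps) marks line
#' transitions. The sequence is cut at those saccades and each resulting
#' segment's mean y is snapped to the nearest line.
#'
#' @param seq A [fixation_sequence()] with at least 3 fixations.
#' @param line_ys Sorted line y-positions.
#' @param seed Integer seed for the k-means restarts.
#' @return A `correction_result`.
#' @export
correct_split <- function(seq, line_ys, seed = 1L) {
  check_correct_input(seq, line_ys)
  n <- nrow(seq)
  if (n < 3L) stop("split needs at least 3 fixations")
  dx <- diff(seq$x)
  if (length(unique(dx)) < 2L) {
    stop("split is undefined when all x-displacements are identical")
  }
  km <- kmeans_1d(dx, 2L, seed)
  sweep_cluster <- which.min(km$centers[, 1L])
  cut_after <- which(km$cluster == sweep_cluster)   # saccade i ends segment at i
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  assignment <- integer(n)
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    assignment[idx] <- nearest_line(mean(seq$y[idx]), line_ys)
  }
  correction_result(seq, assignment, line_ys, "split", list(seed = seed))
}

#' Parameters for the stretch corrector
#'
#' @param scale_bounds Bounds for the vertical scale; must contain 1.
#' @param offset_bounds Bounds for the vertical offset (px); must contain 0.
#' @return A `stretch_params` list.
#' @export
stretch_params <- function(scale_bounds = c(0.9, 1.1),
                           offset_bounds = c(-25, 25)) {
  stopifnot(length(scale_bounds) == 2L, scale_bounds[1L] < scale_bounds[2L],
            scale_bounds[1L] <= 1, scale_bounds[2L] >= 1,
            length(offset_bounds) == 2L, offset_bounds[1L] < offset_bounds[2L],
            offset_bounds[1L] <= 0, offset_bounds[2L] >= 0)
  list(scale_bounds = scale_bounds, offset_bounds = offset_bounds)
}

#' Stretch: global scale-and-offset alignment
#'
#' Finds the vertical scale and offset minimizing the total absolute
#' distance between transformed y-values and their nearest lines,
#' `sum(|s*y + o - nearest_line_y(s*y + o)|)`, by a bounded derivative-free
#' search (coarse grid followed by Nelder-Mead refinement, parameters
#' clamped to the bounds). Final y-values are the nearest lines of the
#' transformed coordinates.
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions.
#' @param params A [stretch_params()].
#' @return A `correction_result`.
#' @export
correct_stretch <- function(seq, line_ys, params = stretch_params()) {
  check_correct_input(seq, line_ys)
  y <- seq$y
  cost <- function(scale, offset) {
    ty <- scale * y + offset
    sum(abs(ty - line_y_at(line_ys, nearest_line(ty, line_ys))))
  }
  # coarse grid: the objective is continuous but has flat regions, so a
  # gradient-free global stage is needed before local polish
  scales <- seq(params$scale_bounds[1L], params$scale_bounds[2L], length.out = 21L)
  offsets <- seq(params$offset_bounds[1L], params$offset_bounds[2L], length.out = 51L)
  grid <- expand.grid(scale = scales, offset = offsets)
  vals <- mapply(cost, grid$scale, grid$offset)
  best <- grid[which.min(vals), ]
  clamp <- function(par) c(
    min(max(par[1L], params$scale_bounds[1L]), params$scale_bounds[2L]),
    min(max(par[2L], params$offset_bounds[1L]), params$offset_bounds[2L]))
  obj <- function(par) { par <- clamp(par); cost(par[1L], par[2L]) }
  fit <- stats::optim(c(best$scale, best$offset), obj, method = "Nelder-Mead",
                      control = list(maxit = 500L))
  par <- clamp(fit$par)
  if (obj(par) > cost(1, 0)) par <- c(1, 0)   # never worse than the identity
  ty <- par[1L] * y + par[2L]
  assignment <- nearest_line(ty, line_ys)
  correction_result(seq, assignment, line_ys, "stretch",
                    c(params, list(fit = list(scale = par[1L],
                                              offset = par[2L],
                                              cost = cost(par[1L], par[2L])))))
}

# dynamic-time-warping alignment of two point sets (rows of a and b);
# returns the accumulated cost and the warping path as an index matrix
dtw_align <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d[, j] <- sqrt((a[, 1L] - b[j, 1L])^2 + (a[, 2L] - b[j, 2L])^2)
  }
  acc <- matrix(Inf, n + 1L, m + 1L)
  acc[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc[i + 1L, j + 1L] <- d[i, j] +
        min(acc[i, j], acc[i, j + 1L], acc[i + 1L, j])
    }
  }
  # backtrack; prefer the diagonal on ties, then the vertical move
  path <- matrix(0L, 0L, 2L)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    path <- rbind(c(i, j), path)
    steps <- c(acc[i, j], acc[i, j + 1L], acc[i + 1L, j])
    move <- which.min(steps)
    if (move == 1L) { i <- i - 1L; j <- j - 1L }
    else if (move == 2L) { i <- i - 1L }
    else { j <- j - 1L }
  }
  list(cost = acc[n + 1L, m + 1L], path = path)
}

#' Warp: dynamic-time-warping alignment to the word sequence
#'
#' Aligns the fixation sequence with the reading-order sequence of word
#' centers by dynamic time warping over pairwise Euclidean distances, then
#' sets each fixation's line to the modal line of the words it was matched
#' with (ties to the topmost line). Assumes roughly linear reading order.
#'
#' @param seq A [fixation_sequence()].
#' @param layout A [text_layout()].
#' @return A `correction_result`.
#' @export
correct_warp <- function(seq, layout) {
  check_correct_input(seq, layout$line_ys)
  wc <- layout$word_centers
  aln <- dtw_align(cbind(seq$x, seq$y), cbind(wc$cx, wc$cy))
  n <- nrow(seq)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    words <- aln$path[aln$path[, 1L] == i, 2L]
    lines <- wc$line[words]
    counts <- table(lines)
    modal <- as.integer(names(counts)[counts == max(counts)])
    assignment[i] <- min(modal)                 # tie -> topmost line
  }
  correction_result(seq, assignment, layout$line_ys, "warp",
                    list(dtw_cost = aln$cost))
}

#' Run all nine correction algorithms
#'
#' Applies attach, chain, cluster, merge, regress, segment, split, stretch
#' and warp to one trial with a shared configuration. Algorithms that error
#' on the input (e.g. too few fixations) are recorded as failures while the
#' others proceed.
#'
#' @param seq A [fixation_sequence()].
#' @param layout A [text_layout()].
#' @param config Optional list of per-algorithm parameters: `chain`,
#'   `merge` (`gradient_thresh`, `error_thresh`), `regress`, `stretch`,
#'   and `seed` (shared by cluster and split).
#' @return Named list of nine `correction_result` objects (or
#'   `correction_failure` records), in a fixed algorithm order.
#' @export
run_all_corrections <- function(seq, layout, config = list()) {
  line_ys <- layout$line_ys
  L2 <- if (length(line_ys) > 1L) (line_ys[2L] - line_ys[1L]) / 2 else 25
  seed <- config$seed %||% 1L
  regress_p <- config$regress %||% regress_params(offset_bounds = c(-L2, L2))
  stretch_p <- config$stretch %||% stretch_params(offset_bounds = c(-L2, L2))
  chain_p <- config$chain %||% chain_params()
  merge_cfg <- config$merge %||% list(gradient_thresh = 0.1, error_thresh = 20)

  runners <- list(
    attach  = function() correct_attach(seq, line_ys),
    chain   = function() correct_chain(seq, line_ys, chain_p),
    cluster = function() correct_cluster(seq, line_ys, seed = seed),
    merge   = function() correct_merge(seq, line_ys,
                                       gradient_thresh = merge_cfg$gradient_thresh,
                                       error_thresh = merge_cfg$error_thresh),
    regress = function() correct_regress(seq, line_ys, regress_p),
    segment = function() correct_segment(seq, line_ys),
    split   = function() correct_split(seq, line_ys, seed = seed),
    stretch = function() correct_stretch(seq, line_ys, stretch_p),
    warp    = function() correct_warp(seq, layout)
  )
  lapply(runners, function(run) {
    tryCatch(run(), error = function(e) {
      structure(list(error = conditionMessage(e)),
                class = "correction_failure")
    })
  })
}

#' Names of the nine correction algorithms
#' @return Character vector in canonical order.
#' @export
correction_algorithms <- function() {
  c("attach", "chain", "cluster", "merge", "regress",
    "segment", "split", "stretch", "warp")
}
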