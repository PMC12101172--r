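# Parametric drift distortions. All four preserve fixation count, order and
# durations; only error_offset touches x.

#' Vertical Gaussian noise distortion
#'
#' Perturbs each fixation's y-coordinate by an independent draw from
#' N(0, `ynoise`), emulating jittery, uncorrelated vertical measurement
#' error. x and duration are untouched.
#'
#' @param seq A [fixation_sequence()].
#' @param ynoise Standard deviation of the vertical noise, pixels (>= 0).
#' @param seed Optional integer; fixes the draws exactly.
#' @param subset Optional logical or integer index selecting which fixations
#'   to perturb; by default every fixation is perturbed.
#' @return A distorted `fixation_sequence`.
#' @export
error_noise <- function(seq, ynoise, seed = NULL, subset = NULL) {
  if (!is.finite(ynoise) || ynoise < 0) stop("ynoise must be >= 0")
  n <- nrow(seq)
  if (n == 0L) return(seq)
  mask <- rep(TRUE, n)
  if (!is.null(subset)) { mask <- rep(FALSE, n); mask[subset] <- TRUE }
  pert <- with_seed(seed, stats::rnorm(n, mean = 0, sd = ynoise))
  out <- seq
  out$y <- seq$y + ifelse(mask, pert, 0)
  out
}

#' Slope distortion (x-dependent vertical drift)
#'
#' Adds a vertical displacement proportional to each fixation's horizontal
#' distance from the first fixation:
#' `y' = y + ((x - first_x) / 100) * slope_factor`. Fixations at the
#' left edge are untouched; drift grows linearly to the right, emulating a
#' calibration error that affects one side of the screen.
#'
#' @param seq A [fixation_sequence()]; must be non-empty.
#' @param slope_factor Vertical pixels of drift per 100 px of horizontal
#'   distance from the first fixation.
#' @return A distorted `fixation_sequence`.
#' @export
error_slope <- function(seq, slope_factor) {
  if (nrow(seq) == 0L) stop("error_slope requires a non-empty sequence")
  if (!is.finite(slope_factor)) stop("slope_factor must be finite")
  out <- seq
  out$y <- seq$y + (seq$x - seq$x[1L]) / 100 * slope_factor
  out
}

#' Shift distortion (line-dependent vertical drift)
#'
#' Adds a vertical displacement proportional to each fixation's distance
#' from the first text line, in units of line height:
#' `y' = y + (|y - line_ys[1]| / line_height) * y_shift_factor`, with
#' `line_height = line_ys[2] - line_ys[1]`. The first line stays put and
#' drift accumulates down the page.
#'
#' @param seq A [fixation_sequence()].
#' @param line_ys Sorted line y-positions; at least two lines.
#' @param y_shift_factor Vertical pixels of drift per line of distance from
#'   the top line.
#' @return A distorted `fixation_sequence`.
#' @export
error_shift <- function(seq, line_ys, y_shift_factor) {
  if (length(line_ys) < 2L) {
    stop("error_shift requires at least two lines (line height undefined)")
  }
  if (!is.finite(y_shift_factor)) stop("y_shift_factor must be finite")
  line_height <- line_ys[2L] - line_ys[1L]
  out <- seq
  out$y <- seq$y + abs(seq$y - line_ys[1L]) / line_height * y_shift_factor
  out
}

#' Constant offset distortion
#'
#' Translates every fixation by `(x_offset, y_offset)`, emulating a uniform
#' calibration offset.
#'
#' @param seq A [fixation_sequence()].
#' @param x_offset,y_offset Finite offsets in pixels.
#' @return A distorted `fixation_sequence`.
#' @export
error_offset <- function(seq, x_offset, y_offset) {
  if (!is.finite(x_offset) || !is.finite(y_offset)) {
    stop("offsets must be finite")
  }
  out <- seq
  out$x <- seq$x + x_offset
  out$y <- seq$y + y_offset
  out
}

#' Describe a distortion
#'
#' A `distortion_spec` names one of the four distortion kinds together with
#' its magnitude parameters and (for the stochastic noise kind) a seed, so
#' that a distortion can be recorded in a manifest and replayed exactly.
#'
#' @param kind One of `"noise"`, `"slope"`, `"shift"`, `"offset"`.
#' @param ... Magnitude parameters: `ynoise` for noise; `slope_factor` for
#'   slope; `y_shift_factor` for shift; `x_offset`, `y_offset` for offset.
#' @param seed Integer seed (noise only).
#' @return A `distortion_spec` object.
#' @examples
#' distortion_spec("offset", x_offset = 0, y_offset = 30)
#' @export
distortion_spec <- function(kind = c("noise", "slope", "shift", "offset"),
                            ..., seed = NULL) {
  kind <- match.arg(kind)
  params <- list(...)
  needed <- switch(kind,
    noise  = "ynoise",
    slope  = "slope_factor",
    shift  = "y_shift_factor",
    offset = c("x_offset", "y_offset"))
  miss <- setdiff(needed, names(params))
  if (length(miss) > 0L) {
    stop(sprintf("distortion kind '%s' needs parameter(s): %s",
                 kind, paste(miss, collapse = ", ")))
  }
  vals <- unlist(params[needed])
  if (any(!is.finite(vals))) stop("distortion parameters must be finite")
  if (kind == "noise" && params$ynoise < 0) stop("ynoise must be >= 0")
  structure(list(kind = kind, params = params[needed], seed = seed),
            class = "distortion_spec")
}

#' @export
print.distortion_spec <- function(x, ...) {
  cat(sprintf("Distortion '%s' (%s)%s\n", x$kind,
              paste(names(x$params), unlist(x$params),
                    sep = "=", collapse = ", "),
              if (is.null(x$seed)) "" else paste0(" seed=", x$seed)))
  invisible(x)
}

#' Apply a distortion spec to a fixation sequence
#'
#' @param seq A [fixation_sequence()].
#' @param spec A [distortion_spec()].
#' @param layout A [text_layout()]; required for the shift kind.
#' @return A distorted `fixation_sequence`.
#' @export
apply_distortion <- function(seq, spec, layout = NULL) {
  stopifnot(inherits(spec, "distortion_spec"))
  switch(spec$kind,
    noise  = error_noise(seq, spec$params$ynoise, seed = spec$seed),
    slope  = error_slope(seq, spec$params$slope_factor),
    shift  = {
      if (is.null(layout)) stop("shift distortion requires a layout")
      error_shift(seq, layout$line_ys, spec$params$y_shift_factor)
    },
    offset = error_offset(seq, spec$params$x_offset, spec$params$y_offset))
}
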