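# Chemical (progress) baseline removal.
#
# Beneath the unfolding endotherm the apparent molar heat capacity follows
# the folded trend before the transition and the unfolded trend after it.
# The chemical baseline connects the two trends through the transition
# region in proportion to the extent of conversion: where the protein is
# mostly folded the baseline tracks the pre-transition line, where mostly
# unfolded the post-transition line. Because the extent of conversion is
# itself computed from the baseline-corrected signal, the construction is
# iterated to a fixed point, starting from a cubic Hermite connector that
# matches value and slope of the two linear trends at the window edges.

#' Baseline windows and connector degree
#'
#' @param pre_window numeric length-2 interval (degC) of pure
#'   pre-transition signal; default: lowest 15\% of the grid.
#' @param post_window numeric length-2 interval of pure post-transition
#'   signal; default: highest 15\%. Must lie entirely above `pre_window`.
#' @param polynomial_degree degree of the initial connector across the
#'   transition: 3 (cubic Hermite, default) or 1 (linear).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(pre_window = NULL, post_window = NULL,
                          polynomial_degree = 3) {
  if (!polynomial_degree %in% c(1, 3)) {
    dscfit_stop("polynomial_degree must be 1 or 3", "dscfit_invalid_input")
  }
  chk <- function(w, nm) {
    if (is.null(w)) return(NULL)
    if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2]) {
      dscfit_stop(sprintf("`%s` must be an increasing length-2 interval", nm),
                  "dscfit_invalid_window")
    }
    as.numeric(w)
  }
  pre <- chk(pre_window, "pre_window")
  post <- chk(post_window, "post_window")
  if (!is.null(pre) && !is.null(post) && pre[2] >= post[1]) {
    dscfit_stop("pre_window must lie entirely below post_window",
                "dscfit_invalid_window")
  }
  structure(list(pre_window = pre, post_window = post,
                 polynomial_degree = polynomial_degree),
            class = "baseline_spec")
}

# Resolve default windows: lowest/highest 15% of the temperature range.
resolve_windows <- function(tt, spec) {
  rng <- range(tt)
  span <- diff(rng)
  pre <- spec$pre_window %||% c(rng[1], rng[1] + 0.15 * span)
  post <- spec$post_window %||% c(rng[2] - 0.15 * span, rng[2])
  list(pre = pre, post = post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear trend fit in a window; returns c(intercept, slope).
window_trend <- function(tt, y, window, which) {
  in_w <- tt >= window[1] & tt <= window[2]
  if (sum(in_w) < 5) {
    dscfit_stop(sprintf("%s window contains fewer than 5 points", which),
                "dscfit_invalid_window")
  }
  stats::coef(stats::lm(y[in_w] ~ tt[in_w]))
}

# Cubic Hermite (or linear) connector between the two trends over
# [t1, t2], matching value (and slope for degree 3) at the edges.
connector <- function(tt, t1, t2, pre_c, post_c, degree) {
  s <- (tt - t1) / (t2 - t1)
  y1 <- pre_c[1] + pre_c[2] * t1
  y2 <- post_c[1] + post_c[2] * t2
  if (degree == 1) return(y1 + (y2 - y1) * s)
  h <- t2 - t1
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * y1 + h10 * h * pre_c[2] + h01 * y2 + h11 * h * post_c[2]
}

#' Remove the chemical baseline from a molar thermogram
#'
#' Fits linear trends of the apparent molar heat capacity inside the pre-
#' and post-transition windows, constructs a progress baseline blending
#' the two trends in proportion to the extent of conversion, and returns
#' the excess heat capacity (signal minus baseline). The extent of
#' conversion is estimated from the running integral of the positive
#' excess signal and the construction is iterated (at most `max_iter`
#' rounds) until the baseline is stationary. The first iterate uses a
#' cubic Hermite connector between the window edges.
#'
#' @param tg a `molar`-stage [thermogram()].
#' @param spec a [baseline_spec()]; default windows are the lowest and
#'   highest 15\% of the temperature range.
#' @param max_iter maximum fixed-point iterations (default 20).
#' @param tol relative convergence tolerance on the baseline change
#'   (default 1e-6).
#' @return A list of class `baseline_result` with elements `excess` (an
#'   `excess`-stage thermogram), `baseline` (per-point values),
#'   `pre_trend`/`post_trend` (intercept, slope), `iterations`,
#'   `converged`.
#' @export
remove_chemical_baseline <- function(tg, spec = baseline_spec(),
                                     max_iter = 20, tol = 1e-6) {
  if (tg$stage != "molar") {
    dscfit_stop("baseline removal requires a molar-stage thermogram",
                "dscfit_invalid_input")
  }
  tt <- tg$temperature
  y <- tg$cp
  w <- resolve_windows(tt, spec)
  pre_c <- window_trend(tt, y, w$pre, "pre")
  post_c <- window_trend(tt, y, w$post, "post")
  t1 <- w$pre[2]
  t2 <- w$post[1]
  pre_line <- pre_c[1] + pre_c[2] * tt
  post_line <- post_c[1] + post_c[2] * tt
  mid <- tt > t1 & tt < t2

  # initial baseline: trends outside, polynomial connector inside
  baseline <- ifelse(tt <= t1, pre_line, post_line)
  baseline[mid] <- connector(tt[mid], t1, t2, pre_c, post_c,
                             spec$polynomial_degree)

  converged <- FALSE
  it <- 0
  scale <- max(abs(y - baseline), abs(y), 1e-300)
  while (it < max_iter) {
    it <- it + 1
    excess <- pmax(y - baseline, 0)
    area <- cumtrapz(tt, excess)
    total <- area[length(area)]
    alpha <- if (total > 0) area / total else as.numeric(tt >= t1)
    # progress blend of the two trends; clamp to pure trends outside
    new_bl <- (1 - alpha) * pre_line + alpha * post_line
    new_bl[tt <= t1] <- pre_line[tt <= t1]
    new_bl[tt >= t2] <- post_line[tt >= t2]
    delta <- max(abs(new_bl - baseline)) / scale
    baseline <- new_bl
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("baseline iteration did not converge; returning last iterate")
  }
  excess_tg <- thermogram(tt, y - baseline,
                          scan_rate = tg$scan_rate, conc = tg$conc,
                          cell_volume = tg$cell_volume, stage = "excess")
  structure(list(excess = excess_tg, baseline = baseline,
                 pre_trend = unname(pre_c), post_trend = unname(post_c),
                 iterations = it, converged = converged,
                 windows = w),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf(
    "Chemical baseline removal: %d iterations (%s), windows [%.1f, %.1f] / [%.1f, %.1f] degC\n",
    x$iterations, if (x$converged) "converged" else "not converged",
    x$windows$pre[1], x$windows$pre[2],
    x$windows$post[1], x$windows$post[2]))
  invisible(x)
}
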