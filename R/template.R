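#' Six-line geometric template for a CW-bias trace
#'
#' The canonical shape of an ensemble attractant response: a flat
#' pre-stimulus baseline (L1 at level `b`), a depressed flat excitation
#' segment (L2 at level `r`, starting at the stimulus time `t1`), three
#' linear recovery segments (L3, L4, L5 ending at levels `v3`, `v4`, `v5`),
#' and a flat post-adaptation segment (L6 at `g = v5`).
#'
#' @param b Baseline CW bias (L1 level), in `[0, 1]`.
#' @param r Excitation CW bias (L2 level); attractants drive this toward 0,
#'   so the constraint `b >= r` is required.
#' @param t1,t2,t3,t4,t5 Breakpoints in seconds: `t1` is the stimulus time
#'   (start of L2); `t2`..`t5` end L2..L5. Must be non-decreasing.
#' @param v3,v4,v5 CW-bias levels at the ends of L3, L4, L5. `v5` is also the
#'   final level `g`. Recovery need not be monotone (overshoot is allowed).
#' @return An object of class `six_line_template`.
#' @examples
#' tpl <- six_line_template(b = 0.3, r = 0, t1 = 100, t2 = 250, t3 = 300,
#'                          t4 = 350, t5 = 400, v3 = 0.1, v4 = 0.25, v5 = 0.3)
#' render_template(tpl, c(50, 275, 500))
#' @export
six_line_template <- function(b, r, t1, t2, t3, t4, t5, v3, v4, v5) {
  ts <- c(t1, t2, t3, t4, t5)
  if (any(diff(ts) < -1e-9)) {
    abort("breakpoints must satisfy t1 <= t2 <= t3 <= t4 <= t5")
  }
  lv <- c(b, r, v3, v4, v5)
  if (any(!is.finite(lv)) || any(lv < -1e-9) || any(lv > 1 + 1e-9)) {
    abort("all levels must be finite and in [0, 1]")
  }
  if (r > b + 1e-9) abort("excitation level r must not exceed baseline b")
  structure(list(b = b, r = r, t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
                 v3 = v3, v4 = v4, v5 = v5, g = v5),
            class = "six_line_template")
}

#' @export
print.six_line_template <- function(x, ...) {
  cat(sprintf(paste0("<six_line_template> b=%.3f r=%.3f ",
                     "t=[%.1f, %.1f, %.1f, %.1f, %.1f] v=[%.3f, %.3f, %.3f]\n"),
              x$b, x$r, x$t1, x$t2, x$t3, x$t4, x$t5, x$v3, x$v4, x$v5))
  invisible(x)
}

#' Evaluate a six-line template at given times
#'
#' Piecewise-linear forward model: flat at `b` before `t1`, flat at `r` on
#' `[t1, t2]` (left-closed, so the value at exactly `t1` is `r`), linear
#' interpolation across L3-L5, flat at `g` after `t5`.
#'
#' @param tpl A [six_line_template()].
#' @param times Numeric vector of times in seconds, sorted ascending.
#' @return Numeric vector of CW-bias values.
#' @export
render_template <- function(tpl, times) {
  stopifnot(inherits(tpl, "six_line_template"))
  if (is.unsorted(times)) abort("`times` must be sorted ascending")
  interp <- function(t, ta, tb, ya, yb) {
    if (tb > ta) ya + (yb - ya) * (t - ta) / (tb - ta) else yb
  }
  vapply(times, function(t) {
    if (t < tpl$t1) tpl$b
    else if (t <= tpl$t2) tpl$r
    else if (t <= tpl$t3) interp(t, tpl$t2, tpl$t3, tpl$r, tpl$v3)
    else if (t <= tpl$t4) interp(t, tpl$t3, tpl$t4, tpl$v3, tpl$v4)
    else if (t <= tpl$t5) interp(t, tpl$t4, tpl$t5, tpl$v4, tpl$v5)
    else tpl$g
  }, numeric(1))
}

#' Render a template into a binned CW-bias trace
#'
#' Convenience forward model used for simulation-free testing: evaluates the
#' template at bin midpoints (the same convention the fitter uses) and
#' optionally adds i.i.d. Gaussian noise, clipped to `[0, 1]`.
#'
#' @inheritParams render_template
#' @param duration Trace duration in seconds (at most 600).
#' @param bin_width Bin width in seconds.
#' @param noise_sd Standard deviation of additive Gaussian noise (bias units).
#' @return A [cw_trace()] with `stimulus_time = tpl$t1`.
#' @export
trace_from_template <- function(tpl, duration = 600, bin_width = 1,
                                noise_sd = 0) {
  t_start <- seq(0, duration - bin_width, by = bin_width)
  vals <- render_template(tpl, t_start + bin_width / 2)
  if (noise_sd > 0) {
    vals <- pmin(1, pmax(0, vals + stats::rnorm(length(vals), 0, noise_sd)))
  }
  cw_trace(t_start, vals, bin_width = bin_width, stimulus_time = tpl$t1)
}

#' Fit the six-line template to a CW-bias trace
#'
#' Least-squares fit over non-missing bins, exploiting the conditionally
#' linear structure: `t1` is pinned to the known stimulus time; the baseline
#' `b` is the mean of pre-stimulus bins; for any candidate set of segment
#' durations the remaining levels `(r, v3, v4, v5)` solve a box-constrained
#' linear least-squares problem. Durations are searched on a coarse grid,
#' refined on a 5-s grid around the incumbent, then polished by Nelder-Mead.
#' The search is deterministic: the same trace and settings always return
#' the same template.
#'
#' @param trace A [cw_trace()] with at least `min_bins` non-missing bins and
#'   a known stimulus time.
#' @param r_max Upper bound on the excitation level `r` (the attractant
#'   response drives CW bias to approximately 0; default 0.2).
#' @param coarse_step Coarse grid step for segment durations, seconds.
#' @param refine_step Refinement grid step, seconds.
#' @param max_excitation Largest excitation duration searched, seconds.
#' @param max_segment Largest single recovery-segment duration searched,
#'   seconds.
#' @param min_bins Minimum number of non-missing bins required.
#' @return An object of class `template_fit`: a list with elements
#'   `template` ([six_line_template()]), `fit_rms` (root-mean-square
#'   residual, bias units), `rss`, `n_bins`, `convergence` and the input
#'   `trace`.
#' @export
fit_template <- function(trace, r_max = 0.2, coarse_step = 25,
                         refine_step = 5, max_excitation = 400,
                         max_segment = 250, min_bins = 20) {
  stopifnot(inherits(trace, "cw_trace"))
  bw <- attr(trace, "bin_width")
  t1 <- attr(trace, "stimulus_time")
  keep <- !is.na(trace$cw_bias)
  tt <- trace$t_start[keep] + bw / 2
  yy <- trace$cw_bias[keep]
  if (length(yy) < min_bins) {
    abort(sprintf("trace has %d non-missing bins; at least %d required",
                  length(yy), min_bins))
  }
  t_max <- max(trace$t_start) + bw
  pre <- tt < t1
  b_level <- if (any(pre)) min(1, max(0, mean(yy[pre]))) else min(1, max(0, mean(yy)))

  span <- t_max - t1
  grid_d2 <- seq(0, min(max_excitation, span), by = coarse_step)
  grid_seg <- seq(0, min(max_segment, span), by = coarse_step)
  coarse <- template_grid_cpp(tt, yy, t1, grid_d2, grid_seg, grid_seg,
                              grid_seg, b_level, r_max, t_max)
  fine <- coarse
  for (step in c(coarse_step / 2.5, refine_step)) {
    axes <- lapply(fine$d, function(d0) {
      unique(pmax(0, seq(d0 - 2 * step, d0 + 2 * step, by = step)))
    })
    fine <- template_grid_cpp(tt, yy, t1, axes[[1]], axes[[2]],
                              axes[[3]], axes[[4]], b_level, r_max, t_max)
  }

  obj <- function(d) {
    if (any(d < 0) || t1 + sum(d) > t_max) return(1e10)
    template_rss_cpp(tt, yy, t1, d, b_level, r_max)$rss
  }
  nm <- stats::optim(fine$d, obj, method = "Nelder-Mead",
                     control = list(maxit = 4000, reltol = 1e-12))
  # accept the polish only on strict improvement so degenerate flat fits
  # keep their exact grid solution
  best_d <- if (nm$value < fine$rss - 1e-12) pmax(0, nm$par) else fine$d
  sol <- template_rss_cpp(tt, yy, t1, best_d, b_level, r_max)
  lv <- sol$levels
  tpl <- six_line_template(
    b = b_level, r = min(lv[1], b_level),
    t1 = t1, t2 = t1 + best_d[1], t3 = t1 + sum(best_d[1:2]),
    t4 = t1 + sum(best_d[1:3]), t5 = t1 + sum(best_d),
    v3 = lv[2], v4 = lv[3], v5 = lv[4])
  structure(list(template = tpl,
                 fit_rms = sqrt(sol$rss / length(yy)),
                 rss = sol$rss,
                 n_bins = length(yy),
                 convergence = nm$convergence,
                 trace = trace),
            class = "template_fit")
}

#' @export
print.template_fit <- function(x, ...) {
  cat(sprintf("<template_fit> rms %.4f over %d bins\n", x$fit_rms, x$n_bins))
  print(x$template)
  invisible(x)
}

#' @rdname fit_template
#' @param x A `template_fit`.
#' @param ... Unused.
#' @export
tidy.template_fit <- function(x, ...) {
  tpl <- x$template
  tibble::tibble(
    term = c("b", "r", "t1", "t2", "t3", "t4", "t5", "v3", "v4", "v5", "g"),
    estimate = unlist(tpl[c("b", "r", "t1", "t2", "t3", "t4", "t5",
                            "v3", "v4", "v5", "g")], use.names = FALSE))
}

#' @rdname fit_template
#' @export
glance.template_fit <- function(x, ...) {
  tibble::tibble(fit_rms = x$fit_rms, rss = x$rss, n_bins = x$n_bins,
                 convergence = x$convergence)
}

#' @rdname fit_template
#' @export
autoplot.template_fit <- function(x, ...) {
  bw <- attr(x$trace, "bin_width")
  grid <- tibble::tibble(
    t = seq(min(x$trace$t_start), max(x$trace$t_start) + bw, length.out = 601))
  grid$fit <- render_template(x$template, grid$t)
  autoplot(x$trace) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$t, y = .data$fit),
                       colour = "blue", linewidth = 0.8)
}

#' Convert a fitted template to the 15-index characteristic vector
#'
#' Summarises the template geometry as the indices used for classification:
#' `y1` is the duration of L2; `(y2, y3, y4)` are the amplitude, slope and
#' duration of L3, `(y5, y6, y7)` and `(y8, y9, y10)` likewise for L4 and
#' L5; `y11`, `y12`, `y13` are the baseline, excitation and final levels;
#' `y14` is the total recovery duration; `y15` the fit RMS. Slopes of
#' zero-duration segments are 0.
#'
#' @param x A `template_fit` (from [fit_template()]) or a
#'   [six_line_template()].
#' @param fit_rms Root-mean-square residual to store as `y15`; taken from
#'   the fit when `x` is a `template_fit`.
#' @param label Chemical label for training vectors; `"UNKNOWN"` for blind
#'   samples.
#' @param concentration_mM Concentration in mM, or `NA` if unknown.
#' @return A one-row tibble with columns `y1`..`y15`, `label`,
#'   `concentration_mM`.
#' @export
template_to_vector <- function(x, fit_rms = NULL, label = "UNKNOWN",
                               concentration_mM = NA_real_) {
  if (inherits(x, "template_fit")) {
    if (is.null(fit_rms)) fit_rms <- x$fit_rms
    x <- x$template
  }
  stopifnot(inherits(x, "six_line_template"))
  if (is.null(fit_rms)) fit_rms <- 0
  seg <- function(amp, dur) if (dur > 0) amp / dur else 0
  d3 <- x$t3 - x$t2; d4 <- x$t4 - x$t3; d5 <- x$t5 - x$t4
  y <- c(x$t2 - x$t1,
         x$v3 - x$r,  seg(x$v3 - x$r, d3),  d3,
         x$v4 - x$v3, seg(x$v4 - x$v3, d4), d4,
         x$v5 - x$v4, seg(x$v5 - x$v4, d5), d5,
         x$b, x$r, x$g,
         d3 + d4 + d5,
         fit_rms)
  out <- tibble::as_tibble(as.list(setNames(y, paste0("y", 1:15))))
  out$label <- label
  out$concentration_mM <- concentration_mM
  out
}

#' Validate a tibble of characteristic vectors
#'
#' Checks the structural invariants of characteristic vectors: all 15 index
#' columns present and finite, durations (`y1`, `y4`, `y7`, `y10`, `y14`)
#' non-negative, levels (`y11`, `y12`, `y13`) in `[0, 1]`.
#'
#' @param vectors A data frame with columns `y1`..`y15`, `label`,
#'   `concentration_mM`.
#' @return The input, invisibly, on success; otherwise an error.
#' @export
validate_vectors <- function(vectors) {
  ycols <- paste0("y", 1:15)
  missing_cols <- setdiff(c(ycols, "label"), names(vectors))
  if (length(missing_cols) > 0) {
    abort(paste0("vectors lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ymat <- as.matrix(vectors[ycols])
  if (any(!is.finite(ymat))) abort("all index values must be finite")
  dur <- as.matrix(vectors[paste0("y", c(1, 4, 7, 10, 14))])
  if (any(dur < -1e-9)) abort("duration indices y1, y4, y7, y10, y14 must be >= 0")
  lev <- as.matrix(vectors[paste0("y", 11:13)])
  if (any(lev < -1e-9 | lev > 1 + 1e-9)) abort("level indices y11..y13 must be in [0, 1]")
  invisible(vectors)
}
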