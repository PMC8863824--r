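#' Label per-frame rotation increments as CW, CCW or NONE
#'
#' Tethered-cell recordings report a signed angle increment per 10-ms video
#' frame. Frames whose absolute increment exceeds `threshold` degrees are
#' counted as rotational motion; the rest (measurement noise, pauses) are
#' labelled `"NONE"` and excluded from all CW-bias calculations downstream.
#' The boundary is excluded: an increment of exactly `threshold` is `"NONE"`.
#'
#' @param angles A data frame with columns `cell_id`, `frame` and
#'   `increment_deg` (signed degrees per frame). Extra columns are carried
#'   through.
#' @param threshold Motion threshold in degrees per frame. Default 7.5, more
#'   than twice the noise floor of the assay.
#' @param cw_sign Which sign of increment counts as clockwise. The camera
#'   orientation fixes this in a real setup; the default `"negative"` maps
#'   negative increments to CW.
#' @return A tibble with columns `cell_id`, `frame`, `label` (factor-free
#'   character, one of `"CW"`, `"CCW"`, `"NONE"`) plus any extra input columns.
#' @examples
#' angles <- tibble::tibble(cell_id = "c1", frame = 1:3,
#'                          increment_deg = c(-10, 10, 5))
#' classify_directions(angles)
#' @export
classify_directions <- function(angles, threshold = 7.5,
                                cw_sign = c("negative", "positive")) {
  cw_sign <- match.arg(cw_sign)
  stopifnot(is.data.frame(angles))
  req <- c("cell_id", "frame", "increment_deg")
  missing_cols <- setdiff(req, names(angles))
  if (length(missing_cols) > 0) {
    abort(paste0("`angles` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (threshold <= 0) abort("`threshold` must be > 0")
  inc <- angles$increment_deg
  bad <- which(!is.finite(inc))
  if (length(bad) > 0) {
    abort(paste0("non-finite angle increment at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 " (cell ", angles$cell_id[bad[1]],
                 ", frame ", angles$frame[bad[1]], ")"))
  }
  sgn <- if (cw_sign == "negative") -1 else 1
  label <- dplyr::case_when(
    abs(inc) <= threshold ~ "NONE",
    sign(inc) == sgn ~ "CW",
    TRUE ~ "CCW"
  )
  out <- dplyr::mutate(tibble::as_tibble(angles), label = label)
  dplyr::select(out, -"increment_deg")
}

#' Construct a CW-bias trace object
#'
#' A `cw_trace` is a tibble of 1-s (by default) bins with the ensemble CW
#' bias per bin, carrying the binning metadata needed by the template fit.
#' Bins in which no frame showed counted motion hold `NA` ("missing"), never
#' an imputed value.
#'
#' @param t_start Bin start times in seconds (half-open bins
#'   `[t_start, t_start + bin_width)`).
#' @param cw_bias Per-bin CW bias in `[0, 1]`, or `NA` for bins without
#'   counted motion.
#' @param bin_width Bin width in seconds.
#' @param stimulus_time Time of the attractant exchange, seconds.
#' @param n_cells Number of cells contributing to the ensemble.
#' @return A tibble of class `cw_trace` with columns `t_start`, `cw_bias`.
#' @export
cw_trace <- function(t_start, cw_bias, bin_width = 1, stimulus_time = 0,
                     n_cells = NA_integer_) {
  stopifnot(length(t_start) == length(cw_bias), bin_width > 0)
  duration <- max(t_start) + bin_width
  if (duration > 600 + 1e-9) {
    abort(sprintf("trace duration %.1f s exceeds the 600 s observation cap", duration))
  }
  if (stimulus_time < 0 || stimulus_time > duration) {
    abort("`stimulus_time` must lie within [0, duration]")
  }
  ok <- is.na(cw_bias) | (cw_bias >= 0 & cw_bias <= 1)
  if (!all(ok)) abort("`cw_bias` values must be in [0, 1] or NA")
  out <- tibble::tibble(t_start = as.numeric(t_start), cw_bias = as.numeric(cw_bias))
  structure(out,
            bin_width = bin_width,
            stimulus_time = stimulus_time,
            n_cells = as.integer(n_cells),
            class = c("cw_trace", class(out)))
}

#' @export
print.cw_trace <- function(x, ...) {
  cat(sprintf("<cw_trace> %d bins of %g s, stimulus at %g s, %s cells\n",
              nrow(x), attr(x, "bin_width"), attr(x, "stimulus_time"),
              ifelse(is.na(attr(x, "n_cells")), "?", attr(x, "n_cells"))))
  NextMethod()
}

#' Ensemble CW bias from per-cell direction labels
#'
#' Pools the frames of all cells into half-open time bins
#' `[k * bin_width, (k + 1) * bin_width)` and computes, per bin, the fraction
#' of CW frames among counted (CW + CCW) frames. `NONE` frames enter neither
#' numerator nor denominator; a bin with no counted frame at all is `NA`.
#'
#' @param directions A data frame of per-frame labels as returned by
#'   [classify_directions()]: columns `cell_id`, `frame`, `label`. An optional
#'   `t0` column gives each cell's recording offset in seconds (default 0);
#'   an optional `frame_interval` column is checked for consistency.
#' @param frame_interval Seconds per frame (default 0.01, i.e. 100 fps).
#' @param bin_width Bin width in seconds; must be a positive multiple of
#'   `frame_interval`.
#' @param stimulus_time Time of the chemical stimulus in seconds.
#' @return A [cw_trace()].
#' @export
ensemble_cw_bias <- function(directions, frame_interval = 0.01, bin_width = 1,
                             stimulus_time = 0) {
  stopifnot(is.data.frame(directions))
  req <- c("cell_id", "frame", "label")
  missing_cols <- setdiff(req, names(directions))
  if (length(missing_cols) > 0) {
    abort(paste0("`directions` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(directions) == 0) abort("at least one cell with one frame is required")
  if ("frame_interval" %in% names(directions)) {
    fis <- unique(directions$frame_interval)
    if (length(fis) > 1) {
      abort(sprintf("cells disagree on frame_interval: %g vs %g", fis[1], fis[2]))
    }
    if (abs(fis[1] - frame_interval) > 1e-12) frame_interval <- fis[1]
  }
  ratio <- bin_width / frame_interval
  if (bin_width <= 0 || abs(ratio - round(ratio)) > 1e-6) {
    abort("`bin_width` must be a positive multiple of `frame_interval`")
  }
  if (is.factor(directions$label)) {
    # factor fast path: remap levels once instead of matching
    # millions of strings
    lev_map <- match(levels(directions$label), c("CW", "CCW", "NONE"))
    if (anyNA(lev_map)) abort("labels must be one of CW, CCW, NONE")
    lab <- lev_map[as.integer(directions$label)]
  } else {
    lab <- match(directions$label, c("CW", "CCW", "NONE"))
    if (anyNA(lab)) abort("labels must be one of CW, CCW, NONE")
  }

  t0 <- if ("t0" %in% names(directions)) directions$t0 else 0
  # frame k (1-based) starts at t0 + (k-1) * frame_interval
  t_frame <- t0 + (directions$frame - 1) * frame_interval
  bin <- as.integer(floor(t_frame / bin_width + 1e-9))
  counted <- lab != 3L
  n_bins <- max(bin) + 1L
  cw <- tabulate(bin[lab == 1L] + 1L, nbins = n_bins)
  tot <- tabulate(bin[counted] + 1L, nbins = n_bins)
  bias <- ifelse(tot > 0, cw / tot, NA_real_)
  cw_trace(t_start = (seq_len(n_bins) - 1) * bin_width, cw_bias = bias,
           bin_width = bin_width, stimulus_time = stimulus_time,
           n_cells = length(unique(directions$cell_id)))
}

#' @rdname ensemble_cw_bias
#' @param x A `cw_trace`.
#' @param ... Unused.
#' @export
autoplot.cw_trace <- function(x, ...) {
  ggplot2::ggplot(tibble::as_tibble(x),
                  ggplot2::aes(x = .data$t_start, y = .data$cw_bias)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(x, "stimulus_time"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (s)", y = "CW bias") +
    ggplot2::ylim(0, 1)
}
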