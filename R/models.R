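#' Learn per-chemical dose-response model functions
#'
#' For every chemical `s` and index `i`, fits the model function
#' `f(x | s, i)` describing how index `i` depends on concentration `x`, by
#' ordinary least squares on a polynomial basis in `u = log10(x / 1 mM)`
#' (degree 1 by default, degree 2 optional). The residual scale
#' `sigma[s, i]` is the degrees-of-freedom-corrected residual SD, floored at
#' `sigma_floor_frac` times the SD of index `i` over the whole training set
#' (and at 1e-6) so that a chemical with near-constant training values never
#' collapses to a delta-function likelihood.
#'
#' @param training A data frame of labelled characteristic vectors
#'   (columns `y1`..`y15`, `label`, `concentration_mM` with all
#'   concentrations > 0), e.g. from [simulate_training_set()] or
#'   [read_vectors_csv()].
#' @param basis `"linear"` or `"quadratic"`: polynomial degree in
#'   `log10(x)`.
#' @param sigma_floor_frac Floor on `sigma[s, i]` as a fraction of the
#'   across-training SD of index `i`. Default 0.05.
#' @return An object of class `model_set`: the ordered chemical labels, the
#'   basis configuration, and a tibble `functions` with one row per
#'   `(chemical, index)` holding coefficients `c0`, `c1`, `c2`, `sigma`,
#'   and the chemical's training concentration range `x_lo`, `x_hi` (mM).
#'   The Gaussian amplitude `A(s, i) = 1 / (sqrt(2 * pi) * sigma)` is implied.
#' @export
fit_model_functions <- function(training, basis = c("linear", "quadratic"),
                                sigma_floor_frac = 0.05) {
  basis <- match.arg(basis)
  validate_vectors(training)
  if (!"concentration_mM" %in% names(training)) {
    abort("training vectors need a `concentration_mM` column")
  }
  x <- training$concentration_mM
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("all training concentrations must be finite and > 0")
  }
  chemicals <- unique(training$label)
  p <- if (basis == "linear") 2L else 3L
  for (s in chemicals) {
    n_conc <- dplyr::n_distinct(x[training$label == s])
    if (n_conc < p + 1L) {
      abort(sprintf("chemical %s has %d distinct concentrations; %d required for the %s basis",
                    s, n_conc, p + 1L, basis))
    }
  }
  floors <- pmax(sigma_floor_frac * apply(as.matrix(training[paste0("y", 1:15)]),
                                          2, stats::sd),
                 1e-6)
  rows <- purrr::map(chemicals, function(s) {
    sub <- training[training$label == s, ]
    u <- log10(sub$concentration_mM)
    X <- if (basis == "linear") cbind(1, u) else cbind(1, u, u^2)
    # one multi-response OLS covers all 15 indices at once
    fit <- stats::lm.fit(X, as.matrix(sub[paste0("y", 1:15)]))
    cf <- unname(fit$coefficients)
    dof <- nrow(sub) - p
    rsd <- if (dof > 0) sqrt(colSums(as.matrix(fit$residuals)^2) / dof) else rep(0, 15)
    tibble::tibble(chemical = s, index = 1:15,
                   c0 = unname(cf[1, ]), c1 = unname(cf[2, ]),
                   c2 = if (basis == "quadratic") unname(cf[3, ]) else NA_real_,
                   sigma = unname(pmax(rsd, floors)),
                   x_lo = min(sub$concentration_mM),
                   x_hi = max(sub$concentration_mM))
  }) |> dplyr::bind_rows()
  structure(list(chemicals = chemicals, basis = basis,
                 sigma_floor_frac = sigma_floor_frac,
                 functions = rows, training = tibble::as_tibble(training)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d chemicals (%s), %s basis in log10(mM)\n",
              length(x$chemicals), paste(x$chemicals, collapse = ", "),
              x$basis))
  invisible(x)
}

#' @rdname fit_model_functions
#' @param x A `model_set`.
#' @param ... Unused.
#' @export
tidy.model_set <- function(x, ...) x$functions

#' @rdname fit_model_functions
#' @export
glance.model_set <- function(x, ...) {
  tibble::tibble(n_chemicals = length(x$chemicals), basis = x$basis,
                 n_training = nrow(x$training),
                 median_sigma = stats::median(x$functions$sigma))
}

#' Evaluate a model function at a concentration
#'
#' Evaluates the fitted basis expansion for `(chemical, index)` at
#' `log10(x)`. Concentrations outside the chemical's training range are
#' evaluated by extension of the polynomial; the result then carries the
#' attribute `extrapolated = TRUE`.
#'
#' @param models A `model_set` from [fit_model_functions()].
#' @param chemical Chemical label.
#' @param index Index number in 1..15.
#' @param x Concentration in mM (> 0); vectorised.
#' @return Predicted index value(s), with an `extrapolated` attribute.
#' @export
predict_index <- function(models, chemical, index, x) {
  stopifnot(inherits(models, "model_set"))
  if (any(x <= 0)) abort("concentration must be > 0")
  row <- models$functions[models$functions$chemical == chemical &
                            models$functions$index == index, ]
  if (nrow(row) != 1) {
    abort(sprintf("no model function for chemical %s, index %s", chemical, index))
  }
  u <- log10(x)
  val <- row$c0 + row$c1 * u
  if (!is.na(row$c2)) val <- val + row$c2 * u^2
  attr(val, "extrapolated") <- any(x < row$x_lo | x > row$x_hi)
  val
}

# Internal: coefficient matrices and sigmas for one chemical, for fast
# evaluation across a concentration grid. Returns list(pred_fun(u) -> matrix
# [length(u) x 15], sigma[15], x_lo, x_hi).
model_eval_set <- function(models, chemical) {
  fns <- models$functions[models$functions$chemical == chemical, ]
  fns <- fns[order(fns$index), ]
  list(
    predict = function(u) {
      X <- if (models$basis == "linear") cbind(1, u) else cbind(1, u, u^2)
      B <- if (models$basis == "linear") rbind(fns$c0, fns$c1) else rbind(fns$c0, fns$c1, fns$c2)
      X %*% B
    },
    sigma = fns$sigma,
    x_lo = fns$x_lo[1],
    x_hi = fns$x_hi[1])
}

#' @rdname fit_model_functions
#' @param indices Which indices to display in the dose-response plot.
#' @export
autoplot.model_set <- function(x, indices = c(1, 4), ...) {
  curves <- purrr::map(x$chemicals, function(s) {
    ev <- model_eval_set(x, s)
    u <- seq(log10(ev$x_lo), log10(ev$x_hi), length.out = 80)
    pred <- ev$predict(u)
    purrr::map(indices, function(i) {
      tibble::tibble(chemical = s, index = paste0("y", i),
                     concentration_mM = 10^u, value = pred[, i])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  pts <- x$training |>
    dplyr::select("label", "concentration_mM",
                  dplyr::all_of(paste0("y", indices))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("y", indices)),
                        names_to = "index", values_to = "value") |>
    dplyr::rename(chemical = "label")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$concentration_mM, y = .data$value,
                               colour = .data$chemical)) +
    ggplot2::geom_point(data = pts, alpha = 0.5, size = 1) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "concentration (mM)", y = "index value")
}
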