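log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Internal: pull the 15 index values out of a one-row data frame / named vector.
vector_y <- function(vector) {
  if (is.data.frame(vector)) {
    if (nrow(vector) != 1) abort("`vector` must be a single characteristic vector (one row)")
    y <- as.numeric(vector[1, paste0("y", 1:15)])
  } else {
    y <- as.numeric(vector[paste0("y", 1:15)])
  }
  if (length(y) != 15 || any(!is.finite(y))) {
    abort("a characteristic vector needs 15 finite index values y1..y15")
  }
  y
}

#' Posterior over chemical identity with concentration marginalised
#'
#' Implements the core inference: for each candidate chemical `s`, the
#' evidence is the integral over concentration of the product of Gaussian
#' likelihood factors, one per index,
#' `A(s,i) * exp(-(y_i - f(x|s,i))^2 / (2 * sigma[s,i]^2))`,
#' computed by trapezoidal quadrature on a uniform grid in
#' `u = log10(x)` spanning the chemical's training range padded by `pad`
#' log-units, with all products accumulated in the log domain. Posterior
#' probabilities normalise the evidences under a uniform prior over
#' chemicals.
#'
#' @param vector A single characteristic vector: one row of a vectors tibble
#'   or a named numeric with elements `y1`..`y15`.
#' @param models A `model_set` from [fit_model_functions()].
#' @param grid_points Number of quadrature nodes per chemical (default 201).
#' @param pad Padding of the integration range beyond the training range, in
#'   log10 units (default 0.5).
#' @param amplitude_mode `"gaussian"` uses `A(s,i) = 1/(sqrt(2*pi)*sigma)`
#'   so each factor is a proper density and chemicals with different sigma
#'   compare fairly; `"unit"` sets every amplitude to 1.
#' @param prior_measure Prior over the unknown concentration:
#'   `"log_uniform"` (uniform in `log10 x`, the default) or
#'   `"linear_uniform"` (uniform in `x` over the padded range).
#' @param active_indices Which of the 15 indices enter the likelihood
#'   product (default all).
#' @return An object of class `chem_posterior`: probabilities over
#'   chemicals (sum to 1), per-chemical log-evidence, MAP concentration per
#'   chemical, the argmax `decision` (ties broken by model order and
#'   flagged), and the per-chemical concentration profile
#'   (grid of `x` vs log-integrand).
#' @export
posterior <- function(vector, models, grid_points = 201, pad = 0.5,
                      amplitude_mode = c("gaussian", "unit"),
                      prior_measure = c("log_uniform", "linear_uniform"),
                      active_indices = 1:15) {
  amplitude_mode <- match.arg(amplitude_mode)
  prior_measure <- match.arg(prior_measure)
  stopifnot(inherits(models, "model_set"))
  y <- vector_y(vector)
  if (length(active_indices) == 0) abort("`active_indices` must be non-empty")
  if (grid_points < 3) abort("`grid_points` must be at least 3")

  per_chem <- purrr::map(models$chemicals, function(s) {
    ev <- model_eval_set(models, s)
    u_lo <- log10(ev$x_lo) - pad
    u_hi <- log10(ev$x_hi) + pad
    u <- seq(u_lo, u_hi, length.out = grid_points)
    du <- u[2] - u[1]
    pred <- ev$predict(u)                      # grid x 15
    sig <- ev$sigma
    ll <- rep(0, grid_points)
    for (i in active_indices) {
      z <- (y[i] - pred[, i]) / sig[i]
      ll <- ll - 0.5 * z^2
      if (amplitude_mode == "gaussian") ll <- ll - log(sqrt(2 * pi) * sig[i])
    }
    log_prior <- if (prior_measure == "log_uniform") {
      rep(-log(u_hi - u_lo), grid_points)
    } else {
      x_lo <- 10^u_lo; x_hi <- 10^u_hi
      -log(x_hi - x_lo) + u * log(10) + log(log(10))
    }
    log_integrand <- ll + log_prior
    log_w <- log(du) + log(c(0.5, rep(1, grid_points - 2), 0.5))
    log_ev <- log_sum_exp(log_w + log_integrand)
    i_map <- which.max(log_integrand)
    flat <- diff(range(log_integrand)) < 1e-9
    list(log_evidence = log_ev,
         map_concentration = 10^u[i_map],
         non_identifiable = flat,
         profile = tibble::tibble(chemical = s, concentration_mM = 10^u,
                                  log_integrand = log_integrand))
  })
  log_ev <- purrr::map_dbl(per_chem, "log_evidence")
  names(log_ev) <- models$chemicals
  if (all(!is.finite(log_ev))) {
    abort(paste0("all evidences underflow; per-chemical log-evidence: ",
                 paste(sprintf("%s=%g", models$chemicals, log_ev), collapse = ", ")))
  }
  probs <- exp(log_ev - log_sum_exp(log_ev))
  probs <- probs / sum(probs)
  best <- max(probs)
  ties <- which(probs >= best - 1e-12)
  structure(list(
    chemicals = models$chemicals,
    probabilities = setNames(probs, models$chemicals),
    log_evidence = log_ev,
    map_concentration = setNames(purrr::map_dbl(per_chem, "map_concentration"),
                                 models$chemicals),
    non_identifiable = setNames(purrr::map_lgl(per_chem, "non_identifiable"),
                                models$chemicals),
    decision = models$chemicals[ties[1]],
    tie = length(ties) > 1,
    profiles = dplyr::bind_rows(purrr::map(per_chem, "profile")),
    settings = list(grid_points = grid_points, pad = pad,
                    amplitude_mode = amplitude_mode,
                    prior_measure = prior_measure,
                    active_indices = active_indices)),
    class = "chem_posterior")
}

#' @export
print.chem_posterior <- function(x, ...) {
  cat(sprintf("<chem_posterior> decision: %s%s\n", x$decision,
              if (x$tie) " (tie)" else ""))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' @rdname posterior
#' @param x A `chem_posterior`.
#' @param ... Unused.
#' @export
tidy.chem_posterior <- function(x, ...) {
  tibble::tibble(chemical = x$chemicals,
                 probability = unname(x$probabilities[x$chemicals]),
                 log_evidence = unname(x$log_evidence[x$chemicals]),
                 map_concentration_mM = unname(x$map_concentration[x$chemicals]))
}

#' @rdname posterior
#' @export
glance.chem_posterior <- function(x, ...) {
  tibble::tibble(decision = x$decision,
                 probability = unname(x$probabilities[x$decision]),
                 tie = x$tie,
                 map_concentration_mM = unname(x$map_concentration[x$decision]))
}

#' @rdname posterior
#' @export
autoplot.chem_posterior <- function(x, ...) {
  ggplot2::ggplot(x$profiles,
                  ggplot2::aes(x = .data$concentration_mM,
                               y = .data$log_integrand,
                               colour = .data$chemical)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (mM)", y = "log integrand")
}

#' Classify a characteristic vector
#'
#' The chemical with maximal posterior probability; ties are broken by model
#' order (and flagged on the underlying [posterior()] object).
#'
#' @inheritParams posterior
#' @param ... Passed to [posterior()].
#' @return A single chemical label.
#' @export
classify <- function(vector, models, ...) {
  posterior(vector, models, ...)$decision
}

#' Classify every row of a vectors tibble
#'
#' @param vectors A data frame of characteristic vectors (columns
#'   `y1`..`y15`, optionally `vector_id`).
#' @inheritParams posterior
#' @param ... Passed to [posterior()].
#' @return A tibble with one row per input: `vector_id`, one
#'   `prob_<chemical>` column per chemical, `decision`,
#'   `map_concentration_mM` (MAP under the decided chemical).
#' @export
classify_vectors <- function(vectors, models, ...) {
  ids <- if ("vector_id" %in% names(vectors)) vectors$vector_id else seq_len(nrow(vectors))
  purrr::map(seq_len(nrow(vectors)), function(j) {
    post <- posterior(vectors[j, ], models, ...)
    row <- tibble::as_tibble(as.list(setNames(
      post$probabilities, paste0("prob_", names(post$probabilities)))))
    dplyr::bind_cols(tibble::tibble(vector_id = ids[j]), row,
                     tibble::tibble(decision = post$decision,
                                    map_concentration_mM =
                                      unname(post$map_concentration[post$decision])))
  }) |> dplyr::bind_rows()
}

#' Maximum a posteriori concentration under a given chemical
#'
#' The grid argmax of the per-chemical integrand from [posterior()]. When
#' the chemical's model functions carry no concentration dependence the
#' profile is flat; the result then carries attribute
#' `non_identifiable = TRUE`.
#'
#' @inheritParams posterior
#' @param chemical Chemical label, present in `models`.
#' @param ... Passed to [posterior()].
#' @return Concentration in mM.
#' @export
estimate_concentration <- function(vector, models, chemical, ...) {
  if (!chemical %in% models$chemicals) {
    abort(sprintf("unknown chemical: %s", chemical))
  }
  post <- posterior(vector, models, ...)
  out <- unname(post$map_concentration[chemical])
  attr(out, "non_identifiable") <- unname(post$non_identifiable[chemical])
  attr(out, "log_evidence") <- unname(post$log_evidence[chemical])
  out
}
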