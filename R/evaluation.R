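# --- minimal non-negative big-integer arithmetic (base 1e7 digit vectors) ---
# Needed because binomial tail terms like C(100, j) * 5^(100-j) far exceed
# double precision, and the tail must be summed exactly before the final
# division. Little-endian digit vectors of doubles; every intermediate
# product stays below 2^53.

big_norm <- function(a) {
  base <- 1e7
  carry <- 0
  i <- 1
  while (i <= length(a) || carry > 0) {
    if (i > length(a)) a[i] <- 0
    v <- a[i] + carry
    a[i] <- v %% base
    carry <- (v - a[i]) / base
    i <- i + 1
  }
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

# m must be a non-negative integer < 2^26 so digit * m < 2^53
big_mul_small <- function(a, m) {
  if (m == 0) return(0)
  big_norm(a * m)
}

# exact division by small integer d (caller guarantees divisibility)
big_div_small <- function(a, d) {
  base <- 1e7
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * base + a[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  if (rem != 0) abort("internal: inexact big-integer division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

# mantissa in [1, 10) and decimal exponent of a big integer
big_mantissa_exp <- function(a) {
  n <- length(a)
  top <- 0
  for (i in seq(n, max(1, n - 3))) top <- top * 1e7 + a[i]
  e_top <- floor(log10(top))
  list(mantissa = top / 10^e_top, exp = e_top + 7 * (max(1, n - 3) - 1))
}

#' Theoretical accuracy of random selection
#'
#' A baseline classifier guessing uniformly among `n_chem` candidate
#' chemicals is correct with probability `1 / n_chem`.
#'
#' @param n_chem Number of chemicals in the tested group (>= 1).
#' @return `1 / n_chem`.
#' @examples
#' rs_rate(6)  # ~0.17
#' @export
rs_rate <- function(n_chem) {
  if (length(n_chem) != 1 || !is.finite(n_chem) || n_chem < 1) {
    abort("`n_chem` must be a single integer >= 1")
  }
  1 / n_chem
}

#' Monte-Carlo standard deviation of the random-selection accuracy
#'
#' Empirical SD, across `reps` replicates, of the accuracy a uniform random
#' guesser attains on `n_total` samples. (The closed-form value is
#' `sqrt(p * (1 - p) / n_total)` with `p = 1 / n_chem`; this routine
#' estimates it numerically, as the definition is stated.)
#'
#' @param n_total Number of classified samples.
#' @param n_chem Number of candidate chemicals.
#' @param reps Number of Monte-Carlo replicates (>= 1000).
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored).
#' @return The Monte-Carlo SD of the accuracy, as a fraction.
#' @export
rs_sd_mc <- function(n_total, n_chem, reps = 10000, seed = NULL) {
  if (reps < 1000) abort("`reps` must be at least 1000")
  if (n_total < 1 || n_chem < 1) abort("`n_total` and `n_chem` must be >= 1")
  if (n_chem == 1) return(0)
  run <- function() stats::sd(stats::rbinom(reps, n_total, 1 / n_chem) / n_total)
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

# evaluate `expr` under a local seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Exact binomial tail probability of a random-selection score
#'
#' The probability that uniform random guessing among `n_chem` chemicals
#' scores at least as well as an observed accuracy:
#' `P(X >= ceiling(accuracy * n_total))` for
#' `X ~ Binomial(n_total, 1 / n_chem)`. The tail is summed in exact integer
#' arithmetic (the terms `choose(n, j) * (n_chem - 1)^(n - j)` overflow
#' doubles long before the probabilities underflow), and only the final
#' ratio is converted to double.
#'
#' @param accuracy Observed accuracy in `[0, 1]`.
#' @param n_total Number of classified samples.
#' @param n_chem Number of candidate chemicals.
#' @return The tail probability as a double.
#' @examples
#' rs_tail_probability(58 / 64, 64, 2)  # 83278001 / 2^64
#' @export
rs_tail_probability <- function(accuracy, n_total, n_chem) {
  if (accuracy < 0 || accuracy > 1) abort("`accuracy` must be in [0, 1]")
  if (n_total < 1 || n_chem < 1) abort("`n_total` and `n_chem` must be >= 1")
  n <- as.integer(round(n_total))
  k <- as.integer(ceiling(accuracy * n - 1e-9))
  if (k <= 0) return(1)
  q <- n_chem - 1
  if (q == 0) return(1)  # guessing among one chemical always succeeds
  # descending recurrence over terms T_j = choose(n, j) * q^(n - j):
  # T_n = 1;  T_{j-1} = T_j * q * j / (n - j + 1)  (division exact)
  term <- 1
  total <- 1  # T_n
  if (k < n) {
    for (j in seq(n, k + 1, by = -1)) {
      term <- big_div_small(big_mul_small(term, q * j), n - j + 1)
      total <- big_add(total, term)
    }
  }
  denom <- 1
  for (i in seq_len(n)) denom <- big_mul_small(denom, n_chem)
  ms <- big_mantissa_exp(total)
  md <- big_mantissa_exp(denom)
  (ms$mantissa / md$mantissa) * 10^(ms$exp - md$exp)
}

#' Decrease in self-information
#'
#' Information gained by the decipherment over random selection:
#' `log2(accuracy) - log2(accuracy_rs)`, in bits. Depends only on the ratio
#' of the two accuracies.
#'
#' @param accuracy Accuracy of the decipherment, in `(0, 1]`.
#' @param accuracy_rs Accuracy of random selection, in `(0, 1]`.
#' @return DSI in bits.
#' @examples
#' dsi(1, 0.5)        # 1 bit
#' dsi(0.43, 1 / 6)   # ~1.37 bits
#' @export
dsi <- function(accuracy, accuracy_rs) {
  if (any(c(accuracy, accuracy_rs) <= 0) || any(c(accuracy, accuracy_rs) > 1)) {
    abort("both accuracies must be in (0, 1] (log2 of 0 is undefined)")
  }
  log2(accuracy) - log2(accuracy_rs)
}

#' Enumerate all k-chemical groups
#'
#' All unordered size-`k` subsets of the chemical labels, in lexicographic
#' order of label positions.
#'
#' @param chemicals Character vector of labels.
#' @param k Group size, `1 <= k <= length(chemicals)`.
#' @return A list of character vectors.
#' @export
enumerate_groups <- function(chemicals, k) {
  n <- length(chemicals)
  if (k < 1 || k > n) abort(sprintf("`k` must be in 1..%d", n))
  combn(chemicals, k, simplify = FALSE)
}

#' Leave-one-out decipherment accuracy for a chemical group
#'
#' For every training vector in the group, refits the model functions on all
#' remaining vectors (a full refit, not a re-normalisation) and classifies
#' the held-out vector; accuracy is the fraction classified as their true
#' label. The report also carries the random-selection baseline, its
#' Monte-Carlo SD, the exact tail probability of the observed accuracy under
#' random selection, and the DSI.
#'
#' @param vectors A data frame of labelled characteristic vectors.
#' @param group Character vector of labels to evaluate (default: all labels
#'   present).
#' @param basis Passed to [fit_model_functions()].
#' @param rs_reps,rs_seed Monte-Carlo settings for the baseline SD.
#' @param ... Passed to [posterior()].
#' @return An object of class `evaluation_report` with elements `group`,
#'   `n_per_chemical`, `accuracy`, `rs_rate`, `rs_sd`, `rs_tail_prob`,
#'   `dsi` (bits, `NA` if accuracy is 0), `degenerate` (single-chemical
#'   group) and the `per_sample` tibble of (true, predicted) pairs.
#' @export
loo_accuracy <- function(vectors, group = NULL, basis = "linear",
                         rs_reps = 10000, rs_seed = 20260101, ...) {
  validate_vectors(vectors)
  if (is.null(group)) group <- unique(vectors$label)
  missing_chem <- setdiff(group, vectors$label)
  if (length(missing_chem) > 0) {
    abort(paste0("no training vectors for: ", paste(missing_chem, collapse = ", ")))
  }
  sub <- vectors[vectors$label %in% group, , drop = FALSE]
  counts <- table(sub$label)
  low <- names(counts)[counts < 4]
  if (length(low) > 0) {
    abort(paste0("chemicals with fewer than 4 records: ", paste(low, collapse = ", ")))
  }
  preds <- purrr::map_chr(seq_len(nrow(sub)), function(j) {
    models <- fit_model_functions(sub[-j, , drop = FALSE], basis = basis)
    classify(sub[j, ], models, ...)
  })
  per_sample <- tibble::tibble(true = sub$label, predicted = preds,
                               correct = sub$label == preds)
  acc <- mean(per_sample$correct)
  n_chem <- length(group)
  rate <- rs_rate(n_chem)
  structure(list(
    group = group,
    n_per_chemical = as.list(counts),
    accuracy = acc,
    rs_rate = rate,
    rs_sd = rs_sd_mc(nrow(sub), n_chem, reps = rs_reps, seed = rs_seed),
    rs_tail_prob = rs_tail_probability(acc, nrow(sub), n_chem),
    dsi = if (acc > 0) dsi(acc, rate) else NA_real_,
    degenerate = n_chem == 1,
    per_sample = per_sample),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> group {%s}: accuracy %.3f (RS %.3f, DSI %s bits)%s\n",
              paste(x$group, collapse = ", "), x$accuracy, x$rs_rate,
              ifelse(is.na(x$dsi), "NA", sprintf("%.2f", x$dsi)),
              if (x$degenerate) " [degenerate single-chemical group]" else ""))
  invisible(x)
}

#' @rdname loo_accuracy
#' @param x An `evaluation_report`.
#' @export
tidy.evaluation_report <- function(x, ...) x$per_sample

#' @rdname loo_accuracy
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(group = paste(x$group, collapse = "+"),
                 n_chem = length(x$group),
                 n_total = nrow(x$per_sample),
                 accuracy = x$accuracy,
                 rs_rate = x$rs_rate,
                 rs_sd = x$rs_sd,
                 rs_tail_prob = x$rs_tail_prob,
                 dsi = x$dsi)
}

#' Accuracy spectrum over all k-chemical groups
#'
#' Runs [loo_accuracy()] on every size-`k` subset of the chemicals present
#' in `vectors`. For `k = 2` the pairwise accuracies are also arranged as a
#' symmetric matrix (diagonal undefined).
#'
#' @inheritParams loo_accuracy
#' @param k Group size.
#' @return An object of class `accuracy_spectrum`: the per-group reports,
#'   a per-group summary tibble, the pairwise `matrix` (for `k = 2`, else
#'   `NULL`), and aggregate `mean_accuracy` / `mean_dsi`.
#' @export
accuracy_spectrum <- function(vectors, k, ...) {
  chems <- unique(vectors$label)
  groups <- enumerate_groups(chems, k)
  reports <- purrr::map(groups, function(g) loo_accuracy(vectors, group = g, ...))
  summary <- dplyr::bind_rows(purrr::map(reports, glance))
  mat <- NULL
  if (k == 2) {
    mat <- matrix(NA_real_, length(chems), length(chems),
                  dimnames = list(chems, chems))
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      mat[g[1], g[2]] <- mat[g[2], g[1]] <- reports[[j]]$accuracy
    }
  }
  structure(list(k = k, chemicals = chems, reports = reports,
                 summary = summary, matrix = mat,
                 mean_accuracy = mean(summary$accuracy),
                 mean_dsi = mean(summary$dsi)),
            class = "accuracy_spectrum")
}

#' @export
print.accuracy_spectrum <- function(x, ...) {
  cat(sprintf("<accuracy_spectrum> k=%d: %d groups, mean accuracy %.3f, mean DSI %.2f bits\n",
              x$k, nrow(x$summary), x$mean_accuracy, x$mean_dsi))
  invisible(x)
}

#' @rdname accuracy_spectrum
#' @param x An `accuracy_spectrum`.
#' @export
tidy.accuracy_spectrum <- function(x, ...) x$summary

#' @rdname accuracy_spectrum
#' @export
glance.accuracy_spectrum <- function(x, ...) {
  tibble::tibble(k = x$k, n_groups = nrow(x$summary),
                 mean_accuracy = x$mean_accuracy, mean_dsi = x$mean_dsi)
}

#' @rdname accuracy_spectrum
#' @export
autoplot.accuracy_spectrum <- function(x, ...) {
  if (!is.null(x$matrix)) {
    df <- tibble::as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE))
    names(df) <- c("chemical_a", "chemical_b", "accuracy")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$chemical_a, y = .data$chemical_b,
                                     fill = .data$accuracy)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
      ggplot2::labs(x = NULL, y = NULL, fill = "LOO accuracy")
  } else {
    df <- x$summary
    df$group_id <- seq_len(nrow(df))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$group_id, y = .data$accuracy)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 1 / x$k, linetype = "dashed") +
      ggplot2::labs(x = "group", y = "LOO accuracy")
  }
}
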