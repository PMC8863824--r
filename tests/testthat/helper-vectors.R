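# Vector-level synthetic training sets: characteristic vectors drawn
# directly around per-chemical dose-response lines, bypassing the trace
# simulator. Used to exercise the model-fitting / classification /
# evaluation layers quickly; the trace-level generator is tested end to end
# separately.
#
# Because the classifier marginalises the unknown concentration, chemicals
# that differ only by an intercept shift along a shared dose slope are NOT
# separable (a concentration shift explains the offset). Separation must
# come from features a concentration shift cannot mimic, so `sep` drives:
# a dose-slope difference on y4, and a shift of the concentration-
# independent final level y13. sep = 0 gives indistinguishable chemicals.
make_gaussian_vectors <- function(chemicals, n_per = 32, seed = 7, sep = 30,
                                  u_range = c(-1, 1)) {
  set.seed(seed)
  purrr::map(seq_along(chemicals), function(j) {
    u <- runif(n_per, u_range[1], u_range[2])
    tibble::tibble(
      y1 = 100 + sep * j + 40 * u + rnorm(n_per, 0, 8),
      y2 = 0.2 + rnorm(n_per, 0, 0.02),
      y3 = 0.004 + rnorm(n_per, 0, 0.001),
      y4 = 60 + (10 + 0.3 * sep * j) * u + rnorm(n_per, 0, 5),
      y5 = 0.1 + rnorm(n_per, 0, 0.02),
      y6 = 0.002 + rnorm(n_per, 0, 0.001),
      y7 = pmax(0, 50 + rnorm(n_per, 0, 8)),
      y8 = 0.05 + rnorm(n_per, 0, 0.02),
      y9 = 0.001 + rnorm(n_per, 0, 0.001),
      y10 = pmax(0, 40 + rnorm(n_per, 0, 8)),
      y11 = pmin(1, pmax(0, 0.3 + rnorm(n_per, 0, 0.03))),
      y12 = pmin(1, pmax(0, 0.05 + rnorm(n_per, 0, 0.02))),
      y13 = pmin(1, pmax(0, 0.3 + 0.003 * sep * j + rnorm(n_per, 0, 0.03))),
      y15 = abs(rnorm(n_per, 0.03, 0.005)),
      label = chemicals[j],
      concentration_mM = 10^u) |>
      dplyr::mutate(y14 = y4 + y7 + y10, .before = "y15")
  }) |>
    dplyr::bind_rows()
}

# A small model set with two chemicals whose curves are far apart relative
# to sigma, built from noiseless-plus-floor training data.
make_separated_models <- function(offset = 100) {
  u <- rep(c(-1, 0, 1), each = 2)
  base <- function(shift) {
    tibble::tibble(
      y1 = 100 + shift + 40 * u, y2 = 0.2, y3 = 0.004,
      y4 = 60 + shift / 10 + 10 * u, y5 = 0.1, y6 = 0.002, y7 = 50,
      y8 = 0.05, y9 = 0.001, y10 = 40, y11 = 0.3, y12 = 0.05, y13 = 0.3,
      y14 = 150 + shift / 10 + 10 * u, y15 = 0.03,
      concentration_mM = 10^u)
  }
  train <- dplyr::bind_rows(
    dplyr::mutate(base(0), label = "A"),
    dplyr::mutate(base(offset), label = "B"))
  fit_model_functions(train)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(names(a), names(b))
  for (nm in names(a)) {
    if (is.numeric(a[[nm]])) expect_equal(a[[nm]], b[[nm]], tolerance = tol)
    else expect_equal(a[[nm]], b[[nm]])
  }
}
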