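test_that("identical model functions give a uniform posterior and a flagged tie", {
  train <- make_gaussian_vectors("A", n_per = 8, seed = 3)
  both <- dplyr::bind_rows(train, dplyr::mutate(train, label = "B"))
  models <- fit_model_functions(both)
  post <- posterior(both[1, ], models)
  expect_equal(unname(post$probabilities), c(0.5, 0.5), tolerance = 1e-12)
  expect_true(post$tie)
  expect_equal(classify(both[1, ], models), "A")  # first label wins ties
})

test_that("an observation consistent with one chemical only is assigned to it", {
  models <- make_separated_models(offset = 100)  # >20 sigma apart on y1
  obs <- models$training[models$training$label == "A" &
                           abs(models$training$concentration_mM - 1) < 1e-9, ][1, ]
  post <- posterior(obs, models)
  expect_gt(post$probabilities[["A"]], 0.999)
  expect_equal(classify(obs, models), "A")
  # posterior probabilities always sum to one
  expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
})

test_that("posterior normalisation holds across random observations", {
  train <- make_gaussian_vectors(c("A", "B", "C"), n_per = 10, seed = 9)
  models <- fit_model_functions(train)
  set.seed(42)
  for (j in sample(nrow(train), 8)) {
    post <- posterior(train[j, ], models)
    expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
    expect_equal(post$decision,
                 names(which.max(post$probabilities)))
  }
})

test_that("relabelling chemicals permutes probabilities (label equivariance)", {
  train <- make_gaussian_vectors(c("A", "B", "C"), n_per = 10, seed = 9)
  obs <- train[5, ]
  m1 <- fit_model_functions(train)
  # reverse the chemical order by reordering rows
  train_rev <- dplyr::arrange(train, dplyr::desc(label))
  m2 <- fit_model_functions(train_rev)
  expect_equal(m2$chemicals, rev(m1$chemicals))
  p1 <- posterior(obs, m1)$probabilities
  p2 <- posterior(obs, m2)$probabilities
  expect_equal(p2[names(p1)], p1, tolerance = 1e-9)
})

test_that("the quadrature is converged at the default grid", {
  models <- make_separated_models(offset = 20)
  # observation at the centre of the training range
  obs <- models$training[models$training$label == "A" &
                           abs(models$training$concentration_mM - 1) < 1e-9, ][1, ]
  p_default <- posterior(obs, models, grid_points = 201)$probabilities
  p_halved <- posterior(obs, models, grid_points = 401)$probabilities
  p_brute <- posterior(obs, models, grid_points = 20001)$probabilities
  expect_lt(max(abs(p_default - p_halved)), 1e-6)
  expect_lt(max(abs(p_default - p_brute)), 1e-6)
})

test_that("uninformative extra indices leave the posterior essentially unchanged", {
  # indices 2..15 carry no chemical or concentration information here
  u <- rep(c(-1, 0, 1), each = 2)
  base <- tibble::tibble(
    y1 = 100 + 40 * u, y2 = 0.2, y3 = 0.004, y4 = 60, y5 = 0.1, y6 = 0.002,
    y7 = 50, y8 = 0.05, y9 = 0.001, y10 = 40, y11 = 0.3, y12 = 0.05,
    y13 = 0.3, y14 = 150, y15 = 0.03, concentration_mM = 10^u)
  train <- dplyr::bind_rows(
    dplyr::mutate(base, label = "A"),
    dplyr::mutate(base, y1 = y1 + 30, label = "B"))
  models <- fit_model_functions(train)
  obs <- train[2, ]
  p_all <- posterior(obs, models)$probabilities
  p_sub <- posterior(obs, models, active_indices = 1)$probabilities
  expect_lt(max(abs(p_all - p_sub)), 1e-5)
})

test_that("concentration is recovered for a noiseless observation", {
  models <- make_separated_models(offset = 100)
  obs <- models$training[models$training$label == "A" &
                           abs(models$training$concentration_mM - 1) < 1e-9, ][1, ]
  xhat <- estimate_concentration(obs, models, "A")
  # within one grid step (in log10) of the generating concentration
  step <- 3 / 200  # padded range is 3 decades over 201 points
  expect_lt(abs(log10(xhat)), step + 1e-12)
  expect_false(attr(xhat, "non_identifiable"))
  expect_error(estimate_concentration(obs, models, "Z"), "unknown chemical")
})

test_that("flat model functions flag a non-identifiable concentration", {
  u <- rep(c(-1, 0, 1), each = 2)
  base <- tibble::tibble(
    y1 = 100, y2 = 0.2, y3 = 0.004, y4 = 60, y5 = 0.1, y6 = 0.002, y7 = 50,
    y8 = 0.05, y9 = 0.001, y10 = 40, y11 = 0.3, y12 = 0.05, y13 = 0.3,
    y14 = 150, y15 = 0.03, concentration_mM = 10^u, label = "A")
  models <- fit_model_functions(base)
  xhat <- estimate_concentration(base[1, ], models, "A")
  expect_true(attr(xhat, "non_identifiable"))
  # a far-away observation still returns a MAP, with low evidence reported
  far <- dplyr::mutate(base[1, ], y1 = y1 + 1000)
  xfar <- estimate_concentration(far, models, "A")
  expect_true(is.finite(xfar))
  expect_lt(attr(xfar, "log_evidence"), attr(xhat, "log_evidence"))
})

test_that("a single-chemical model set returns probability one", {
  train <- make_gaussian_vectors("A", n_per = 8, seed = 3)
  models <- fit_model_functions(train)
  post <- posterior(train[1, ], models)
  expect_equal(unname(post$probabilities), 1)
  expect_equal(post$decision, "A")
})

test_that("classify_vectors reports one posterior row per input", {
  train <- make_gaussian_vectors(c("A", "B"), n_per = 8, seed = 3)
  models <- fit_model_functions(train)
  res <- classify_vectors(train[1:5, ], models)
  expect_equal(nrow(res), 5)
  expect_true(all(c("prob_A", "prob_B", "decision", "map_concentration_mM")
                  %in% names(res)))
  expect_equal(res$prob_A + res$prob_B, rep(1, 5), tolerance = 1e-12)
})
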