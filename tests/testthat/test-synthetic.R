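fast_cfg <- function(...) {
  args <- utils::modifyList(list(duration = 300, stimulus_time = 60,
                                 n_cells = 10, seed = 5), list(...))
  do.call(sim_config, args)
}

test_that("cell simulation is deterministic and respects the forced-CCW window", {
  pr <- chemical_profile("det", tau0 = 100, beta = 0, recovery_total = 80,
                         cell_cv = 0, conc_range = c(0.01, 10))
  cfg <- fast_cfg()
  a <- simulate_cell(pr, 1, cfg, cell_seed = 99)
  b <- simulate_cell(pr, 1, cfg, cell_seed = 99)
  expect_identical(a, b)
  # with cell_cv = 0 and beta = 0 the window is exactly tau0 for any x
  for (x in c(0.05, 5)) {
    cell <- simulate_cell(pr, x, cfg, cell_seed = 7)
    t_frame <- (cell$frame - 1) * cfg$frame_interval
    win <- t_frame >= cfg$stimulus_time & t_frame < cfg$stimulus_time + 100
    expect_true(all(cell$label[win] %in% c("CCW", "NONE")))
  }
  expect_error(simulate_cell(pr, -1, cfg), "> 0")
})

test_that("sub-threshold doses leave the trace stationary across the stimulus", {
  # tau = 50 + 60 * log10(x) <= 0 at x = 0.01
  pr <- chemical_profile("weak", tau0 = 50, beta = 60, recovery_total = 100,
                         cell_cv = 0, conc_range = c(0.001, 10),
                         baseline_kappa = 1e5)
  cfg <- sim_config(duration = 400, stimulus_time = 200, n_cells = 30, seed = 8)
  tr <- simulate_ensemble(pr, 0.01, cfg)
  pre <- mean(tr$cw_bias[tr$t_start < 200], na.rm = TRUE)
  post <- mean(tr$cw_bias[tr$t_start >= 200], na.rm = TRUE)
  expect_lt(abs(pre - post), 0.03)
})

test_that("the excitation window drives ensemble bias to zero and baseline matches", {
  pr <- chemical_profile("strong", tau0 = 120, beta = 20,
                         recovery_total = 100, cell_cv = 0.1,
                         conc_range = c(0.01, 10), baseline_mean = 0.3)
  cfg <- sim_config(duration = 400, stimulus_time = 100, n_cells = 40, seed = 21)
  tr <- simulate_ensemble(pr, 1, cfg)
  tau <- 120  # at x = 1 mM
  win <- tr$t_start >= 100 & tr$t_start < 100 + tau * (1 - 2 * 0.1)
  expect_lte(mean(tr$cw_bias[win], na.rm = TRUE), 0.02)
  # pre-stimulus ensemble bias within 3 SE of the Beta mean
  pre_vals <- tr$cw_bias[tr$t_start < 100]
  se <- stats::sd(pre_vals, na.rm = TRUE) / sqrt(sum(!is.na(pre_vals)))
  expect_lt(abs(mean(pre_vals, na.rm = TRUE) - 0.3), 3 * se)
})

test_that("pre-stimulus ensemble bias carries no trend", {
  pr <- chemical_profile("flat2", tau0 = 0, beta = 0, recovery_total = 50,
                         cell_cv = 0)
  slopes <- purrr::map_dbl(1:5, function(s) {
    cfg <- sim_config(duration = 200, stimulus_time = 190, n_cells = 20,
                      seed = s)
    tr <- simulate_ensemble(pr, 1, cfg)
    unname(coef(lm(cw_bias ~ t_start, data = tr[tr$t_start < 190, ]))[2])
  })
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 3 * se)
})

test_that("a one-cell ensemble equals that cell's own binned bias", {
  pr <- chemical_profile("solo", tau0 = 60, beta = 10, recovery_total = 80,
                         conc_range = c(0.01, 10))
  cfg <- fast_cfg(n_cells = 1)
  tr <- simulate_ensemble(pr, 1, cfg, trace_id = 3L)
  cell <- simulate_cell(pr, 1, cfg, cell_seed = desiram:::derive_seed(5, 3L, 1L),
                        cell_id = "cell_1")
  own <- ensemble_cw_bias(cell, stimulus_time = cfg$stimulus_time)
  expect_equal(tr$cw_bias, own$cw_bias)
})

test_that("training-set generation is labelled, complete and reproducible", {
  prs <- list(
    chemical_profile("P1", tau0 = 60, beta = 25, recovery_total = 80,
                     conc_range = c(0.01, 10), cell_cv = 0.1),
    chemical_profile("P2", tau0 = 100, beta = 10, recovery_total = 120,
                     conc_range = c(0.01, 10), cell_cv = 0.1))
  names(prs) <- c("P1", "P2")
  cfg <- fast_cfg()
  conc <- c(0.1, 1, 5, 10)
  tr <- simulate_training_set(prs, conc, reps = 2, cfg = cfg)
  expect_equal(nrow(tr), 2 * 4 * 2)
  expect_equal(sort(unique(tr$label)), c("P1", "P2"))
  expect_equal(sort(unique(tr$concentration_mM)), conc)
  expect_silent(validate_vectors(tr))
  tr2 <- simulate_training_set(prs, conc, reps = 2, cfg = cfg)
  expect_identical(tr, tr2)
  expect_error(simulate_training_set(prs, c(100), reps = 1, cfg = cfg),
               "outside")
})

test_that("mean excitation duration grows with concentration when beta > 0", {
  pr <- chemical_profile("dose", tau0 = 80, beta = 40, recovery_total = 80,
                         conc_range = c(0.01, 10), cell_cv = 0.1)
  names_pr <- list(dose = pr)
  cfg <- sim_config(duration = 300, stimulus_time = 60, n_cells = 25, seed = 17)
  tr <- simulate_training_set(names_pr, c(0.1, 10), reps = 3, cfg = cfg)
  y1_lo <- mean(tr$y1[tr$concentration_mM == 0.1])
  y1_hi <- mean(tr$y1[tr$concentration_mM == 10])
  expect_gt(y1_hi, y1_lo)
  # roughly two decades * beta apart
  expect_lt(abs((y1_hi - y1_lo) - 80) / 80, 0.5)
})

test_that("shipped profiles match the assay's training ranges", {
  prs <- default_profiles()
  expect_equal(prs[["L-Ser"]]$conc_range, c(0.001, 0.05))
  expect_equal(prs[["L-Glu"]]$conc_range, c(0.01, 50))
  expect_equal(prs[["L-Asp"]]$conc_range, c(0.001, 3))
  expect_equal(prs[["D-Asp"]]$conc_range, c(0.01, 50))
  expect_equal(prs[["L-Asn"]]$conc_range, c(0.05, 30))
  expect_equal(prs[["L-Cys"]]$conc_range, c(0.01, 3))
  expect_length(prs, 8)
  # the beverage pair differs only in dose response, not geometry
  a <- prs[["Cola-A"]]; b <- prs[["Cola-B"]]
  expect_equal(a$recovery_shape, b$recovery_shape)
  expect_equal(a$recovery_fracs, b$recovery_fracs)
  expect_lt(abs(a$tau0 - b$tau0) / a$tau0, 0.1)
  expect_false(a$beta == b$beta)
})

test_that("profile construction validates its parameters", {
  expect_error(chemical_profile("bad", tau0 = -1, beta = 0,
                                recovery_total = 10))
  expect_error(chemical_profile("bad", tau0 = 1, beta = 0,
                                recovery_total = 10,
                                recovery_fracs = c(0.5, 0.5, 0.5)))
  expect_error(chemical_profile("bad", tau0 = 1, beta = 0,
                                recovery_total = 10,
                                conc_range = c(10, 1)))
  expect_error(sim_config(duration = 700), "600")
})
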