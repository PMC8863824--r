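# exact tail values computed independently with rational arithmetic
# (fractions over integers), frozen here
tail_oracle <- tibble::tibble(
  n = c(64, 10, 96, 100, 50, 100, 7, 100),
  n_chem = c(2, 3, 6, 5, 4, 2, 6, 6),
  k_acc = c(58 / 64, 7 / 10, 41 / 96, 30 / 100, 20 / 50, 80 / 100, 3 / 7, 43 / 100),
  p = c(4.51450948022250054e-12, 1.96616369455875628e-02,
        1.73321805668251417e-09, 1.12489787209916342e-02,
        1.39176086786606656e-02, 5.57954452862597573e-10,
        9.57754629629629650e-02, 5.43908677020845486e-10))

test_that("random-selection rate is the reciprocal of the group size", {
  expect_equal(rs_rate(2), 0.5)
  expect_equal(round(rs_rate(6), 2), 0.17)
  expect_equal(rs_rate(1), 1)
  expect_error(rs_rate(0), ">= 1")
})

test_that("Monte-Carlo RS standard deviation matches the binomial closed form", {
  sd64 <- rs_sd_mc(64, 2, reps = 1e6, seed = 1)
  expect_lt(abs(sd64 - sqrt(0.25 / 64)), 1e-3)  # 0.0625
  expect_equal(rs_sd_mc(64, 1), 0)
  # SD shrinks as 1/sqrt(n)
  sd256 <- rs_sd_mc(256, 2, reps = 1e6, seed = 2)
  expect_lt(abs(sd64 / sd256 - 2), 0.05)
  expect_error(rs_sd_mc(64, 2, reps = 10), "1000")
})

test_that("exact binomial tails match the rational-arithmetic oracle", {
  for (j in seq_len(nrow(tail_oracle))) {
    got <- rs_tail_probability(tail_oracle$k_acc[j], tail_oracle$n[j],
                               tail_oracle$n_chem[j])
    expect_equal(got, tail_oracle$p[j], tolerance = 1e-12)
  }
  expect_equal(rs_tail_probability(58 / 64, 64, 2), 83278001 / 2^64,
               tolerance = 1e-14)
  expect_equal(rs_tail_probability(1, 2, 2), 0.25)
  expect_equal(rs_tail_probability(0, 64, 2), 1)
})

test_that("exact tails agree with R's binomial tail across n and group sizes", {
  for (n in c(5, 17, 33, 64, 100)) {
    for (nc in 2:6) {
      for (acc in c(0.2, 0.5, 0.9, 1)) {
        k <- ceiling(acc * n - 1e-9)
        expect_equal(rs_tail_probability(acc, n, nc),
                     stats::pbinom(k - 1, n, 1 / nc, lower.tail = FALSE),
                     tolerance = 1e-11)
      }
    }
  }
  # monotone non-increasing in accuracy
  accs <- seq(0, 1, by = 0.1)
  ps <- purrr::map_dbl(accs, rs_tail_probability, n_total = 60, n_chem = 3)
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[1], 1)
})

test_that("DSI is the log2 accuracy ratio", {
  for (a in c(0.1, 0.43, 1)) expect_equal(dsi(a, a), 0)
  expect_equal(dsi(1, 0.5), 1)
  expect_equal(dsi(0.43, 1 / 6), log2(0.43 * 6))
  expect_equal(dsi(0.43, 1 / 6), 1.37, tolerance = 0.005)
  # depends only on the ratio
  for (c_ratio in c(1.5, 2.58, 4)) {
    expect_equal(dsi(rs_rate(6) * c_ratio, rs_rate(6)), log2(c_ratio))
  }
  expect_error(dsi(0, 0.5), "\\(0, 1\\]")
})

test_that("group enumeration is complete and lexicographic", {
  chems <- LETTERS[1:6]
  expect_length(enumerate_groups(chems, 2), 15)
  expect_length(enumerate_groups(chems, 3), 20)
  expect_length(enumerate_groups(chems, 6), 1)
  expect_equal(enumerate_groups(chems, 2)[[1]], c("A", "B"))
  expect_equal(enumerate_groups(chems, 2)[[15]], c("E", "F"))
  expect_error(enumerate_groups(chems, 7), "1..6")
})

test_that("leave-one-out separates well-separated chemicals", {
  train <- make_gaussian_vectors(c("A", "B"), n_per = 32, seed = 7, sep = 30)
  rep2 <- loo_accuracy(train, rs_reps = 1000)
  expect_gte(rep2$accuracy, 0.9)
  expect_equal(rep2$rs_rate, 0.5)
  expect_false(rep2$degenerate)
  expect_equal(nrow(rep2$per_sample), 64)
  expect_lt(rep2$rs_tail_prob, 1e-6)
  expect_gt(rep2$dsi, 0.8)
  # record order does not matter
  perm <- train[rev(seq_len(nrow(train))), ]
  expect_equal(loo_accuracy(perm, rs_reps = 1000)$accuracy, rep2$accuracy)
})

test_that("indistinguishable chemicals score at chance level", {
  accs <- purrr::map_dbl(1:20, function(s) {
    train <- make_gaussian_vectors(c("A", "B"), n_per = 32, seed = 100 + s,
                                   sep = 0)
    loo_accuracy(train, rs_reps = 1000)$accuracy
  })
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("degenerate and invalid groups are handled", {
  train <- make_gaussian_vectors("A", n_per = 8, seed = 2)
  rep1 <- loo_accuracy(train, rs_reps = 1000)
  expect_equal(rep1$accuracy, 1)
  expect_true(rep1$degenerate)
  small <- make_gaussian_vectors(c("A", "B"), n_per = 3, seed = 2)
  expect_error(loo_accuracy(small, rs_reps = 1000), "fewer than 4")
  expect_error(loo_accuracy(train, group = c("A", "Z"), rs_reps = 1000), "Z")
})

test_that("the accuracy spectrum covers every group and is symmetric for pairs", {
  train <- make_gaussian_vectors(c("A", "B", "C"), n_per = 8, seed = 13,
                                 sep = 40)
  spec2 <- accuracy_spectrum(train, k = 2, rs_reps = 1000)
  expect_equal(nrow(spec2$summary), 3)
  m <- spec2$matrix
  expect_true(all(is.na(diag(m))))
  expect_equal(m[upper.tri(m)], t(m)[upper.tri(m)])
  expect_true(all(spec2$summary$rs_rate == 0.5))
  # k = N reduces to a single full-group report
  spec3 <- accuracy_spectrum(train, k = 3, rs_reps = 1000)
  expect_equal(nrow(spec3$summary), 1)
  full <- loo_accuracy(train, rs_reps = 1000)
  expect_equal(spec3$summary$accuracy, full$accuracy)
  expect_equal(spec3$mean_accuracy, full$accuracy)
})
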