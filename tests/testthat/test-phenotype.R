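make_trials <- function(items, n_each, participant = "p01") {
  rows <- lapply(seq_along(items), function(i) {
    k <- n_each[i]
    data.frame(participant = participant, item = items[i],
               onset_s = seq(0, by = 10, length.out = k) + i * 1000,
               kind = c("study", rep("test", k - 1)),
               correct = TRUE, rt_s = 1.2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("participant SoF averages phi over sufficiently-presented items", {
  tr <- make_trials(c("a", "b"), c(5, 5))
  ph <- compute_sof(tr, c(a = 0.28, b = 0.32))
  expect_equal(ph$sof, 0.30)
  expect_equal(ph$n_items_used, 2L)

  tr2 <- make_trials(c("a", "b", "c"), c(5, 5, 2))
  ph2 <- compute_sof(tr2, c(a = 0.28, b = 0.32, c = 0.60))
  expect_equal(ph2$sof, 0.30)          # item c presented only twice
  expect_equal(ph2$n_items_used, 2L)

  same <- compute_sof(make_trials("a", 4), c(a = 0.305))
  expect_equal(same$sof, 0.305)

  expect_error(compute_sof(make_trials("a", 2), c(a = 0.3)),
               "insufficient-data")
})

test_that("predicted response times replay traces under the global SoF", {
  tr <- data.frame(participant = "p01", item = "a",
                   onset_s = c(0, 10), kind = c("study", "test"),
                   correct = TRUE, rt_s = c(1.5, 2.1),
                   stringsAsFactors = FALSE)
  pr <- predicted_rts(tr, sof = 0.3)
  expect_equal(pr$A, -0.3 * log(10), tolerance = 1e-12)
  expect_equal(pr$predicted_rt_s, 0.3 + exp(0.3 * log(10)), tolerance = 1e-12)
  expect_equal(pr$predicted_rt_s, 2.30, tolerance = 1e-2)

  tr1 <- data.frame(participant = "p01", item = "a",
                    onset_s = c(0, 1), kind = c("study", "test"),
                    correct = TRUE, rt_s = c(1.5, 1.3),
                    stringsAsFactors = FALSE)
  expect_equal(predicted_rts(tr1, sof = 0.3)$predicted_rt_s, 1.3)

  # an intervening rehearsal speeds the later of two equal-lag tests
  tr2 <- data.frame(participant = "p01", item = "a",
                    onset_s = c(0, 40, 80), kind = c("study", "test", "test"),
                    correct = TRUE, rt_s = 1.5, stringsAsFactors = FALSE)
  pr2 <- predicted_rts(tr2, sof = 0.3)
  expect_lt(pr2$predicted_rt_s[2], pr2$predicted_rt_s[1])

  bad <- data.frame(participant = "p01", item = "a", onset_s = 5,
                    kind = "test", correct = TRUE, rt_s = 1,
                    stringsAsFactors = FALSE)
  expect_error(predicted_rts(bad, sof = 0.3), "precedes")
})

test_that("outlier rule removes strictly-slower-than-cap responses in place", {
  expect_equal(filter_outliers(c(0.5, 7.9, 8.1)), c(0.5, 7.9))
  expect_equal(filter_outliers(c(3, 8, 1)), c(3, 8, 1))
  expect_equal(filter_outliers(numeric(0)), numeric(0))
})

test_that("response-time histograms bin into ten 800 ms bins", {
  h <- rt_histogram(c(0.1, 0.79, 0.81, 7.99, 8.0))
  expect_length(h$counts, 10L)
  expect_equal(sum(h$counts), 5L)
  expect_equal(h$counts[1], 2L)
  expect_equal(h$counts[10], 2L)
})

test_that("KL divergence is zero at equality, asymmetric, and closed-form", {
  a <- rt_histogram(rep(c(1, 2, 5), times = c(4, 3, 3)))
  expect_equal(kl_divergence(a, a), 0)

  conc <- structure(list(edges = seq(0, 8, 0.8),
                         counts = c(10, rep(0L, 9))), class = "rt_histogram")
  unif <- structure(list(edges = seq(0, 8, 0.8),
                         counts = rep(1L, 10)), class = "rt_histogram")
  expect_equal(kl_divergence(conc, unif, smoothing = 0), log2(10),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(kl_divergence(a, unif),
                                kl_divergence(unif, a))))
  expect_gte(kl_divergence(a, unif), 0)
  b <- rt_histogram(c(0.3, 2.2, 6.6))
  expect_error(kl_divergence(a, structure(list(edges = seq(0, 4, 0.4),
                                               counts = rep(1L, 10)),
                                          class = "rt_histogram")),
               "mismatched")
  expect_gte(kl_divergence(a, b), 0)
})

test_that("chi-square fit handles equality, hand-worked counts, and merging", {
  a <- rt_histogram(rep(seq(0.4, 7.6, by = 0.8), times = 3))
  fit <- chi_square_fit(a, a)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p, 1)

  O <- structure(list(edges = c(0, 4, 8), counts = c(10L, 0L)),
                 class = "rt_histogram")
  E <- structure(list(edges = c(0, 4, 8), counts = c(5L, 5L)),
                 class = "rt_histogram")
  fit2 <- chi_square_fit(O, E)
  expect_equal(fit2$statistic, 10)
  expect_equal(fit2$dof, 1L)

  # sparse expectations merge until every expected count reaches 1
  O3 <- structure(list(edges = seq(0, 8, 0.8),
                       counts = c(5L, 3L, rep(0L, 8))),
                  class = "rt_histogram")
  E3 <- structure(list(edges = seq(0, 8, 0.8),
                       counts = c(60L, 30L, rep(1L, 8))),
                  class = "rt_histogram")
  fit3 <- chi_square_fit(O3, E3)
  expect_lt(fit3$n_bins, 10L)
  expect_gte(fit3$dof, 1L)
})

test_that("accuracy table codes the P > 0.5 boundary as predicted-incorrect", {
  tr <- data.frame(participant = "p01", item = rep(c("a", "b"), each = 2),
                   onset_s = c(0, 0.5, 10, 11),
                   kind = rep(c("study", "test"), 2),
                   correct = c(TRUE, TRUE, TRUE, FALSE), rt_s = 1,
                   stringsAsFactors = FALSE)
  tab <- accuracy_diagnostics(tr, sof = 0.3)
  expect_equal(sum(tab), 2L)                  # one test trial per item
  # item a tested at lag 0.5 (A > 0, predicted correct, observed correct);
  # item b tested at lag 1 (A = 0, boundary -> predicted incorrect)
  expect_equal(tab["correct", "correct"], 1L)
  expect_equal(tab["incorrect", "incorrect"], 1L)
})

test_that("refitting model-generated sessions yields near-zero divergence", {
  set.seed(21)
  cfg <- scheduler_config(session_length = 400)
  resp <- simulate_learner(0.3, config = cfg, rt_noise_sigma = 0.02)
  s <- run_session(resp, cfg)
  ph <- compute_sof(s$trials, s$state$phis)
  fd <- fit_diagnostics(s$trials, ph$sof)
  expect_lt(fd$kl_bits, 0.5)
  expect_gte(fd$n_retained, fd$chisq$dof + 1)
})
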