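test_that("activation evaluates the log-sum of power-law trace decays", {
  h1 <- encoding_history("w", times = 0, decays = 0.3)
  expect_equal(activation(h1, 600), -0.3 * log(600), tolerance = 1e-12)
  expect_lt(abs(activation(h1, 600) - -1.9191), 1e-4)

  # unit-lag identity: one second after a lone trace, activation is zero
  h2 <- encoding_history("w", times = 5, decays = 0.47)
  expect_equal(activation(h2, 6), 0, tolerance = 1e-12)

  h3 <- encoding_history("w", times = c(0, 10), decays = c(0.3, 0.4253))
  expect_lt(abs(activation(h3, 70) - -0.788), 1e-3)
})

test_that("activation rejects empty histories and non-causal queries", {
  expect_error(activation(encoding_history("w"), 10), "no-trace")
  h <- encoding_history("w", times = c(0, 10), decays = c(0.3, 0.4))
  expect_error(activation(h, 10), "exceed")
  expect_error(activation(h, 5), "exceed")
})

test_that("activation matches a brute-force trace loop to 1e-10", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    times <- sort(stats::runif(n, 0, 500))
    decays <- stats::runif(n, 0.1, 0.8)
    h <- encoding_history("w", times = times, decays = decays)
    t <- max(times) + stats::runif(1, 0.5, 300)
    expect_equal(activation(h, t), brute_force_activation(times, decays, t),
                 tolerance = 1e-10)
  }
})

test_that("decay rate is the scaled exponentiated activation plus phi", {
  expect_equal(decay_rate(encoding_history("w"), 0, phi = 0.3), 0.3)
  h <- encoding_history("w", times = 0, decays = 0.3)
  expect_equal(decay_rate(h, 10, phi = 0.3),
               0.25 * exp(-0.3 * log(10)) + 0.3, tolerance = 1e-12)
  expect_equal(decay_rate(h, 10, phi = 0.3), 0.4253, tolerance = 1e-4)
  # d >= phi always, and increasing in prior activation
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    hh <- encoding_history("w", times = sort(stats::runif(n, 0, 60)),
                           decays = stats::runif(n, 0.3, 0.5))
    expect_gt(decay_rate(hh, 61, phi = 0.3), 0.3)
  }
})

test_that("encode appends a trace without mutating its input", {
  h0 <- encoding_history("w")
  h1 <- encode(h0, 0, phi = 0.3)
  expect_equal(h1$times, 0)
  expect_equal(h1$decays, 0.3)
  expect_length(h0$times, 0)            # value semantics
  h2 <- encode(h1, 10, phi = 0.3)
  expect_equal(h2$decays[2], 0.4253, tolerance = 1e-4)
  expect_error(encode(h2, 10, phi = 0.3), "exceed")
  h <- h0
  for (k in 1:25) h <- encode(h, k * 2, phi = 0.3)
  expect_length(h$times, 25)
})

test_that("retrieval probability is the logistic link with a -Inf floor", {
  expect_equal(retrieval_probability(0), 0.5)
  expect_equal(retrieval_probability(-Inf), 0)
  A600 <- -0.3 * log(600)
  expect_lt(retrieval_probability(A600), 0.25)
  expect_lt(abs(retrieval_probability(A600) - 0.128), 1e-3)
  # strictly increasing bijection into (0, 1)
  As <- seq(-10, 10, length.out = 101)
  ps <- retrieval_probability(As)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("predicted response time decreases in activation toward t0", {
  expect_equal(predicted_rt(0), 1.3)
  expect_lt(abs(predicted_rt(-0.3 * log(600)) - 7.12), 1e-2)
  expect_equal(predicted_rt(50), 0.3, tolerance = 1e-6)
  As <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(predicted_rt(As)) < 0))
  expect_true(all(predicted_rt(As) >= 0.3))
})

test_that("forgetting curves decay monotonically and order by phi", {
  fc <- forgetting_curve(0.3, horizon = 600, step = 1)
  expect_true(all(diff(fc$P) < 0))
  expect_lt(fc$P[fc$t == 600], 0.25)
  expect_equal(fc$P[fc$t == 1], 0.5)
  fb <- forgetting_curve(0.4, horizon = 600, step = 1)
  expect_true(all(fc$P[fc$t > 1] > fb$P[fb$t > 1]))
})
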