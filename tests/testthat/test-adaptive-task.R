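test_that("scheduler introduces, rehearses, and falls back in rule order", {
  cfg <- scheduler_config()
  st <- new_scheduler_state(cfg)
  nt <- next_trial(st, cfg)
  expect_equal(nt$kind, "study")
  expect_equal(nt$item, "item01")

  # an item studied 300 s ago has decayed past the threshold: test it
  st$histories[["item01"]] <- encode(encoding_history("item01"), 0, 0.3)
  st$introduced <- "item01"
  st$clock <- 300
  expect_lt(activation(st$histories[["item01"]], 315),
            cfg$activation_threshold)
  nt <- next_trial(st, cfg)
  expect_equal(nt, list(item = "item01", kind = "test"))

  # freshly-encoded items are safe: introduce the next item instead
  st$histories[["item01"]] <- encode(st$histories[["item01"]], 300, 0.3)
  nt <- next_trial(st, cfg)
  expect_equal(nt$kind, "study")
  expect_equal(nt$item, "item02")

  # all introduced and none at risk: lowest-activation item, as a test
  cfg2 <- scheduler_config(n_items = 2)
  st2 <- new_scheduler_state(cfg2)
  st2$histories[["item01"]] <- encode(encoding_history("item01"), 0, 0.3)
  st2$histories[["item02"]] <- encode(encoding_history("item02"), 4, 0.3)
  st2$introduced <- c("item01", "item02")
  st2$clock <- 5
  nt <- next_trial(st2, cfg2)
  expect_equal(nt, list(item = "item01", kind = "test"))
})

test_that("phi grid refit recovers the generating value from noise-free logs", {
  cfg <- scheduler_config()
  for (phi_true in c(0.22, 0.35, 0.48)) {
    trials <- noise_free_item_log(phi_true, test_times = c(30, 90, 200))
    expect_equal(update_phi(trials, 0.3, config = cfg), phi_true,
                 tolerance = cfg$phi_step + 1e-9)
  }
})

test_that("phi adjusts upward after an error and is fixed at zero residual", {
  cfg <- scheduler_config()
  bad <- data.frame(participant = "p", item = "i",
                    onset_s = c(0, 60), kind = c("study", "test"),
                    correct = c(TRUE, FALSE), rt_s = c(1.5, 3),
                    stringsAsFactors = FALSE)
  expect_gte(update_phi(bad, 0.3, config = cfg), 0.3)
  # observations equal to predictions under the incumbent: unchanged
  ok <- noise_free_item_log(0.3, test_times = c(40, 120))
  expect_equal(update_phi(ok, 0.3, config = cfg), 0.3)
  # no test trials at all: incumbent returned untouched
  study_only <- bad[1, , drop = FALSE]
  expect_identical(update_phi(study_only, 0.271, config = cfg), 0.271)
})

test_that("per-item phi recovery is near-exact across a noise-free grid", {
  cfg <- scheduler_config()
  phis <- seq(0.22, 0.50, length.out = 100)
  rec <- vapply(phis, function(p) {
    trials <- noise_free_item_log(p, test_times = c(25, 70, 180, 420))
    update_phi(trials, 0.3, config = cfg)
  }, numeric(1))
  expect_gte(stats::cor(phis, rec), 0.95)
  expect_lt(max(abs(rec - phis)), 2 * cfg$phi_step)
})

test_that("sessions keep time, only test studied items, and honour budgets", {
  cfg <- scheduler_config(session_length = 120)
  responder <- function(item, kind, A) list(correct = TRUE, rt = 0.5)
  s <- run_session(responder, cfg)
  expect_true(all(s$trials$correct))
  expect_lte(length(s$state$introduced), cfg$n_items)
  expect_true(all(diff(s$trials$onset_s) > 0))
  expect_lte(max(s$trials$onset_s), cfg$session_length)
  expect_lte(s$state$clock, cfg$session_length + 0.5 + cfg$isi_correct)
  # a test trial never precedes that item's first study
  firsts <- tapply(seq_len(nrow(s$trials)), s$trials$item, min)
  expect_true(all(s$trials$kind[firsts] == "study"))

  empty <- run_session(responder, scheduler_config(session_length = 0))
  expect_equal(nrow(empty$trials), 0L)
})

test_that("simulated sessions land in the published trial-count envelope", {
  set.seed(100)
  cfg <- scheduler_config()
  counts <- vapply(c(0.28, 0.305, 0.33), function(sof) {
    resp <- simulate_learner(sof, config = cfg, rt_noise_sigma = 0.3)
    nrow(run_session(resp, cfg)$trials)
  }, numeric(1))
  expect_true(all(counts >= 91 & counts <= 221))
})

test_that("disabling re-encoding on errors changes histories, not ordering", {
  set.seed(11)
  cfg_on <- scheduler_config(session_length = 180)
  cfg_off <- scheduler_config(session_length = 180,
                              encode_on_incorrect = FALSE)
  resp <- simulate_learner(0.32, config = cfg_on, rt_noise_sigma = 0.2)
  s_on <- run_session(resp, cfg_on)
  set.seed(11)
  resp <- simulate_learner(0.32, config = cfg_off, rt_noise_sigma = 0.2)
  s_off <- run_session(resp, cfg_off)
  for (s in list(s_on, s_off)) {
    for (h in s$state$histories)
      if (length(h$times) > 1) expect_true(all(diff(h$times) > 0))
  }
  n_err <- sum(!s_off$trials$correct)
  if (n_err > 0) {
    traces <- function(s) sum(lengths(lapply(s$state$histories, `[[`, "times")))
    expect_true(traces(s_on) != traces(s_off) ||
                  nrow(s_on$trials) != nrow(s_off$trials))
  }
})
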