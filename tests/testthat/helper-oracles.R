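# Independent oracles and fixture builders shared across the suite.

# Literal trace-by-trace activation sum, written as a scalar loop so it
# shares no code path with the vectorized implementation.
brute_force_activation <- function(times, decays, t) {
  total <- 0
  for (i in seq_along(times))
    total <- total + exp(-decays[i] * log(t - times[i]))
  log(total)
}

# Partial correlation of every pair by explicit residual regression on the
# remaining columns (the textbook definition).
residual_regression_partials <- function(ts) {
  p <- ncol(ts)
  out <- diag(p)
  dimnames(out) <- list(colnames(ts), colnames(ts))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- ts[, -c(i, j), drop = FALSE]
    ri <- stats::lm.fit(cbind(1, others), ts[, i])$residuals
    rj <- stats::lm.fit(cbind(1, others), ts[, j])$residuals
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# Random named feature matrix shaped like a cohort's edge features.
random_features <- function(n = 33, p = 45, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("f", sprintf("%02d", seq_len(p)))
  X
}

# Design whose standardized columns are exactly orthonormal under the
# solver's 1/n-variance convention, so the lasso solution has the
# soft-thresholding closed form.
orthonormal_design <- function(n = 40, p = 8, seed = 2) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * p), n, p)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  Q <- sweep(Q, 2, colMeans(Q))          # re-centre (numerically tiny shift)
  Q <- qr.Q(qr(Q))
  X <- Q * sqrt(n)
  colnames(X) <- paste0("q", seq_len(p))
  X
}

# Trial log for one item following a fixed test schedule, with response
# times generated noise-free from the latency model under `phi_true`.
noise_free_item_log <- function(phi_true, test_times,
                                params = model_params(),
                                config = scheduler_config(),
                                participant = "p01", item = "item01") {
  h <- encode(encoding_history(item), 0, phi_true, params)
  rows <- list(data.frame(participant = participant, item = item,
                          onset_s = 0, kind = "study", correct = TRUE,
                          rt_s = 1.5, stringsAsFactors = FALSE))
  for (tt in test_times) {
    A <- activation(h, tt)
    rows[[length(rows) + 1L]] <-
      data.frame(participant = participant, item = item, onset_s = tt,
                 kind = "test", correct = TRUE,
                 rt_s = predicted_rt(A, params), stringsAsFactors = FALSE)
    h <- encode(h, tt, phi_true, params)   # correct test re-encodes
  }
  do.call(rbind, rows)
}

planted_feature_names <- function() {
  pe <- default_planted_edges()
  paste(pe$network_a, pe$network_b, sep = "--")
}
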