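random_ts <- function(n = 210, p = 17, seed = 3) {
  set.seed(seed)
  ts <- matrix(stats::rnorm(n * p), n, p)
  colnames(ts) <- yeo17_parcellation()$networks[seq_len(p)]
  ts
}

test_that("the shipped parcellation has the published group structure", {
  p <- yeo17_parcellation()
  expect_length(p$networks, 17L)
  expect_equal(sum(p$group == "DMN"), 3L)
  expect_equal(sum(p$group == "Retrieval"), 6L)
  expect_equal(sum(p$group == "Storage"), 8L)
  expect_setequal(names(p$group)[p$group == "DMN"],
                  c("Default A", "Default B", "Default C"))
  expect_setequal(names(p$group)[p$group == "Retrieval"],
                  c("Control A", "Control B", "Dorsal Attention A",
                    "Salience B", "Limbic B", "Temporal Parietal"))
})

test_that("Pearson connectomes match a naive two-pass oracle", {
  ts <- random_ts()
  cm <- pearson_connectome(ts)
  naive <- matrix(NA_real_, 17, 17)
  for (i in 1:17) for (j in 1:17) {
    x <- ts[, i] - mean(ts[, i]); y <- ts[, j] - mean(ts[, j])
    naive[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  expect_lt(max(abs(unclass(cm) - naive)), 1e-12)
  expect_equal(diag(unclass(cm)), rep(1, 17), ignore_attr = TRUE)

  two <- cbind(a = ts[, 1], b = ts[, 1], c = -ts[, 1] + 1e-9 * ts[, 2])
  cm2 <- pearson_connectome(two)
  expect_equal(cm2["a", "b"], 1)
  expect_equal(cm2["a", "c"], -1, tolerance = 1e-6)

  bad <- ts; bad[, 4] <- 2
  expect_error(pearson_connectome(bad), "Somatomotor B")
})

test_that("partial correlations equal the residual-regression definition", {
  ts <- random_ts(seed = 9)
  pc <- partial_connectome(ts)
  oracle <- residual_regression_partials(ts)
  expect_lt(max(abs(unclass(pc) - oracle)), 1e-8)

  # classic suppression: X3 = X1 + X2 + noise induces a negative partial
  set.seed(10)
  x1 <- stats::rnorm(500); x2 <- stats::rnorm(500)
  x3 <- x1 + x2 + stats::rnorm(500, 0, 0.1)
  trio <- cbind(A = x1, B = x2, C = x3)
  pt <- partial_connectome(trio)
  expect_lt(pt["A", "B"], -0.9)
  expect_lt(abs(stats::cor(x1, x2)), 0.1)

  ind <- random_ts(n = 5000, p = 5, seed = 13)
  pi_ <- partial_connectome(ind)
  expect_lt(max(abs(unclass(pi_)[row(pi_) != col(pi_)])), 0.06)
})

test_that("connectomes are invariant to per-column affine rescaling", {
  ts <- random_ts(seed = 17)
  scl <- sweep(sweep(ts, 2, stats::runif(17, 1, 5), "*"),
               2, stats::runif(17, -3, 3), "+")
  expect_equal(unclass(pearson_connectome(ts)),
               unclass(pearson_connectome(scl)), tolerance = 1e-10)
  expect_equal(unclass(partial_connectome(ts)),
               unclass(partial_connectome(scl)), tolerance = 1e-8)
})

test_that("Fisher-z averaging is identity-preserving, odd, and convex-free", {
  ts <- random_ts(seed = 23)
  m <- pearson_connectome(ts)
  expect_equal(unclass(fisher_group_average(list(m, m))), unclass(m),
               tolerance = 1e-12)

  mk <- function(r) {
    v <- matrix(r, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
    diag(v) <- 1
    connectivity_matrix(v, "pearson")
  }
  expect_equal(fisher_group_average(list(mk(0.5), mk(-0.5)))["x", "y"], 0)
  avg <- fisher_group_average(list(mk(0.3), mk(0.7)))["x", "y"]
  expect_equal(avg, tanh((atanh(0.3) + atanh(0.7)) / 2), tolerance = 1e-12)
  expect_lt(abs(avg - 0.527), 2e-3)
  expect_gt(avg, 0.5)   # z-averaging exceeds the arithmetic mean here

  degen <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_warning(fisher_group_average(list(connectivity_matrix(degen, "pearson"))),
                 "clipped")
})

test_that("feature extraction yields the 45 DMN-anchored edges in order", {
  ed <- feature_edges()
  expect_equal(nrow(ed), 45L)
  expect_equal(ed$feature[1:3], c("Default A--Default B",
                                  "Default A--Default C",
                                  "Default B--Default C"))
  expect_equal(ed$network_a[4:17], rep("Default A", 14))

  ts <- random_ts(seed = 29)
  cm <- partial_connectome(ts)
  fv <- extract_features(cm)
  expect_length(fv, 45L)
  expect_equal(unname(fv["Default A--Default C"]),
               cm["Default A", "Default C"])

  eye <- diag(17)
  dimnames(eye) <- list(yeo17_parcellation()$networks,
                        yeo17_parcellation()$networks)
  expect_true(all(extract_features(connectivity_matrix(eye, "partial")) == 0))

  wrong <- cm
  rownames(wrong)[1] <- colnames(wrong)[1] <- "Elsewhere"
  expect_error(extract_features(wrong), "parcellation")

  X <- feature_matrix(list(p1 = cm, p2 = cm))
  expect_equal(dim(X), c(2L, 45L))
  expect_identical(colnames(X), ed$feature)
})
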