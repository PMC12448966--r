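#' Participant-level speed of forgetting
#'
#' Averages the final per-item decay intercepts over the items a participant
#' actually learned: only items presented at least \code{min_presentations}
#' times (study and test trials combined) contribute to the mean.
#'
#' @param trials Trial records of a single participant (data frame with
#'   columns \code{participant,item,onset_s,kind,correct,rt_s}).
#' @param final_phis Named numeric vector of final per-item phi estimates.
#' @param min_presentations Minimum presentations for an item to qualify.
#'   Default 3.
#' @return An object of class \code{phenotype}: \code{participant},
#'   \code{per_item_phi} (qualifying items only), \code{sof} (their
#'   unweighted mean), \code{n_items_used}.
#' @export
compute_sof <- function(trials, final_phis, min_presentations = 3) {
  stopifnot(length(unique(trials$participant)) <= 1L)
  pres <- table(trials$item)
  keep <- names(pres)[pres >= min_presentations]
  keep <- intersect(keep, names(final_phis))
  if (length(keep) == 0L)
    stop("insufficient-data: no item presented at least ",
         min_presentations, " times")
  phi <- final_phis[keep]
  structure(list(participant = if (nrow(trials)) trials$participant[1] else NA,
                 per_item_phi = phi, sof = mean(phi),
                 n_items_used = length(phi)),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("<phenotype> participant=%s  SoF=%.4f  (%d items)\n",
              format(x$participant), x$sof, x$n_items_used))
  invisible(x)
}

#' Model-predicted response times under the participant-level phenotype
#'
#' Replays every item's encoding events with all trace decay rates
#' recomputed under the single participant-level speed of forgetting (not
#' the per-item estimates), then evaluates the latency equation at each test
#' trial. This is the post-hoc fit check: one global parameter must account
#' for all of a participant's test latencies.
#'
#' @param trials One participant's trial records.
#' @param sof Participant-level speed of forgetting (scalar).
#' @param params A \code{\link{model_params}}.
#' @param config A \code{\link{scheduler_config}} (re-encoding policy).
#' @return Data frame of test trials with added columns \code{A}
#'   (activation at trial onset) and \code{predicted_rt_s}.
#' @export
predicted_rts <- function(trials, sof, params = model_params(),
                          config = scheduler_config()) {
  tests <- trials[trials$kind == "test", , drop = FALSE]
  out <- vector("list", length(unique(tests$item)))
  k <- 0L
  for (it in unique(tests$item)) {
    item_tr <- trials[trials$item == it, , drop = FALSE]
    enc_times <- item_encoding_times(item_tr, config)
    tt <- item_tr[item_tr$kind == "test", , drop = FALSE]
    if (length(enc_times) == 0L || any(tt$onset_s <= enc_times[1]))
      stop("test trial precedes any study of item ", it)
    D <- replay_decays(enc_times, sof, params)
    A <- vapply(tt$onset_s, function(t) replay_activation(enc_times, D, t),
                numeric(1))
    tt$A <- A
    tt$predicted_rt_s <- params$t0 + params$F * exp(-A)
    k <- k + 1L
    out[[k]] <- tt
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$onset_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove response-time outliers
#'
#' Drops responses slower than the cap (default 8 s), preserving order.
#'
#' @param rts Numeric vector of response times in seconds.
#' @param cap Exclusive upper bound in seconds. Default 8.
#' @return The retained response times.
#' @export
filter_outliers <- function(rts, cap = 8) {
  rts[rts <= cap]
}

#' Bin response times into the standard 800 ms histogram
#'
#' Ten 800 ms bins spanning 0-8 s. Values outside (0, 8] are not counted;
#' apply \code{\link{filter_outliers}} first to make the retained total
#' explicit.
#'
#' @param rts Response times in seconds.
#' @param edges Bin edges; default \code{seq(0, 8, by = 0.8)} (11 edges).
#' @return An object of class \code{rt_histogram} with \code{edges} and
#'   integer \code{counts}.
#' @export
rt_histogram <- function(rts, edges = seq(0, 8, by = 0.8)) {
  stopifnot(length(edges) >= 3L, all(diff(edges) > 0))
  keep <- rts > edges[1] & rts <= edges[length(edges)]
  idx <- findInterval(rts[keep], edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, counts = counts), class = "rt_histogram")
}

check_same_edges <- function(a, b) {
  stopifnot(inherits(a, "rt_histogram"), inherits(b, "rt_histogram"))
  if (length(a$edges) != length(b$edges) ||
      any(abs(a$edges - b$edges) > 1e-12))
    stop("histograms have mismatched bin edges")
}

#' Kullback-Leibler divergence between binned response-time distributions
#'
#' KL(observed || predicted) over bin proportions, reported in bits: the
#' mean number of bits lost when observed response times are replaced by the
#' model's predictions. Additive smoothing (default 0.5 pseudo-counts per
#' bin, applied to both histograms before normalizing) keeps the divergence
#' finite when the model leaves a bin empty.
#'
#' @param observed,predicted \code{\link{rt_histogram}} objects on the same
#'   edges.
#' @param smoothing Pseudo-count added to every bin. Default 0.5; use 0 for
#'   the unsmoothed divergence (may be \code{Inf}).
#' @return Non-negative divergence in bits.
#' @export
kl_divergence <- function(observed, predicted, smoothing = 0.5) {
  check_same_edges(observed, predicted)
  p <- observed$counts + smoothing
  q <- predicted$counts + smoothing
  p <- p / sum(p)
  q <- q / sum(q)
  terms <- ifelse(p > 0, p * (log2(p) - log2(q)), 0)
  sum(terms)
}

#' Chi-square comparison of observed and model-predicted RT histograms
#'
#' Expected counts are the predicted bin proportions scaled to the observed
#' total; adjacent bins are merged until every expected count is at least 1
#' (small-expectation bins carry no usable signal). The statistic is the
#' usual sum of (O-E)^2/E with dof = retained bins - 1.
#'
#' @inheritParams kl_divergence
#' @param min_expected Merge threshold for expected counts. Default 1.
#' @return List with \code{statistic}, \code{dof}, \code{p}, and
#'   \code{n_bins} (after merging).
#' @export
chi_square_fit <- function(observed, predicted, min_expected = 1) {
  check_same_edges(observed, predicted)
  O <- as.numeric(observed$counts)
  N <- sum(O)
  if (sum(predicted$counts) == 0) stop("predicted histogram is empty")
  E <- predicted$counts / sum(predicted$counts) * N
  # merge the smallest-expectation bin into its neighbour until all E >= min
  while (length(E) > 1L && any(E < min_expected)) {
    i <- which.min(E)
    j <- if (i == length(E)) i - 1L else i + 1L
    E[j] <- E[j] + E[i]; O[j] <- O[j] + O[i]
    E <- E[-i]; O <- O[-i]
  }
  if (length(E) < 2L)
    stop("degenerate-fit: fewer than 2 bins with usable expected counts")
  stat <- sum((O - E)^2 / E)
  dof <- length(E) - 1L
  list(statistic = stat, dof = dof,
       p = stats::pchisq(stat, dof, lower.tail = FALSE), n_bins = length(E))
}

#' Trial-level accuracy confusion table
#'
#' Classifies each test trial as predicted-correct when the model's
#' retrieval probability exceeds 0.5 (activation strictly above zero; the
#' boundary case counts as predicted-incorrect) and crosses this with the
#' observed response.
#'
#' @inheritParams predicted_rts
#' @return A 2x2 integer matrix, rows = predicted (incorrect, correct),
#'   columns = observed (incorrect, correct).
#' @export
accuracy_diagnostics <- function(trials, sof, params = model_params(),
                                 config = scheduler_config()) {
  pr <- predicted_rts(trials, sof, params, config)
  pred <- factor(as.integer(pr$A > 0), levels = c(0, 1))
  obs <- factor(as.integer(pr$correct), levels = c(0, 1))
  tab <- table(predicted = pred, observed = obs)
  matrix(as.integer(tab), 2, 2,
         dimnames = list(predicted = c("incorrect", "correct"),
                         observed = c("incorrect", "correct")))
}

#' Per-participant model-fit diagnostics
#'
#' Convenience wrapper: recomputes predicted response times under the
#' participant-level speed of forgetting, applies the outlier rule to the
#' observed latencies, bins both distributions, and reports the KL
#' divergence and chi-square fit.
#'
#' @inheritParams predicted_rts
#' @return List with \code{kl_bits}, \code{chisq} (statistic, dof, p),
#'   \code{n_total}, \code{n_retained}, and the two histograms.
#' @export
fit_diagnostics <- function(trials, sof, params = model_params(),
                            config = scheduler_config()) {
  pr <- predicted_rts(trials, sof, params, config)
  retained <- pr[pr$rt_s <= config$rt_cap, , drop = FALSE]
  obs_h <- rt_histogram(retained$rt_s, edges = seq(0, config$rt_cap,
                                                   length.out = 11L))
  pred_h <- rt_histogram(retained$predicted_rt_s,
                         edges = seq(0, config$rt_cap, length.out = 11L))
  list(kl_bits = kl_divergence(obs_h, pred_h),
       chisq = chi_square_fit(obs_h, pred_h),
       n_total = nrow(pr), n_retained = nrow(retained),
       observed = obs_h, predicted = pred_h)
}
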