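#' Synthetic-cohort specification
#'
#' Defines the simulated study: a cohort of learners whose true speeds of
#' forgetting are drawn from a truncated normal matching the published
#' cohort distribution (mean 0.305, SD 0.029, n = 33), behavioral sessions
#' generated by the trace-decay model with multiplicative lognormal
#' response-time noise, and per-participant ROI time series (210 volumes,
#' TR 2 s, 17 networks) whose partial correlations carry a planted linear
#' relation to the true speed of forgetting on a set of DMN-anchored edges.
#'
#' @param n_participants Cohort size. Default 33.
#' @param sof_mean,sof_sd Mean and SD of the true speed-of-forgetting
#'   distribution. Defaults 0.305 and 0.029.
#' @param sof_bounds Truncation bounds. Default c(0.20, 0.45).
#' @param rt_noise_sigma Lognormal sdlog of the multiplicative RT noise.
#'   Default 0.3.
#' @param n_rois Number of networks. Default 17.
#' @param n_volumes Volumes per resting-state run. Default 210.
#' @param tr Repetition time in seconds. Default 2.
#' @param planted_edges Data frame (\code{network_a}, \code{network_b},
#'   \code{gamma}): per-edge slope of the target partial correlation per SD
#'   of speed of forgetting. Every edge must touch a DMN subnetwork. The
#'   default plants +0.12, +0.12 and -0.12 on Default A--Default C,
#'   Default B--Visual A and Default C--Dorsal Attention B.
#' @param base_partial Partial correlation placed on consecutive-network
#'   edges of the shared base pattern, and (with positive sign) on every
#'   planted edge, so each planted edge has a stable group-mean
#'   connectivity sign for the sign-adjustment step. Default 0.10.
#' @param noise_scale Marginal variance scale of the simulated BOLD signal
#'   (does not affect correlations). Default 1.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_participants = 33, sof_mean = 0.305,
                        sof_sd = 0.029, sof_bounds = c(0.20, 0.45),
                        rt_noise_sigma = 0.3, n_rois = 17, n_volumes = 210,
                        tr = 2, planted_edges = default_planted_edges(),
                        base_partial = 0.10, noise_scale = 1, seed = 1L) {
  stopifnot(n_participants >= 1, sof_sd > 0, n_volumes > n_rois,
            rt_noise_sigma >= 0, tr > 0, noise_scale > 0)
  parc <- yeo17_parcellation()
  grp <- parc$group
  if (nrow(planted_edges)) {
    stopifnot(all(c("network_a", "network_b", "gamma") %in%
                    names(planted_edges)))
    touch_dmn <- grp[planted_edges$network_a] == "DMN" |
      grp[planted_edges$network_b] == "DMN"
    if (any(!touch_dmn)) stop("planted edges must touch a DMN subnetwork")
  }
  structure(list(n_participants = as.integer(n_participants),
                 sof_mean = sof_mean, sof_sd = sof_sd,
                 sof_bounds = sof_bounds, rt_noise_sigma = rt_noise_sigma,
                 n_rois = as.integer(n_rois),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 planted_edges = planted_edges, base_partial = base_partial,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_planted_edges <- function() {
  data.frame(network_a = c("Default A", "Default B", "Default C"),
             network_b = c("Default C", "Visual A", "Dorsal Attention B"),
             gamma = c(0.12, 0.12, -0.12), stringsAsFactors = FALSE)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulated learner responder
#'
#' Builds the responder callback \code{run_session} drives: on a test
#' probe with model-truth activation A, correctness is Bernoulli with the
#' logistic retrieval probability and the response time is the latency
#' equation's prediction times lognormal noise (capped at \code{rt_cap};
#' failed retrievals take long); study trials take lognormal time around
#' 1.5 s. Uses the session's RNG stream.
#'
#' @param sof_true The learner's true speed of forgetting.
#' @param params A \code{\link{model_params}}.
#' @param config A \code{\link{scheduler_config}}.
#' @param rt_noise_sigma Lognormal sdlog of RT noise; 0 gives noise-free
#'   latencies equal to the model prediction.
#' @param study_rt_mean Median study-trial duration in seconds. Default 1.5.
#' @return A function \code{(item, kind, A_true) -> list(correct, rt)}.
#' @export
simulate_learner <- function(sof_true, params = model_params(),
                             config = scheduler_config(),
                             rt_noise_sigma = 0.3, study_rt_mean = 1.5) {
  force(sof_true)
  responder <- function(item, kind, A_true) {
    noise <- function() if (rt_noise_sigma > 0)
      exp(stats::rnorm(1, 0, rt_noise_sigma)) else 1
    if (kind == "study")
      return(list(correct = TRUE, rt = study_rt_mean * noise()))
    p <- retrieval_probability(A_true)
    correct <- stats::runif(1) < p
    base_rt <- if (is.finite(A_true)) predicted_rt(A_true, params) else
      config$rt_cap
    list(correct = correct, rt = min(base_rt * noise(), config$rt_cap))
  }
  attr(responder, "sof_true") <- sof_true
  responder
}

#' Simulate the behavioral arm of a cohort
#'
#' Draws each participant's true speed of forgetting from the truncated
#' normal of the spec and runs a full adaptive session with a simulated
#' learner. All randomness flows from the spec's master seed, so reruns are
#' bit-identical.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param config A \code{\link{scheduler_config}}.
#' @param params A \code{\link{model_params}}.
#' @return List with \code{trials} (all participants' trial records),
#'   \code{truth} (data frame \code{participant}, \code{sof_true}),
#'   \code{states} (final scheduler states, holding the per-item phi
#'   estimates), and \code{spec}.
#' @export
simulate_cohort_behavior <- function(spec = cohort_spec(),
                                     config = scheduler_config(),
                                     params = model_params()) {
  set.seed(spec$seed)
  ids <- sprintf("p%02d", seq_len(spec$n_participants))
  sof <- rtruncnorm1(spec$n_participants, spec$sof_mean, spec$sof_sd,
                     spec$sof_bounds[1], spec$sof_bounds[2])
  states <- vector("list", spec$n_participants)
  logs <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    responder <- simulate_learner(sof[i], params, config,
                                  rt_noise_sigma = spec$rt_noise_sigma)
    sess <- run_session(responder, config, params, participant = ids[i])
    logs[[i]] <- sess$trials
    states[[i]] <- sess$state
  }
  names(states) <- ids
  list(trials = do.call(rbind, logs),
       truth = data.frame(participant = ids, sof_true = sof,
                          stringsAsFactors = FALSE),
       states = states, spec = spec)
}

#' Estimated phenotypes of a simulated cohort
#'
#' Applies the participant-level aggregation rule (mean final phi over
#' items presented at least three times) to each simulated session.
#'
#' @param sim Output of \code{\link{simulate_cohort_behavior}}.
#' @param min_presentations Qualification threshold. Default 3.
#' @return Data frame \code{participant}, \code{sof}, \code{n_items_used}.
#' @export
cohort_phenotypes <- function(sim, min_presentations = 3) {
  rows <- lapply(names(sim$states), function(id) {
    tr <- sim$trials[sim$trials$participant == id, , drop = FALSE]
    ph <- compute_sof(tr, sim$states[[id]]$phis, min_presentations)
    data.frame(participant = id, sof = ph$sof,
               n_items_used = ph$n_items_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Target partial-correlation matrix for one participant
#'
#' The shared base pattern (a weak chain of \code{base_partial} partial
#' correlations between consecutive networks, and \code{base_partial} on
#' every planted edge) plus, on each planted edge,
#' \code{gamma * (sof - sof_mean) / sof_sd}. Parameterized directly on the
#' precision matrix (unit diagonal, off-diagonal = minus the partial
#' correlation); if the result is not positive definite its eigenvalues are
#' clipped at a small floor.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param sof_true The participant's true speed of forgetting.
#' @return List with \code{partial} (17 x 17 target partial correlations)
#'   and \code{sigma} (the implied covariance).
#' @export
target_partial_matrix <- function(spec, sof_true) {
  parc <- yeo17_parcellation()
  nets <- parc$networks
  p <- length(nets)
  P <- matrix(0, p, p, dimnames = list(nets, nets))
  for (k in seq_len(p - 1L))
    P[k, k + 1L] <- P[k + 1L, k] <- spec$base_partial
  z <- (sof_true - spec$sof_mean) / spec$sof_sd
  pe <- spec$planted_edges
  for (k in seq_len(nrow(pe))) {
    a <- pe$network_a[k]; b <- pe$network_b[k]
    P[a, b] <- P[b, a] <- spec$base_partial + pe$gamma[k] * z
  }
  if (max(abs(P)) >= 1) stop("target partial correlation outside (-1, 1)")
  Om <- diag(p) - P
  ev <- eigen(Om, symmetric = TRUE)
  if (min(ev$values) <= 1e-8) {
    Om <- ev$vectors %*% diag(pmax(ev$values, 1e-4)) %*% t(ev$vectors)
    if (min(eigen(Om, symmetric = TRUE)$values) <= 0)
      stop("precision matrix not positive definite after projection")
  }
  Sigma <- solve(Om) * spec$noise_scale
  dimnames(Sigma) <- list(nets, nets)
  d <- sqrt(diag(Om))
  partial <- -Om / tcrossprod(d)
  diag(partial) <- 1
  dimnames(partial) <- list(nets, nets)
  list(partial = partial, sigma = Sigma)
}

#' Simulate one participant's ROI time series
#'
#' Independent multivariate-normal volumes under the participant's target
#' covariance (temporal autocorrelation is deliberately not modeled; the
#' partial-correlation pipeline is insensitive to it to first order).
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param sof_true The participant's true speed of forgetting.
#' @return Numeric matrix, \code{n_volumes} x \code{n_rois}, columns named
#'   by network. Uses the current RNG stream.
#' @export
simulate_timeseries <- function(spec, sof_true) {
  tgt <- target_partial_matrix(spec, sof_true)
  ts <- MASS::mvrnorm(spec$n_volumes, mu = rep(0, nrow(tgt$sigma)),
                      Sigma = tgt$sigma)
  colnames(ts) <- rownames(tgt$sigma)
  ts
}

#' Simulate the imaging arm of a cohort
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param truth Data frame \code{participant}, \code{sof_true} (from
#'   \code{\link{simulate_cohort_behavior}}).
#' @return Named list of time-series matrices, one per participant.
#'   Seeded from \code{spec$seed + 1} so the imaging stream is independent
#'   of the behavioral one.
#' @export
simulate_cohort_timeseries <- function(spec, truth) {
  set.seed(spec$seed + 1L)
  out <- lapply(seq_len(nrow(truth)), function(i)
    simulate_timeseries(spec, truth$sof_true[i]))
  names(out) <- truth$participant
  out
}
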