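#' Configuration of the adaptive paired-associate session
#'
#' Defaults reproduce the study design: 25 cue-target pairs learned in a
#' 12-minute session, a 600 ms inter-stimulus interval after correct
#' responses, and corrective feedback after errors. The activation threshold
#' and lookahead control the spacing policy: an item is due for a test when
#' its predicted activation a short lookahead into the future has dropped
#' below the threshold.
#'
#' @param n_items Number of paired associates in the pool. Default 25.
#' @param session_length Session duration in seconds. Default 720 (12 min).
#' @param isi_correct Inter-stimulus interval after a correct response, in
#'   seconds. Default 0.6.
#' @param feedback_duration Duration of corrective feedback after an
#'   incorrect response, in seconds. Fixed in simulation (the live task is
#'   participant-paced). Default 4.
#' @param activation_threshold Activation level below which an item is
#'   considered at risk of being forgotten and is scheduled for a test.
#'   Default -1.2, calibrated so a learner with phi near 0.3 completes
#'   about 140 trials in a 12-minute session.
#' @param lookahead Horizon in seconds at which predicted activation is
#'   evaluated when scheduling. Default 15.
#' @param phi_init Initial per-item speed-of-forgetting estimate. Default 0.3.
#' @param rt_cap Response-time ceiling in seconds; observed RTs are clamped
#'   here during estimation and incorrect responses count as this latency.
#'   Also the outlier cutoff used in fit diagnostics. Default 8.
#' @param phi_bounds Lower and upper bounds of the decay-intercept grid.
#'   Default c(0.10, 0.60).
#' @param phi_step Grid resolution for the per-item refit. Default 0.001.
#' @param encode_on_incorrect Whether an incorrect test trial appends a trace
#'   at feedback offset (the learner re-studies the pair during corrective
#'   feedback). Default TRUE.
#' @return An object of class \code{scheduler_config}.
#' @export
scheduler_config <- function(n_items = 25, session_length = 720,
                             isi_correct = 0.6, feedback_duration = 4,
                             activation_threshold = -1.2, lookahead = 15,
                             phi_init = 0.3, rt_cap = 8,
                             phi_bounds = c(0.10, 0.60), phi_step = 0.001,
                             encode_on_incorrect = TRUE) {
  stopifnot(n_items >= 1, session_length >= 0, isi_correct > 0,
            feedback_duration > 0, lookahead > 0, phi_init > 0, rt_cap > 0,
            length(phi_bounds) == 2L, phi_bounds[1] > 0,
            phi_bounds[2] > phi_bounds[1], phi_step > 0)
  structure(list(n_items = as.integer(n_items),
                 session_length = session_length, isi_correct = isi_correct,
                 feedback_duration = feedback_duration,
                 activation_threshold = activation_threshold,
                 lookahead = lookahead, phi_init = phi_init, rt_cap = rt_cap,
                 phi_bounds = phi_bounds, phi_step = phi_step,
                 encode_on_incorrect = isTRUE(encode_on_incorrect)),
            class = "scheduler_config")
}

#' Fresh scheduler state
#'
#' @param config A \code{\link{scheduler_config}}.
#' @param items Optional character vector of item identifiers; defaults to
#'   \code{"item01"..}.
#' @return An object of class \code{scheduler_state} holding per-item
#'   encoding histories, per-item phi estimates, the set of introduced items
#'   and the session clock.
#' @export
new_scheduler_state <- function(config = scheduler_config(), items = NULL) {
  if (is.null(items))
    items <- sprintf("item%02d", seq_len(config$n_items))
  if (length(items) == 0L) stop("empty item pool")
  histories <- stats::setNames(lapply(items, encoding_history), items)
  structure(list(items = items, histories = histories,
                 phis = stats::setNames(rep(config$phi_init, length(items)), items),
                 introduced = character(0), clock = 0),
            class = "scheduler_state")
}

#' Choose the next trial
#'
#' Among introduced items, predicted activation at \code{clock + lookahead}
#' is computed from each item's current traces; the lowest-activation item
#' whose prediction falls below the threshold is tested. If no item is at
#' risk and unintroduced items remain, a new item is introduced as a study
#' trial; once all items are introduced, the lowest-activation item is
#' tested regardless of the threshold.
#'
#' @param state A \code{\link{new_scheduler_state}} object.
#' @param config A \code{\link{scheduler_config}}.
#' @return A list with elements \code{item} and \code{kind}
#'   (\code{"study"} or \code{"test"}).
#' @export
next_trial <- function(state, config = scheduler_config()) {
  if (length(state$items) == 0L) stop("empty item pool")
  t_eval <- state$clock + config$lookahead
  if (length(state$introduced)) {
    A <- vapply(state$introduced, function(it)
      activation_or_neg_inf(state$histories[[it]], t_eval), numeric(1))
    due <- A < config$activation_threshold
    if (any(due)) {
      item <- state$introduced[due][which.min(A[due])]
      return(list(item = item, kind = "test"))
    }
  }
  remaining <- setdiff(state$items, state$introduced)
  if (length(remaining))
    return(list(item = remaining[1L], kind = "study"))
  item <- state$introduced[which.min(A)]
  list(item = item, kind = "test")
}

# Encoding-event times implied by an item's trial records under the
# re-encoding policy: study trials and correct test trials encode at onset;
# incorrect test trials (optionally) re-encode when corrective feedback
# appears, i.e. at onset + rt (feedback ends exactly at the next trial's
# onset, so encoding there would collide with it).
item_encoding_times <- function(trials, config) {
  enc <- trials$kind == "study" | (trials$kind == "test" & trials$correct)
  times <- trials$onset_s[enc]
  if (config$encode_on_incorrect) {
    bad <- trials$kind == "test" & !trials$correct
    times <- c(times, trials$onset_s[bad] + trials$rt_s[bad])
  }
  sort(times)
}

# Decay rates of successive traces at `enc_times`, for each candidate phi.
# Returns a length(phis) x length(enc_times) matrix. Row-vectorized over the
# candidate grid; within a row the recursion is inherently sequential
# because each trace's decay depends on activation under earlier decays.
replay_decays <- function(enc_times, phis, params) {
  n <- length(enc_times); m <- length(phis)
  D <- matrix(0, m, n)
  for (k in seq_len(n)) {
    if (k == 1L) {
      A <- rep(-Inf, m)
    } else {
      lags <- enc_times[k] - enc_times[seq_len(k - 1L)]
      S <- exp(-D[, seq_len(k - 1L), drop = FALSE] *
                 matrix(log(lags), m, k - 1L, byrow = TRUE))
      A <- log(rowSums(S))
    }
    D[, k] <- params$c * exp(A) + phis
  }
  D
}

# Activation at time `t` for each candidate phi, given replayed decays.
replay_activation <- function(enc_times, D, t) {
  use <- enc_times < t
  if (!any(use)) return(rep(-Inf, nrow(D)))
  lags <- t - enc_times[use]
  S <- exp(-D[, use, drop = FALSE] *
             matrix(log(lags), nrow(D), sum(use), byrow = TRUE))
  log(rowSums(S))
}

#' Re-estimate an item's speed of forgetting from its test trials
#'
#' Grid refit: for each candidate phi on the configured grid, the item's
#' trace decay rates are replayed from its encoding events and the model's
#' predicted response time is computed at every past correct test trial;
#' the phi minimizing the squared log-latency error against the observed
#' (clamped) response times is returned, so slow responses push phi up and
#' fast responses pull it down. Residuals are taken on the log scale
#' because the latency model's noise is multiplicative; this makes the
#' refit the maximum-likelihood estimate under lognormal response-time
#' noise. Ties break toward the smaller phi. Retrieval latency is only
#' defined when retrieval succeeds, so incorrect responses enter the refit
#' only while an item has no correct test yet: they then count as if they
#' took \code{rt_cap} seconds, which drives phi upward after an early
#' error, per the adjustment rule.
#'
#' @param trials Data frame of one item's trial records so far, with columns
#'   \code{onset_s}, \code{kind}, \code{correct}, \code{rt_s}.
#' @param current_phi Incumbent estimate, returned unchanged when the item
#'   has no test trials yet.
#' @param params A \code{\link{model_params}}.
#' @param config A \code{\link{scheduler_config}}.
#' @return The re-estimated phi (scalar).
#' @export
update_phi <- function(trials, current_phi, params = model_params(),
                       config = scheduler_config()) {
  tests <- trials[trials$kind == "test", , drop = FALSE]
  if (nrow(tests) == 0L) return(current_phi)
  if (any(tests$correct)) tests <- tests[tests$correct, , drop = FALSE]
  obs <- pmin(tests$rt_s, config$rt_cap)
  obs[!tests$correct] <- config$rt_cap
  enc_times <- item_encoding_times(trials, config)
  phis <- seq(config$phi_bounds[1], config$phi_bounds[2], by = config$phi_step)
  D <- replay_decays(enc_times, phis, params)
  sse <- numeric(length(phis))
  for (j in seq_len(nrow(tests))) {
    A <- replay_activation(enc_times, D, tests$onset_s[j])
    pred <- params$t0 + params$F * exp(-A)
    sse <- sse + (log(obs[j]) - log(pred))^2
  }
  phis[which.min(sse)]
}

#' Run a simulated adaptive learning session
#'
#' Drives the scheduler against a responder callback, emitting trial records
#' and updating per-item phi estimates after every test response. The clock
#' advances by the response time plus the post-trial interval (short ISI
#' after correct responses, feedback duration after errors); trials are
#' emitted until the clock reaches the session length.
#'
#' @param responder Function \code{(item, kind, A_true) -> list(correct, rt)}
#'   simulating (or replaying) a learner; \code{A_true} is the item's current
#'   model activation (\code{-Inf} for a first study). When the responder
#'   carries a \code{sof_true} attribute (as those built by
#'   \code{\link{simulate_learner}} do), the session maintains a parallel
#'   ground-truth set of histories whose decay rates are replayed under that
#'   value, and \code{A_true} is the \emph{true} activation; the scheduler
#'   itself only ever sees its own estimates.
#' @param config A \code{\link{scheduler_config}}.
#' @param params A \code{\link{model_params}}.
#' @param participant Participant identifier stamped on the records.
#' @return A list with \code{trials} (data frame:
#'   \code{participant,item,onset_s,kind,correct,rt_s}) and \code{state}
#'   (final \code{scheduler_state}, including final per-item phi estimates).
#' @export
run_session <- function(responder, config = scheduler_config(),
                        params = model_params(), participant = "p01") {
  state <- new_scheduler_state(config)
  phi_true <- attr(responder, "sof_true", exact = TRUE)
  true_hist <- state$histories
  rows <- vector("list", 512L)
  n <- 0L
  while (state$clock < config$session_length) {
    nt <- next_trial(state, config)
    item <- nt$item; kind <- nt$kind
    h <- if (is.null(phi_true)) state$histories[[item]] else true_hist[[item]]
    t_probe <- max(state$clock,
                   if (length(h$times)) max(h$times) + 1e-6 else -Inf)
    A_true <- activation_or_neg_inf(h, t_probe)
    resp <- responder(item, kind, A_true)
    correct <- if (kind == "study") TRUE else isTRUE(resp$correct)
    rt <- resp$rt
    if (!is.numeric(rt) || rt <= 0) stop("responder returned non-positive rt")
    n <- n + 1L
    if (n > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[n]] <- data.frame(participant = participant, item = item,
                            onset_s = state$clock, kind = kind,
                            correct = correct, rt_s = rt,
                            stringsAsFactors = FALSE)
    state$introduced <- union(state$introduced, item)
    item_trials <- do.call(rbind, Filter(function(r) r$item == item,
                                         rows[seq_len(n)]))
    if (kind == "test")
      state$phis[[item]] <- update_phi(item_trials, state$phis[[item]],
                                       params, config)
    # rebuild the item's history from its encoding events under the current
    # phi estimate, so traces stay consistent with the latest refit
    enc_times <- item_encoding_times(item_trials, config)
    d <- replay_decays(enc_times, state$phis[[item]], params)
    state$histories[[item]] <- encoding_history(item, enc_times, as.numeric(d))
    if (!is.null(phi_true)) {
      dt <- replay_decays(enc_times, phi_true, params)
      true_hist[[item]] <- encoding_history(item, enc_times, as.numeric(dt))
    }
    state$clock <- state$clock + rt +
      if (correct) config$isi_correct else config$feedback_duration
  }
  trials <- if (n) do.call(rbind, rows[seq_len(n)]) else
    data.frame(participant = character(0), item = character(0),
               onset_s = numeric(0), kind = character(0),
               correct = logical(0), rt_s = numeric(0))
  rownames(trials) <- NULL
  list(trials = trials, state = state)
}
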