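#' Model parameters for the trace-decay memory model
#'
#' Bundles the fixed constants of the declarative-memory model: the decay
#' scaling factor \code{c}, the non-memory response-time offset \code{t0}
#' (seconds), and the latency scale \code{F}.
#'
#' @param c Decay scaling factor applied to the exponentiated activation at
#'   encoding time. Dimensionless, must be positive. Default 0.25.
#' @param t0 Fixed response-time offset in seconds for perceptual encoding and
#'   motor execution. Must be non-negative. Default 0.3.
#' @param F Latency scaling constant (seconds per unit of exp(-A)). Must be
#'   positive. Default 1.
#' @return An object of class \code{model_params}.
#' @examples
#' p <- model_params()
#' predicted_rt(0, p) # 1.3 s at activation zero
#' @export
model_params <- function(c = 0.25, t0 = 0.3, F = 1) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0,
            is.numeric(t0), length(t0) == 1L, t0 >= 0,
            is.numeric(F), length(F) == 1L, F > 0)
  structure(list(c = c, t0 = t0, F = F), class = "model_params")
}

#' Encoding history of a single memory item
#'
#' A memory item accumulates one episodic trace per encoding event; each trace
#' carries its creation time (seconds since session start) and its own decay
#' rate. Histories are value objects: \code{\link{encode}} returns a new
#' history and never mutates its input.
#'
#' @param item Item identifier (any scalar).
#' @param times Numeric vector of trace creation times, strictly increasing.
#' @param decays Numeric vector of per-trace decay rates, same length as
#'   \code{times}, all positive.
#' @return An object of class \code{encoding_history}.
#' @export
encoding_history <- function(item = NA, times = numeric(0), decays = numeric(0)) {
  stopifnot(is.numeric(times), is.numeric(decays), length(times) == length(decays))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("trace times must be strictly increasing")
  if (any(decays <= 0)) stop("decay rates must be positive")
  structure(list(item = item, times = as.numeric(times),
                 decays = as.numeric(decays)),
            class = "encoding_history")
}

#' @export
print.encoding_history <- function(x, ...) {
  cat(sprintf("<encoding_history> item=%s, %d trace(s)\n",
              format(x$item), length(x$times)))
  if (length(x$times))
    print(data.frame(t = x$times, d = x$decays))
  invisible(x)
}

#' Memory activation at a given time
#'
#' Activation is the log of the summed power-law-decaying strengths of all
#' traces: \eqn{A(m, t) = \log \sum_i (t - t_i)^{-d_i}}. It governs both the
#' probability and the latency of retrieval.
#'
#' @param history An \code{\link{encoding_history}}.
#' @param t Query time in seconds; must be strictly later than every trace in
#'   the history.
#' @return Log-activation (unitless real).
#' @examples
#' h <- encoding_history("pair1", times = 0, decays = 0.3)
#' activation(h, 600) # -0.3 * log(600)
#' @export
activation <- function(history, t) {
  stopifnot(inherits(history, "encoding_history"),
            is.numeric(t), length(t) == 1L, is.finite(t))
  if (length(history$times) == 0L)
    stop("no-trace: activation undefined for an empty history (treat as -Inf)")
  if (t <= max(history$times))
    stop("query time must exceed every trace creation time")
  log(sum((t - history$times)^(-history$decays)))
}

# Activation with the empty-history convention A = -Inf (empty log-sum).
# Internal helper: schedulers and decay computations use this limit directly.
activation_or_neg_inf <- function(history, t) {
  if (length(history$times) == 0L) return(-Inf)
  activation(history, t)
}

#' Decay rate of a new trace
#'
#' A trace created at time \code{t_new} inherits a decay rate
#' \eqn{d = c e^{A(m, t_{new})} + \phi}, where the activation is evaluated on
#' the history as it stands \emph{before} the new trace is added. For an empty
#' history the empty-sum limit \eqn{A = -\infty} gives \eqn{d = \phi}: the
#' first trace of an item decays at exactly the item's speed of forgetting.
#'
#' @param history An \code{\link{encoding_history}} (state before encoding).
#' @param t_new Creation time of the new trace (seconds); must exceed all
#'   existing trace times.
#' @param phi Speed-of-forgetting parameter (decay intercept).
#' @param params A \code{\link{model_params}} object.
#' @return The new trace's decay rate (dimensionless, always >= phi).
#' @examples
#' decay_rate(encoding_history(), 0, phi = 0.3)           # 0.3 (first trace)
#' h <- encoding_history(times = 0, decays = 0.3)
#' decay_rate(h, 10, phi = 0.3)                           # ~0.4253
#' @export
decay_rate <- function(history, t_new, phi, params = model_params()) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi > 0)
  if (length(history$times) && t_new <= max(history$times))
    stop("new trace time must exceed all existing trace times")
  A <- activation_or_neg_inf(history, t_new)
  params$c * exp(A) + phi
}

#' Append an encoding event to a history
#'
#' Computes the decay rate of the new trace under \code{phi} and returns a new
#' history with the trace appended; the input history is unchanged.
#'
#' @inheritParams decay_rate
#' @return A new \code{\link{encoding_history}}.
#' @export
encode <- function(history, t_new, phi, params = model_params()) {
  d <- decay_rate(history, t_new, phi, params)
  encoding_history(history$item, c(history$times, t_new), c(history$decays, d))
}

#' Retrieval probability from activation
#'
#' The logistic link \eqn{P(m) = 1 / (1 + e^{-A(m)})}; an activation of
#' \code{-Inf} (never-encoded item) maps to probability 0.
#'
#' @param A Log-activation (finite real or -Inf).
#' @return Probability in [0, 1).
#' @examples
#' retrieval_probability(0)    # 0.5
#' retrieval_probability(-Inf) # 0
#' @export
retrieval_probability <- function(A) {
  stopifnot(is.numeric(A))
  ifelse(A == -Inf, 0, stats::plogis(A))
}

#' Predicted response time from activation
#'
#' Retrieval latency \eqn{T = t_0 + F e^{-A(m)}} in seconds: strictly
#' decreasing in activation, bounded below by the non-memory offset
#' \code{t0}.
#'
#' @param A Log-activation (finite real; vectorized).
#' @param params A \code{\link{model_params}} object.
#' @return Predicted response time(s) in seconds.
#' @examples
#' predicted_rt(0) # 1.3
#' @export
predicted_rt <- function(A, params = model_params()) {
  stopifnot(is.numeric(A), all(is.finite(A)))
  params$t0 + params$F * exp(-A)
}

#' Forgetting curve after a single unrehearsed encoding
#'
#' Evaluates activation and retrieval probability on a time grid following a
#' single trace encoded at time 0 with decay rate \eqn{d_1 = \phi} (the
#' first-trace limit). With \eqn{\phi = 0.3} the retrieval probability drops
#' below 25\% within the first ten minutes.
#'
#' @param phi Speed of forgetting.
#' @param horizon Last time point in seconds.
#' @param step Grid spacing in seconds.
#' @param params A \code{\link{model_params}} object.
#' @return A data frame with columns \code{t}, \code{A}, \code{P}.
#' @examples
#' fc <- forgetting_curve(0.3, horizon = 600, step = 10)
#' tail(fc, 1) # P just under 0.128 at 600 s
#' @export
forgetting_curve <- function(phi, horizon, step, params = model_params()) {
  stopifnot(horizon > step, step > 0)
  h <- encode(encoding_history("curve"), 0, phi, params)
  t <- seq(step, horizon, by = step)
  A <- vapply(t, function(tt) activation(h, tt), numeric(1))
  data.frame(t = t, A = A, P = retrieval_probability(A))
}
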