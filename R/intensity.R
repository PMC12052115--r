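#' Baseline intensity
#'
#' History-independent component of the conditional intensity:
#' \deqn{\lambda^b(t) = \theta t^{\theta - 1} e^{\alpha^\top x},}
#' a power-law time trend scaled by a log-linear covariate term. For
#' `theta < 1` the power law is singular at the origin, so `t` must be
#' strictly positive.
#'
#' @param params a [model_params()] object.
#' @param x covariate vector, same length as `params$alpha`.
#' @param t positive time (days); may be a vector.
#' @return non-negative intensity value(s).
#' @examples
#' baseline_intensity(model_params(theta = 2, alpha = 0), x = 0, t = 3) # 6
#' @export
baseline_intensity <- function(params, x, t) {
  stopifnot(inherits(params, "tpp_params"))
  check_covariate_dim(x, params$alpha)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be strictly positive (power-law origin)", call. = FALSE)
  lin <- if (length(x)) sum(params$alpha * x) else 0
  params$theta * t^(params$theta - 1) * exp(lin)
}

#' Triggering (self-exciting) intensity
#'
#' History-dependent component of the conditional intensity: each past event
#' at \eqn{t_j < t} contributes an exponentially decaying excitation
#' \eqn{\beta \gamma e^{-\gamma (t - t_j)}}. Events at or after `t`
#' contribute nothing (strict inequality).
#'
#' @param params a [model_params()] object.
#' @param history numeric vector of past event times, all strictly before `t`.
#' @param t evaluation time.
#' @return non-negative intensity; `0` for an empty history.
#' @examples
#' triggering_intensity(model_params(beta = 1, gamma = 1), history = 0, t = log(2))
#' @export
triggering_intensity <- function(params, history, t) {
  stopifnot(inherits(params, "tpp_params"), length(t) == 1L, is.finite(t))
  history <- as.numeric(history)
  if (length(history) == 0L) return(0)
  if (any(history >= t))
    stop("all history times must be strictly before `t`", call. = FALSE)
  params$beta * params$gamma * sum(exp(-params$gamma * (t - history)))
}

#' Total conditional intensity
#'
#' Sum of [baseline_intensity()] and [triggering_intensity()] evaluated with
#' the recipient's events strictly before `t`:
#' \deqn{\lambda_i(t \mid H_i(t)) = \theta t^{\theta-1} e^{\alpha^\top x_i}
#'   + \sum_{j: t_{ij} < t} \beta \gamma e^{-\gamma (t - t_{ij})}.}
#'
#' @param params a [model_params()] object.
#' @param recipient a [recipient_history()] object.
#' @param t positive scalar time.
#' @return non-negative intensity.
#' @export
total_intensity <- function(params, recipient, t) {
  stopifnot(inherits(recipient, "recipient_history"))
  hist <- recipient$event_times[recipient$event_times < t]
  baseline_intensity(params, recipient$covariates, t) +
    triggering_intensity(params, hist, t)
}

#' Cumulative intensity (compensator)
#'
#' Closed-form integral of the conditional intensity from 0 to `t_end`:
#' \deqn{\Lambda(t) = t^{\theta} e^{\alpha^\top x}
#'   + \beta \sum_{j: t_j < t} \left(1 - e^{-\gamma (t - t_j)}\right).}
#' Monotone non-decreasing in `t_end`; events at or after `t_end` are
#' ignored. `t_end` beyond the recipient's own observation window is
#' allowed (extrapolation of the fitted intensity).
#'
#' @inheritParams total_intensity
#' @param t_end positive scalar horizon (days).
#' @return non-negative cumulative intensity.
#' @export
cumulative_intensity <- function(params, recipient, t_end) {
  stopifnot(inherits(params, "tpp_params"), inherits(recipient, "recipient_history"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("`t_end` must be a positive finite scalar", call. = FALSE)
  check_covariate_dim(recipient$covariates, params$alpha)
  lin <- if (length(recipient$covariates))
    sum(params$alpha * recipient$covariates) else 0
  hist <- recipient$event_times[recipient$event_times < t_end]
  trig <- if (length(hist))
    params$beta * sum(1 - exp(-params$gamma * (t_end - hist))) else 0
  t_end^params$theta * exp(lin) + trig
}

#' Probability of at least one event by a horizon
#'
#' The risk of an event by time `t_end` is `1 - exp(-Lambda(t_end))` with
#' `Lambda` the cumulative intensity of [cumulative_intensity()].
#'
#' @inheritParams cumulative_intensity
#' @return probability in `[0, 1)`.
#' @export
overdose_risk <- function(params, recipient, t_end) {
  1 - exp(-cumulative_intensity(params, recipient, t_end))
}
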