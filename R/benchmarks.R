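# Poisson benchmarks: the memoryless comparison models fitted and evaluated
# through the same interfaces as the triggering model.
#
#  * HPP: constant intensity lambda_i(t) = theta; closed-form MLE.
#  * NHPP: the covariate-adjusted power-law baseline with the triggering
#    term pinned at zero — i.e. the full model with beta bounds [0, 0].

#' Fit a homogeneous Poisson process
#'
#' Closed-form maximum likelihood: `theta-hat` is the total event count
#' divided by the total observation time `sum(T_i)`.
#'
#' @param cohort a `tpp_cohort`.
#' @return a `tpp_fit` with `family = "HPP"`; `params$theta` holds the rate
#'   (per day), the covariate vector is zero.
#' @examples
#' # 4 events over 2 days -> rate 2/day
#' r <- recipient_history("a", c(0.2, 0.5, 1.1, 1.9), numeric(0), 2)
#' fit_hpp(new_cohort(list(r)))$params$theta
#' @export
fit_hpp <- function(cohort) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  n_ev <- total_events(cohort)
  Ttot <- sum(cohort_obs_lengths(cohort))
  if (Ttot <= 0) stop("total observation time is zero", call. = FALSE)
  if (n_ev == 0L) {
    warning("cohort has no events; HPP rate estimated as 0", call. = FALSE)
    rate <- 0
    ll <- 0
  } else {
    rate <- n_ev / Ttot
    ll <- n_ev * log(rate) - rate * Ttot
  }
  p <- length(cohort$covariate_names)
  params <- model_params(theta = max(rate, .Machine$double.xmin),
                         alpha = stats::setNames(rep(0, p), cohort$covariate_names),
                         beta = 0, gamma = 1)
  params$theta <- rate  # allow the boundary value 0 on the stored estimate
  new_tpp_fit(params = params, log_lik = ll, n_params = 1L,
              n_events = max(n_ev, 1L), converged = TRUE, n_iter = 0L,
              message = "closed form", family = "HPP")
}

#' Fit a non-homogeneous Poisson process
#'
#' The covariate-adjusted power-law intensity
#' \eqn{\lambda_i(t) = \theta t^{\theta-1} e^{\alpha^\top x_i}} without
#' self-excitation: implemented exactly as [fit_mle()] with the `beta`
#' bounds collapsed to `[0, 0]` (and `gamma` pinned, since it is
#' unidentified when `beta = 0`). Free parameters: `theta` and `alpha`.
#'
#' @inheritParams fit_mle
#' @return a `tpp_fit` with `family = "NHPP"`.
#' @export
fit_nhpp <- function(cohort, init = NULL, control = list()) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  p <- length(cohort$covariate_names)
  b <- default_bounds(p)
  lower <- b$lower; upper <- b$upper
  lower[2L + p] <- upper[2L + p] <- 0      # beta pinned at 0
  g0 <- if (is.null(init)) 0.1 else init$gamma
  lower[3L + p] <- upper[3L + p] <- g0     # gamma irrelevant, pinned
  fit <- fit_mle(cohort, init = init, lower = lower, upper = upper,
                 control = control)
  fit$family <- "NHPP"
  fit
}

#' Predicted event count for a benchmark model
#'
#' The expected number of events among the `M` test recipients over the
#' window `[0, L)` under a memoryless benchmark:
#' HPP \eqn{M \hat\theta L}; NHPP
#' \eqn{\sum_i L^{\hat\theta} e^{\hat\alpha^\top x_i}}.
#'
#' @param model a `tpp_fit` of family `"HPP"` or `"NHPP"`.
#' @param test a `tpp_cohort` of test recipients.
#' @param horizon positive window length `L` in days.
#' @return expected total count (non-negative scalar).
#' @export
predict_counts_benchmark <- function(model, test, horizon) {
  stopifnot(inherits(model, "tpp_fit"), inherits(test, "tpp_cohort"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("`horizon` must be a positive scalar", call. = FALSE)
  if (model$family == "HPP")
    return(length(test$recipients) * model$params$theta * horizon)
  if (model$family %in% c("NHPP", "triggering")) {
    p <- length(model$params$alpha)
    if (p != length(test$covariate_names))
      stop("model covariate dimension does not match the test cohort", call. = FALSE)
    X <- cohort_covariate_matrix(test)
    lin <- if (p > 0) as.numeric(X %*% model$params$alpha) else
      numeric(length(test$recipients))
    return(sum(horizon^model$params$theta * exp(lin)))
  }
  stop("unknown benchmark family: ", model$family, call. = FALSE)
}
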