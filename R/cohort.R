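#' One recipient's event history
#'
#' Container for a single recipient: an ordered sequence of event times
#' (days since the recipient's index date), a fixed static covariate vector,
#' and the administrative censoring horizon `obs_length` (days from index
#' date to the end of observation). The time origin `t = 0` is the index
#' date and the observation interval is the half-open `[0, obs_length)`.
#'
#' Events recorded exactly at `t = 0` would make the power-law baseline
#' singular for `theta < 1`; they are shifted to `epsilon` (default `1e-6`
#' days) with a warning.
#'
#' @param recipient_id scalar identifier (coerced to character).
#' @param event_times numeric vector of event times in days; must be
#'   strictly increasing after sorting (no tied times) and lie in
#'   `[0, obs_length)`.
#' @param covariates named or unnamed numeric vector of dummy-encoded
#'   covariates.
#' @param obs_length positive scalar, days of observation.
#' @param epsilon replacement time for events recorded exactly at 0.
#'
#' @return An object of class `"recipient_history"`.
#' @examples
#' recipient_history("r1", c(12, 40.5, 200), covariates = c(male = 1), 365)
#' @export
recipient_history <- function(recipient_id, event_times = numeric(0),
                              covariates = numeric(0), obs_length,
                              epsilon = 1e-6) {
  if (!is.numeric(obs_length) || length(obs_length) != 1L ||
      !is.finite(obs_length) || obs_length <= 0)
    stop("`obs_length` must be a positive finite scalar", call. = FALSE)
  event_times <- sort(as.numeric(event_times))
  if (anyNA(event_times)) stop("event times must not contain NA", call. = FALSE)
  if (length(event_times) && any(event_times < 0))
    stop("event times must be non-negative", call. = FALSE)
  if (length(event_times) && any(event_times == 0)) {
    warning(sprintf("recipient %s: event at t = 0 shifted to %g days",
                    as.character(recipient_id), epsilon), call. = FALSE)
    event_times[event_times == 0] <- epsilon
    event_times <- sort(event_times)
  }
  if (length(event_times) > 1L && any(diff(event_times) <= 0))
    stop(sprintf("recipient %s: event times must be strictly increasing (ties found)",
                 as.character(recipient_id)), call. = FALSE)
  if (length(event_times) && any(event_times >= obs_length))
    stop(sprintf("recipient %s: event times must lie in [0, obs_length)",
                 as.character(recipient_id)), call. = FALSE)
  cov_names <- names(covariates)
  covariates <- as.numeric(covariates)
  names(covariates) <- cov_names
  structure(
    list(recipient_id = as.character(recipient_id),
         event_times = event_times,
         covariates = covariates,
         obs_length = as.numeric(obs_length)),
    class = "recipient_history"
  )
}

#' @export
print.recipient_history <- function(x, ...) {
  cat(sprintf("Recipient %s: %d events over %.1f days\n",
              x$recipient_id, length(x$event_times), x$obs_length))
  invisible(x)
}

#' A cohort of recipients
#'
#' Bundles `recipient_history` records that share a common covariate
#' dimension. Optionally carries the dummy-encoding map so that covariate
#' coefficients stay interpretable.
#'
#' @param recipients list of [recipient_history()] objects, at least one.
#' @param covariate_names character vector naming the covariate columns;
#'   defaults to the names on the first recipient's covariate vector.
#'
#' @return An object of class `"tpp_cohort"`.
#' @export
new_cohort <- function(recipients, covariate_names = NULL) {
  if (!is.list(recipients) || length(recipients) < 1L)
    stop("a cohort needs at least one recipient", call. = FALSE)
  if (!all(vapply(recipients, inherits, logical(1), "recipient_history")))
    stop("all elements must be `recipient_history` objects", call. = FALSE)
  p <- length(recipients[[1L]]$covariates)
  dims <- vapply(recipients, function(r) length(r$covariates), integer(1))
  if (any(dims != p))
    stop("all recipients must share the covariate dimension", call. = FALSE)
  if (is.null(covariate_names)) {
    covariate_names <- names(recipients[[1L]]$covariates)
    if (is.null(covariate_names) && p > 0)
      covariate_names <- paste0("x", seq_len(p))
  }
  if (length(covariate_names) != p)
    stop("`covariate_names` must have one entry per covariate", call. = FALSE)
  structure(
    list(recipients = recipients, covariate_names = as.character(covariate_names)),
    class = "tpp_cohort"
  )
}

#' @export
print.tpp_cohort <- function(x, ...) {
  n_ev <- total_events(x)
  cat(sprintf("Cohort: %d recipients, %d events, %d covariates\n",
              length(x$recipients), n_ev, length(x$covariate_names)))
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.tpp_cohort <- function(x) length(x$recipients)

#' Total number of events in a cohort
#' @param cohort a `tpp_cohort`.
#' @return integer event count summed over recipients.
#' @export
total_events <- function(cohort) {
  sum(vapply(cohort$recipients, function(r) length(r$event_times), integer(1)))
}

#' Subset a cohort by recipient position
#' @param cohort a `tpp_cohort`.
#' @param idx integer or logical index into the recipient list.
#' @return a `tpp_cohort` containing the selected recipients.
#' @export
subset_cohort <- function(cohort, idx) {
  new_cohort(cohort$recipients[idx], covariate_names = cohort$covariate_names)
}

# internal: N x p covariate matrix
cohort_covariate_matrix <- function(cohort) {
  p <- length(cohort$covariate_names)
  X <- matrix(0, nrow = length(cohort$recipients), ncol = p,
              dimnames = list(NULL, cohort$covariate_names))
  if (p > 0)
    for (i in seq_along(cohort$recipients))
      X[i, ] <- cohort$recipients[[i]]$covariates
  X
}

cohort_obs_lengths <- function(cohort) {
  vapply(cohort$recipients, function(r) r$obs_length, numeric(1))
}
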