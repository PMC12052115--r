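# Likelihood machinery.
#
# The log-likelihood of the process over per-recipient windows [0, T_i) is
#   l(Theta) = sum_i [ sum_j log lambda_i(t_ij) - Lambda_i(T_i) ]
# with the compensator Lambda available in closed form. The triggering sum
# at the j-th event, A_ij = sum_{k<j} exp(-gamma (t_ij - t_ik)), obeys the
# exponential-kernel recursion A_i1 = 0, A_ij = (A_i,j-1 + 1) d_ij with
# d_ij = exp(-gamma gap_ij). We run that recursion across all recipients at
# once on gap matrices padded with Inf, which keeps every likelihood
# evaluation vectorized (no per-event R loops) and immune to overflow: only
# non-negative gaps are ever exponentiated.

LOGLIK_SENTINEL <- -1e10  # returned instead of -Inf/NaN so L-BFGS-B can retreat

# internal: precompute everything about a cohort the likelihood needs
build_lik_data <- function(cohort) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  n <- length(cohort$recipients)
  counts <- vapply(cohort$recipients, function(r) length(r$event_times), integer(1))
  maxn <- max(counts, 0L)
  Tmat <- matrix(NA_real_, n, maxn)   # event times, padded NA
  Gmat <- matrix(Inf, n, maxn)        # gaps t_j - t_{j-1}, padded Inf
  for (i in seq_len(n)) {
    ti <- cohort$recipients[[i]]$event_times
    if (length(ti)) {
      Tmat[i, seq_along(ti)] <- ti
      Gmat[i, seq_along(ti)] <- c(Inf, diff(ti))  # first gap unused (A_1 = 0)
    }
  }
  list(
    n = n, p = length(cohort$covariate_names), counts = counts, maxn = maxn,
    X = cohort_covariate_matrix(cohort),
    Ti = cohort_obs_lengths(cohort),
    Tmat = Tmat, Gmat = Gmat, mask = !is.na(Tmat),
    total_events = sum(counts)
  )
}

# internal: log-likelihood from precomputed data; returns LOGLIK_SENTINEL on
# non-finite values (e.g. log of an underflowed intensity)
loglik_from_data <- function(theta, alpha, beta, gamma, dat) {
  lin <- if (dat$p > 0) as.numeric(dat$X %*% alpha) else numeric(dat$n)
  ebx <- exp(lin)
  comp <- dat$Ti^theta * ebx
  ll <- 0
  if (dat$maxn > 0L) {
    # triggering recursion, all recipients in lockstep over event index j
    D <- exp(-gamma * dat$Gmat)            # padded entries -> exp(-Inf) = 0
    A <- matrix(0, dat$n, dat$maxn)
    if (dat$maxn > 1L)
      for (j in 2:dat$maxn) A[, j] <- (A[, j - 1L] + 1) * D[, j]
    lam <- theta * dat$Tmat^(theta - 1) * ebx + beta * gamma * A
    logs <- log(lam[dat$mask])
    if (any(!is.finite(logs))) return(LOGLIK_SENTINEL)
    # compensator triggering term: beta * sum_j (1 - exp(-gamma (T_i - t_ij)))
    Etrig <- exp(-gamma * (dat$Ti - dat$Tmat))  # NA on padding
    comp <- comp + beta * rowSums(1 - Etrig, na.rm = TRUE)
    ll <- sum(logs)
  }
  ll <- ll - sum(comp)
  if (!is.finite(ll)) LOGLIK_SENTINEL else ll
}

#' Log-likelihood of the triggering point process
#'
#' Evaluates
#' \deqn{\ell(\Theta) = \sum_{i=1}^N \Big[ \sum_{j=1}^{n_i}
#'   \log \lambda_i(t_{ij}) - \Lambda_i(T_i) \Big]}
#' using the closed-form compensator, with per-recipient censoring horizons
#' \eqn{T_i}. If any event intensity underflows to zero the function
#' returns the documented large negative sentinel (`-1e10`) instead of
#' `-Inf`, so bounded optimizers can retreat.
#'
#' @param params a [model_params()] object whose `alpha` matches the
#'   cohort's covariate dimension.
#' @param cohort a `tpp_cohort`.
#' @return scalar log-likelihood.
#' @examples
#' r <- recipient_history("a", c(1, 4), covariates = numeric(0), obs_length = 10)
#' log_likelihood(model_params(theta = 1), new_cohort(list(r)))  # 0 - 10 = -10
#' @export
log_likelihood <- function(params, cohort) {
  stopifnot(inherits(params, "tpp_params"))
  if (!inherits(cohort, "tpp_cohort")) stop("`cohort` must be a tpp_cohort", call. = FALSE)
  if (length(params$alpha) != length(cohort$covariate_names))
    stop("alpha dimension does not match cohort covariates", call. = FALSE)
  dat <- build_lik_data(cohort)
  loglik_from_data(params$theta, params$alpha, params$beta, params$gamma, dat)
}

#' Default box constraints for fitting
#'
#' The optimizer works on the natural parameter scale with box constraints:
#' `theta` in `[1e-4, 10]`, `beta` in `[0, 10]`, `gamma` in `[1e-4, 10]`,
#' `alpha` unbounded. Note the upper bound on `beta` deliberately exceeds 1:
#' subcriticality is a simulator requirement, not a fitting constraint.
#'
#' @param p number of covariates.
#' @return list with numeric vectors `lower` and `upper` in the parameter
#'   order `(theta, alpha, beta, gamma)`.
#' @export
default_bounds <- function(p) {
  list(lower = c(1e-4, rep(-Inf, p), 0, 1e-4),
       upper = c(10, rep(Inf, p), 10, 10))
}

#' Maximum-likelihood fit of the triggering process
#'
#' Maximizes the closed-form log-likelihood by bounded quasi-Newton
#' (`L-BFGS-B`) on the natural parameter scale, with numerically
#' approximated gradients. The default start is
#' `theta = 1, alpha = 0, beta = 0.1, gamma = 0.1`; because the likelihood
#' is non-convex, `n_restarts` seeded random restarts around the start can
#' be requested and the best optimum is kept.
#'
#' Setting `lower == upper` for a coordinate pins that parameter (it is then
#' not counted in `n_params`); this is how the Poisson benchmarks are
#' obtained as restricted fits (see [fit_nhpp()]).
#'
#' @param cohort a `tpp_cohort` with at least one event overall.
#' @param init optional [model_params()] start.
#' @param lower,upper optional bound vectors in the order
#'   `(theta, alpha, beta, gamma)`; defaults from [default_bounds()].
#' @param n_restarts number of additional random restarts (default 0).
#' @param restart_seed seed for the restart draws.
#' @param control passed to [stats::optim()] (on top of `fnscale = -1`).
#' @return A `tpp_fit` object: `params`, `log_lik`, `n_params`, `aic`,
#'   `bic` (sample size = total event count), `converged`, `n_iter`,
#'   `message`.
#' @seealso [log_likelihood()], [information_criteria()]
#' @export
fit_mle <- function(cohort, init = NULL, lower = NULL, upper = NULL,
                    n_restarts = 0, restart_seed = 1L, control = list()) {
  if (!inherits(cohort, "tpp_cohort")) stop("`cohort` must be a tpp_cohort", call. = FALSE)
  dat <- build_lik_data(cohort)
  if (dat$total_events < 1L)
    stop("cannot fit: cohort has no events", call. = FALSE)
  p <- dat$p
  b <- default_bounds(p)
  if (is.null(lower)) lower <- b$lower
  if (is.null(upper)) upper <- b$upper
  if (length(lower) != p + 3L || length(upper) != p + 3L)
    stop("bounds must have length p + 3 (theta, alpha, beta, gamma)", call. = FALSE)
  if (is.null(init)) {
    init <- model_params(theta = 1, alpha = rep(0, p), beta = 0.1, gamma = 0.1)
  } else if (length(init$alpha) != p) {
    stop("`init` alpha dimension does not match the cohort", call. = FALSE)
  }
  par0 <- pmin(pmax(params_to_vector(init), lower), upper)

  # L-BFGS-B mishandles coordinates with lower == upper; optimize the free
  # coordinates only and keep pinned ones fixed at their bound
  free <- lower < upper
  assemble <- function(par_free) {
    full <- par0
    full[free] <- par_free
    full
  }
  negll_full <- function(par) {
    -loglik_from_data(par[1L],
                      if (p > 0) par[seq(2L, 1L + p)] else numeric(0),
                      par[2L + p], par[3L + p], dat)
  }
  negll <- function(par_free) negll_full(assemble(par_free))
  run_one <- function(par) {
    if (!any(free)) {
      return(list(par = par, value = negll_full(par), convergence = 0L,
                  counts = c(`function` = 1L, gradient = 0L), message = NULL))
    }
    res <- stats::optim(par[free], negll, method = "L-BFGS-B",
                        lower = lower[free], upper = upper[free],
                        control = utils::modifyList(list(maxit = 500L), control))
    res$par <- assemble(res$par)
    res
  }
  safe_run <- function(par) {
    tryCatch(run_one(par), error = function(e)
      list(par = par, value = -LOGLIK_SENTINEL, convergence = 99L,
           counts = c(`function` = 0L, gradient = 0L), message = conditionMessage(e)))
  }
  best <- safe_run(par0)
  if (n_restarts > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(restart_seed)
    for (k in seq_len(n_restarts)) {
      lo <- pmax(lower, c(0.05, rep(-2, p), 0, 0.01))
      hi <- pmin(upper, c(3, rep(2, p), 1.5, 2))
      start <- stats::runif(p + 3L, lo, hi)
      start[!free] <- par0[!free]
      cand <- safe_run(start)
      if (cand$value < best$value) best <- cand
    }
  }
  n_params <- sum(free)
  ll <- -best$value
  msg <- if (!is.null(best$message) && nzchar(best$message %||% "")) best$message else ""
  new_tpp_fit(
    params = vector_to_params(best$par, p, alpha_names = cohort$covariate_names),
    log_lik = ll, n_params = n_params, n_events = dat$total_events,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    n_iter = unname(best$counts[1L]), message = msg, family = "triggering"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal fit-object constructor shared with the benchmarks
new_tpp_fit <- function(params, log_lik, n_params, n_events, converged,
                        n_iter, message, family) {
  aic <- 2 * n_params - 2 * log_lik
  bic <- n_params * log(n_events) - 2 * log_lik
  structure(
    list(params = params, log_lik = log_lik, n_params = n_params,
         n_events = n_events, aic = aic, bic = bic, converged = converged,
         n_iter = n_iter, message = message, family = family),
    class = "tpp_fit"
  )
}

#' @export
print.tpp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model fit (%s)\n", x$family,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  print(x$params, digits = digits)
  cat(sprintf("  log-lik %.3f | AIC %.2f | BIC %.2f (k = %d, events = %d)\n",
              x$log_lik, x$aic, x$bic, x$n_params, x$n_events))
  invisible(x)
}

#' Information criteria of a fit
#'
#' `AIC = 2 k - 2 l(Theta-hat)` and `BIC = k log(n) - 2 l(Theta-hat)` where
#' `k` counts the free parameters and the BIC sample size `n` is the total
#' number of events across the cohort (the convention used throughout this
#' package; point-process observations are events, not recipients).
#'
#' @param fit a `tpp_fit`.
#' @return named numeric vector `c(aic =, bic =)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "tpp_fit"), is.finite(fit$log_lik))
  c(aic = fit$aic, bic = fit$bic)
}

# internal: save/restore .Random.seed so helper seeding doesn't clobber callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
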