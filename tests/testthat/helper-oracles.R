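# Independent oracles and small fixtures shared across the suite.
# The oracles deliberately take the slow route (direct O(n^2) kernel sums,
# adaptive quadrature of the intensity) so they share no code path with the
# closed-form/vectorized implementation they check.

# compensator by adaptive quadrature, integrating piecewise between events
# (the intensity is smooth within segments, kinked at events)
quad_Lambda <- function(params, recipient, t_end = recipient$obs_length) {
  brk <- sort(unique(c(0, recipient$event_times[recipient$event_times < t_end], t_end)))
  total <- 0
  for (k in seq_len(length(brk) - 1L)) {
    total <- total + stats::integrate(
      function(u) vapply(u, function(uu) total_intensity(params, recipient, uu),
                         numeric(1)),
      brk[k], brk[k + 1L], rel.tol = 1e-10)$value
  }
  total
}

# log-likelihood the long way: direct intensity evaluations + quadrature
naive_loglik <- function(params, cohort) {
  s <- 0
  for (r in cohort$recipients) {
    for (tj in r$event_times)
      s <- s + log(total_intensity(params, r, tj))
    s <- s - quad_Lambda(params, r)
  }
  s
}

# build a cohort from a list of event-time vectors (uses x1..xp covariates)
make_cohort <- function(times_list, obs_length, X = NULL) {
  n <- length(times_list)
  if (is.null(X)) X <- matrix(0, n, 0)
  obs <- rep_len(obs_length, n)
  nm <- if (ncol(X)) paste0("x", seq_len(ncol(X))) else character(0)
  recips <- lapply(seq_len(n), function(i) {
    xv <- if (ncol(X)) stats::setNames(X[i, ], nm) else numeric(0)
    recipient_history(paste0("r", i), times_list[[i]], xv, obs[i])
  })
  new_cohort(recips, covariate_names = nm)
}

# random small instance: N <= 5 recipients, n_i <= 5 events, p = 2 covariates
rand_small_instance <- function() {
  n <- sample(1:5, 1)
  Tw <- stats::runif(1, 5, 50)
  times_list <- lapply(seq_len(n), function(i) {
    ni <- sample(0:5, 1)
    sort(stats::runif(ni, 0.05, Tw * 0.98))
  })
  X <- matrix(stats::rbinom(2 * n, 1, 0.5), n, 2)
  params <- model_params(theta = stats::runif(1, 0.3, 1.5),
                         alpha = stats::runif(2, -1, 1),
                         beta = stats::runif(1, 0, 0.9),
                         gamma = stats::runif(1, 0.05, 1))
  list(cohort = make_cohort(times_list, Tw, X), params = params)
}

# two-binary-covariate spec used by recovery experiments
binary2_spec <- function(p1 = 0.5, p2 = 0.5) {
  list(list(name = "x1", prevalence = p1),
       list(name = "x2", prevalence = p2))
}
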