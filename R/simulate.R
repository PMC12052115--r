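# Simulators.
#
# Two independent samplers of the same process law:
#  * the exact cluster (branching) construction — immigrants from the
#    inhomogeneous Poisson baseline, each event spawning offspring through
#    the exponential triggering kernel, recursively;
#  * Ogata-style thinning from the conditional intensity, used as a
#    distributional cross-check.

#' Default synthetic covariate specification
#'
#' Mirrors the covariate structure of a Medicaid overdose-recurrence cohort:
#' sex (2 levels), age group (4), race (4), rural/urban geography (3), and
#' two binary treatment flags (opioid withdrawal, medications for opioid use
#' disorder). Probabilities are plausible cohort marginals chosen once for
#' the synthetic world; every element can be overridden via `sim_config()`.
#'
#' Categorical variables are specified as `list(name=, levels=, probs=)` and
#' dummy-encoded against the alphabetically first level; binary flags as
#' `list(name=, prevalence=)`.
#'
#' @return list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "sex", levels = c("female", "male"), probs = c(0.5, 0.5)),
    list(name = "age_group", levels = c("18-34", "35-49", "50-65", "66+"),
         probs = c(0.40, 0.30, 0.20, 0.10)),
    list(name = "race", levels = c("black", "caucasian", "hispanic", "other"),
         probs = c(0.15, 0.70, 0.10, 0.05)),
    list(name = "geography", levels = c("mixed", "rural", "urban"),
         probs = c(0.20, 0.30, 0.50)),
    list(name = "withdrawal", prevalence = 0.30),
    list(name = "moud", prevalence = 0.40)
  )
}

#' Default generating parameters for synthetic cohorts
#'
#' The stated synthetic world: a mildly decreasing baseline
#' (`theta = 0.2`, about `365^0.2 = 3.25` baseline events per recipient-year
#' for the reference covariate pattern), moderate self-excitation
#' (`beta = 0.3` offspring per event) decaying over about ten days
#' (`gamma = 0.1`/day), and small log-linear covariate effects. See the
#' methods vignette for the rationale.
#'
#' @param covariate_spec covariate specification the `alpha` vector must match.
#' @return a [model_params()] object.
#' @export
default_true_params <- function(covariate_spec = default_covariate_spec()) {
  nm <- covariate_dummy_names(covariate_spec)
  alpha <- stats::setNames(rep(0, length(nm)), nm)
  pick <- function(n, v) if (n %in% nm) alpha[[n]] <<- v
  pick("sex.male", 0.20)
  pick("age_group.35-49", -0.10)
  pick("age_group.50-65", -0.20)
  pick("age_group.66+", -0.40)
  pick("race.caucasian", 0.10)
  pick("geography.urban", 0.15)
  pick("withdrawal", 0.30)
  pick("moud", -0.25)
  model_params(theta = 0.2, alpha = alpha, beta = 0.3, gamma = 0.1)
}

# internal: dummy column names implied by a covariate spec
covariate_dummy_names <- function(spec) {
  unlist(lapply(spec, function(s) {
    if (!is.null(s$levels)) {
      lev <- sort(s$levels)
      paste(s$name, lev[-1L], sep = ".")
    } else {
      s$name
    }
  }), use.names = FALSE)
}

validate_covariate_spec <- function(spec) {
  if (!is.list(spec)) stop("covariate_spec must be a list", call. = FALSE)
  for (s in spec) {
    if (is.null(s$name)) stop("every covariate needs a name", call. = FALSE)
    if (!is.null(s$levels)) {
      if (is.null(s$probs) || length(s$probs) != length(s$levels))
        stop(sprintf("covariate %s: probs must match levels", s$name), call. = FALSE)
      if (abs(sum(s$probs) - 1) > 1e-8)
        stop(sprintf("covariate %s: probabilities must sum to 1", s$name), call. = FALSE)
    } else if (is.null(s$prevalence) || s$prevalence < 0 || s$prevalence > 1) {
      stop(sprintf("covariate %s: needs levels/probs or a prevalence in [0,1]",
                   s$name), call. = FALSE)
    }
  }
  invisible(spec)
}

#' Simulation configuration
#'
#' @param n_recipients positive integer cohort size.
#' @param obs_length scalar observation window in days, or a function of `n`
#'   returning per-recipient windows.
#' @param true_params generating [model_params()]; must have `beta < 1`
#'   (subcritical) so event counts are a.s. finite.
#' @param covariate_spec see [default_covariate_spec()].
#' @param seed integer master seed.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_recipients = 1000, obs_length = 365,
                       true_params = NULL,
                       covariate_spec = default_covariate_spec(),
                       seed = 1L) {
  if (!is.numeric(n_recipients) || length(n_recipients) != 1L ||
      n_recipients < 1 || n_recipients != round(n_recipients))
    stop("`n_recipients` must be a positive integer", call. = FALSE)
  validate_covariate_spec(covariate_spec)
  if (is.null(true_params)) true_params <- default_true_params(covariate_spec)
  stopifnot(inherits(true_params, "tpp_params"))
  if (true_params$beta >= 1)
    stop("simulation requires beta < 1 (subcritical process)", call. = FALSE)
  p <- length(covariate_dummy_names(covariate_spec))
  if (length(true_params$alpha) != p)
    stop(sprintf("true_params alpha has length %d but the covariate spec implies %d dummies",
                 length(true_params$alpha), p), call. = FALSE)
  if (!is.function(obs_length) &&
      (!is.numeric(obs_length) || obs_length <= 0))
    stop("`obs_length` must be positive or a function", call. = FALSE)
  structure(list(n_recipients = as.integer(n_recipients),
                 obs_length = obs_length, true_params = true_params,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: draw an n x p dummy matrix from a covariate spec (uses current RNG)
simulate_covariates <- function(n, spec) {
  cols <- list()
  for (s in spec) {
    if (!is.null(s$levels)) {
      lev <- sort(s$levels)
      pr <- s$probs[order(s$levels)]
      draw <- sample(lev, n, replace = TRUE, prob = pr)
      for (l in lev[-1L])
        cols[[paste(s$name, l, sep = ".")]] <- as.numeric(draw == l)
    } else {
      cols[[s$name]] <- as.numeric(stats::runif(n) < s$prevalence)
    }
  }
  if (length(cols) == 0L) return(matrix(0, n, 0))
  do.call(cbind, cols)
}

#' Simulate one recipient by the cluster (branching) representation
#'
#' Draws an event stream on `[0, obs_length)` from the exact process law:
#' immigrant events from the inhomogeneous Poisson baseline with compensator
#' \eqn{\Lambda^b(t) = t^\theta e^{\alpha^\top x}} (count
#' `Poisson(Lambda_b(T))`, times by inverting the compensator at uniform
#' order statistics); each event at time `s` independently spawns
#' `Poisson(beta (1 - e^{-gamma (T - s)}))` offspring with delays drawn from
#' the Exponential(`gamma`) kernel truncated to the remaining window;
#' recursion over generations until extinction. Offspring beyond the window
#' are right-truncated away, matching administrative censoring.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param params generating [model_params()] with `beta < 1`.
#' @param x covariate vector matching `params$alpha`.
#' @param obs_length positive window length in days.
#' @param recipient_id identifier for the returned history.
#' @param label_events if `TRUE`, attach a `"labels"` attribute marking each
#'   event `"immigrant"` or `"offspring"` (ground truth for decomposition
#'   checks).
#' @return a [recipient_history()]; with `label_events`, carries the labels
#'   attribute aligned with `event_times`.
#' @export
simulate_recipient <- function(params, x, obs_length, recipient_id = "sim",
                               label_events = FALSE) {
  stopifnot(inherits(params, "tpp_params"))
  if (params$beta >= 1)
    stop("simulation requires beta < 1 (subcritical process)", call. = FALSE)
  check_covariate_dim(x, params$alpha)
  if (obs_length <= 0) stop("`obs_length` must be positive", call. = FALSE)
  Tw <- obs_length
  ebx <- exp(if (length(x)) sum(params$alpha * x) else 0)
  # immigrants: invert Lambda_b at uniform order statistics
  lam_tot <- Tw^params$theta * ebx
  n_imm <- stats::rpois(1L, lam_tot)
  imm <- if (n_imm > 0)
    (sort(stats::runif(n_imm)) * lam_tot / ebx)^(1 / params$theta) else numeric(0)
  times <- imm
  labels <- rep("immigrant", n_imm)
  gen <- imm
  while (length(gen)) {
    trunc_mass <- params$beta * (1 - exp(-params$gamma * (Tw - gen)))
    n_off <- stats::rpois(length(gen), trunc_mass)
    if (sum(n_off) == 0L) break
    parent <- rep(gen, n_off)
    pmass <- rep(1 - exp(-params$gamma * (Tw - gen)), n_off)
    u <- stats::runif(length(parent))
    delay <- -log(1 - u * pmass) / params$gamma  # truncated Exp(gamma)
    children <- parent + delay
    children <- children[children < Tw]  # guard FP edge
    times <- c(times, children)
    labels <- c(labels, rep("offspring", length(children)))
    gen <- children
  }
  ord <- order(times)
  times <- times[ord]
  labels <- labels[ord]
  # continuous law: ties have probability 0, but guard against FP collisions
  if (length(times) > 1L && any(diff(times) <= 0)) {
    keep <- c(TRUE, diff(times) > 0)
    times <- times[keep]
    labels <- labels[keep]
  }
  rh <- recipient_history(recipient_id, times, covariates = x,
                          obs_length = Tw)
  if (label_events) attr(rh, "labels") <- labels
  rh
}

#' Simulate a cohort
#'
#' Draws `n_recipients` independent recipients under a [sim_config()]:
#' covariates first under the master seed, then each recipient's event
#' stream under the derived seed `seed + i` (documented scheme, so stream
#' `i` is reproducible independently of cohort size). The caller's RNG
#' state is restored on exit.
#'
#' @param config a [sim_config()].
#' @param label_events propagate ground-truth immigrant/offspring labels.
#' @return a `tpp_cohort`; recipients carry a `"labels"` attribute when
#'   `label_events = TRUE`.
#' @export
simulate_cohort <- function(config, label_events = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  n <- config$n_recipients
  set.seed(config$seed)
  X <- simulate_covariates(n, config$covariate_spec)
  Tis <- if (is.function(config$obs_length)) config$obs_length(n)
         else rep(config$obs_length, n)
  if (length(Tis) != n || any(Tis <= 0))
    stop("obs_length sampler must return n positive horizons", call. = FALSE)
  nm <- covariate_dummy_names(config$covariate_spec)
  recips <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(config$seed + i)
    xi <- if (ncol(X)) stats::setNames(X[i, ], nm) else numeric(0)
    recips[[i]] <- simulate_recipient(config$true_params, xi, Tis[i],
                                      recipient_id = sprintf("sim%05d", i),
                                      label_events = label_events)
  }
  new_cohort(recips, covariate_names = nm)
}

#' Simulate one recipient by Ogata thinning
#'
#' Rejection sampler from the conditional intensity, distributionally
#' equivalent to [simulate_recipient()] and kept as an independent oracle.
#' The baseline must be bounded on the window: `theta >= 1` gives the bound
#' `theta T^{theta-1} e^{alpha' x}` automatically; for `theta < 1` a finite
#' `baseline_bound` must be supplied by the caller.
#'
#' @inheritParams simulate_recipient
#' @param baseline_bound optional upper bound on the baseline intensity over
#'   `(0, obs_length]`; required when `theta < 1`.
#' @return a [recipient_history()].
#' @export
thinning_simulate <- function(params, x, obs_length, recipient_id = "sim",
                              baseline_bound = NULL) {
  stopifnot(inherits(params, "tpp_params"))
  check_covariate_dim(x, params$alpha)
  if (obs_length <= 0) stop("`obs_length` must be positive", call. = FALSE)
  ebx <- exp(if (length(x)) sum(params$alpha * x) else 0)
  if (is.null(baseline_bound)) {
    if (params$theta < 1)
      stop("theta < 1 has an unbounded baseline at 0; supply `baseline_bound`",
           call. = FALSE)
    baseline_bound <- params$theta * obs_length^(params$theta - 1) * ebx
  }
  bg <- params$beta * params$gamma
  s <- 0
  v <- 0  # current triggering intensity (decays between events)
  times <- numeric(0)
  repeat {
    B <- baseline_bound + v
    if (B <= 0) break
    w <- stats::rexp(1L) / B
    s_new <- s + w
    if (s_new >= obs_length) break
    v <- v * exp(-params$gamma * w)
    s <- s_new
    lam <- params$theta * s^(params$theta - 1) * ebx + v
    if (stats::runif(1L) * B <= lam) {
      times <- c(times, s)
      v <- v + bg
    }
  }
  recipient_history(recipient_id, times, covariates = x, obs_length = obs_length)
}
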