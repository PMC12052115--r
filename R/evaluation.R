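# Evaluation protocol: plug-in count prediction over windows [0, L), MAE and
# MAPE over replicated recipient-level train/test splits, the
# baseline/triggering decomposition of the predicted counts, and the t-test
# on the replicated triggering estimates.

#' Predicted event count with baseline/triggering decomposition
#'
#' Expected number of events among the test recipients over `[0, L)` under
#' the plug-in conditional intensity: each recipient's realized events
#' inside the window feed the triggering term,
#' \deqn{\hat m_{[0,L)} = \sum_{i=1}^{M} \Lambda_i(L)
#'   = \underbrace{\sum_i L^{\theta} e^{\alpha^\top x_i}}_{baseline}
#'   + \underbrace{\beta \sum_i \sum_{t_{ij} < L} (1 - e^{-\gamma (L - t_{ij})})}_{triggering}.}
#' The two parts sum to the total exactly (the total is computed as their
#' sum), which is what makes the decomposition of predicted counts into
#' baseline-explained and triggering-explained shares well defined.
#'
#' @param params a [model_params()] (typically a fitted `$params`).
#' @param test a `tpp_cohort` of test recipients.
#' @param horizon positive window length `L` in days. A warning is issued
#'   if it exceeds some test recipient's observation window (the prediction
#'   then extrapolates beyond that recipient's censoring date).
#' @return named numeric vector `c(total=, baseline_part=, triggering_part=)`.
#' @export
predict_counts <- function(params, test, horizon) {
  stopifnot(inherits(params, "tpp_params"), inherits(test, "tpp_cohort"))
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("`horizon` must be a positive finite scalar", call. = FALSE)
  p <- length(params$alpha)
  if (p != length(test$covariate_names))
    stop("params covariate dimension does not match the test cohort", call. = FALSE)
  if (horizon > min(cohort_obs_lengths(test)))
    warning("horizon exceeds some recipients' observation windows; ",
            "prediction extrapolates past their censoring dates", call. = FALSE)
  X <- cohort_covariate_matrix(test)
  lin <- if (p > 0) as.numeric(X %*% params$alpha) else
    numeric(length(test$recipients))
  baseline_part <- sum(horizon^params$theta * exp(lin))
  triggering_part <- sum(vapply(test$recipients, function(r) {
    h <- r$event_times[r$event_times < horizon]
    if (length(h)) params$beta * sum(1 - exp(-params$gamma * (horizon - h))) else 0
  }, numeric(1)))
  c(total = baseline_part + triggering_part,
    baseline_part = baseline_part, triggering_part = triggering_part)
}

#' Actual event count over a window
#'
#' Number of observed events in `[0, L)` intersected with each recipient's
#' own observation window `[0, T_i)`.
#'
#' @inheritParams predict_counts
#' @param cohort a `tpp_cohort`.
#' @return integer total count.
#' @export
actual_counts <- function(cohort, horizon) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  sum(vapply(cohort$recipients, function(r)
    sum(r$event_times < min(horizon, r$obs_length)), numeric(1)))
}

#' Mean absolute error over replications
#'
#' `MAE = mean(|predicted_r - actual_r|)` over the `R` replications.
#'
#' @param predicted,actual equal-length numeric vectors of predicted and
#'   actual counts per replication.
#' @return non-negative scalar.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop("`predicted` and `actual` must be non-empty and of equal length",
         call. = FALSE)
  mean(abs(predicted - actual))
}

#' Mean absolute percentage error over replications
#'
#' `MAPE = 100/R * sum(|predicted_r - actual_r| / actual_r)`, in percent.
#' Every actual count must be strictly positive.
#'
#' @inheritParams mae
#' @return non-negative percentage.
#' @export
mape <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop("`predicted` and `actual` must be non-empty and of equal length",
         call. = FALSE)
  if (any(actual == 0))
    stop("MAPE undefined: some actual counts are zero", call. = FALSE)
  100 * mean(abs(predicted - actual) / actual)
}

#' Recipient-level train/test split sizes
#'
#' The number of training recipients is `round(train_frac * N)`; e.g. an
#' 80/20 split of 1,186 recipients gives 949 training and 237 test.
#'
#' @param n cohort size.
#' @param train_frac training fraction in (0, 1).
#' @return named integer vector `c(train=, test=)`.
#' @export
split_sizes <- function(n, train_frac = 0.8) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  n_train <- as.integer(round(train_frac * n))
  c(train = n_train, test = as.integer(n) - n_train)
}

#' Replicated train/test evaluation
#'
#' Runs the replicated protocol: for each replication `r`, a seeded random
#' recipient-level 80/20 split (replication seed = `seed + r`), a model fit
#' on the training recipients, plug-in count predictions on the test
#' recipients for every window `L`, and the realized counts in `[0, L)`.
#' Aggregates MAE and MAPE per window, the baseline/triggering shares of
#' the predicted counts, and the series of triggering estimates
#' `beta-hat_r`.
#'
#' Fit failures are recorded and excluded with a logged count, never
#' silently dropped. Windows whose actual count is zero in some replication
#' get `NA` MAPE with a warning.
#'
#' @param cohort a `tpp_cohort` with at least 5 recipients.
#' @param windows numeric vector of window lengths `L` in days.
#' @param n_reps number of replications.
#' @param train_frac training fraction (default 0.8).
#' @param seed master seed; replication `r` uses `seed + r`.
#' @param model `"full"` (triggering), `"hpp"` or `"nhpp"`.
#' @param fit_args list of extra arguments for the fitter.
#' @return a `tpp_eval` object: `per_replication` data frame
#'   (`r`, `L`, `predicted`, `actual`, `baseline_part`, `triggering_part`,
#'   `beta_hat`), `mae`, `mape`, `triggering_proportion` (per-window
#'   pooled triggering share of predicted counts), `beta_hats`, `n_failed`.
#' @export
run_replications <- function(cohort, windows, n_reps, train_frac = 0.8,
                             seed = 1L, model = c("full", "hpp", "nhpp"),
                             fit_args = list()) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  model <- match.arg(model)
  n <- length(cohort$recipients)
  if (n < 5L) stop("need at least 5 recipients to split", call. = FALSE)
  if (length(windows) == 0L || any(windows <= 0))
    stop("`windows` must be positive horizons", call. = FALSE)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  sizes <- split_sizes(n, train_frac)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  rows <- vector("list", n_reps)
  beta_hats <- rep(NA_real_, n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx_train <- sample.int(n, sizes[["train"]])
    train <- subset_cohort(cohort, idx_train)
    test <- subset_cohort(cohort, -idx_train)
    fit <- tryCatch(
      switch(model,
             full = do.call(fit_mle, c(list(train), fit_args)),
             hpp = fit_hpp(train),
             nhpp = do.call(fit_nhpp, c(list(train), fit_args))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      message(sprintf("replication %d: fit failed (%s); excluded",
                      r, conditionMessage(fit)))
      next
    }
    beta_hats[r] <- if (model == "full") fit$params$beta else NA_real_
    pr <- lapply(windows, function(L) {
      act <- actual_counts(test, L)
      if (model == "hpp") {
        tot <- predict_counts_benchmark(fit, test, L)
        c(predicted = tot, actual = act, baseline_part = tot, triggering_part = 0)
      } else {
        pc <- suppressWarnings(predict_counts(fit$params, test, L))
        c(predicted = unname(pc["total"]), actual = act,
          baseline_part = unname(pc["baseline_part"]),
          triggering_part = unname(pc["triggering_part"]))
      }
    })
    rows[[r]] <- data.frame(r = r, L = windows, do.call(rbind, pr))
  }
  per_rep <- do.call(rbind, rows)
  if (is.null(per_rep)) stop("all replications failed to fit", call. = FALSE)
  per_rep$beta_hat <- beta_hats[per_rep$r]
  if (n_failed > 0L)
    message(sprintf("%d of %d replications failed and were excluded",
                    n_failed, n_reps))

  agg <- function(f, needs_pos = FALSE) {
    vapply(windows, function(L) {
      d <- per_rep[per_rep$L == L, ]
      if (needs_pos && any(d$actual == 0)) return(NA_real_)
      f(d$predicted, d$actual)
    }, numeric(1))
  }
  mae_w <- stats::setNames(agg(mae), windows)
  mape_w <- stats::setNames(agg(mape, needs_pos = TRUE), windows)
  if (anyNA(mape_w))
    warning("MAPE is NA for windows with zero actual counts", call. = FALSE)
  trig_w <- stats::setNames(vapply(windows, function(L) {
    d <- per_rep[per_rep$L == L, ]
    sum(d$triggering_part) / sum(d$predicted)
  }, numeric(1)), windows)

  structure(
    list(model = model, windows = windows,
         n_replications = n_reps, n_failed = n_failed,
         sizes = sizes, seed = seed,
         per_replication = per_rep,
         mae = mae_w, mape = mape_w,
         triggering_proportion = trig_w,
         beta_hats = beta_hats[!is.na(beta_hats)]),
    class = "tpp_eval"
  )
}

#' @export
print.tpp_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Replicated evaluation (%s model): %d replications, %d/%d split\n",
              x$model, x$n_replications, x$sizes[["train"]], x$sizes[["test"]]))
  tab <- data.frame(L = x$windows,
                    MAE = round(x$mae, digits),
                    MAPE_pct = round(x$mape, digits),
                    triggering_share = round(x$triggering_proportion, digits))
  print(tab, row.names = FALSE)
  if (x$n_failed) cat(sprintf("  (%d failed replications excluded)\n", x$n_failed))
  invisible(x)
}

#' One-sided t-test on the replicated triggering estimates
#'
#' Tests `H0: beta-hat = 0` against `Ha: beta-hat > 0` with a one-sample
#' t statistic `t = mean / (sd / sqrt(R))` on `R - 1` degrees of freedom
#' (upper tail). With zero variance the p-value degenerates: 0 if the
#' common value is positive, 1 otherwise, with a warning.
#'
#' @param beta_hats numeric vector of triggering estimates over
#'   replications (length >= 2).
#' @return list with `t_stat`, `p_value`, `df`, `mean`, `sd`.
#' @export
triggering_significance <- function(beta_hats) {
  beta_hats <- beta_hats[is.finite(beta_hats)]
  R <- length(beta_hats)
  if (R < 2L) stop("need at least 2 finite replicate estimates", call. = FALSE)
  m <- mean(beta_hats)
  s <- stats::sd(beta_hats)
  if (s == 0) {
    warning("zero variance across replications; degenerate p-value", call. = FALSE)
    return(list(t_stat = if (m > 0) Inf else NaN,
                p_value = if (m > 0) 0 else 1, df = R - 1L, mean = m, sd = s))
  }
  t_stat <- m / (s / sqrt(R))
  list(t_stat = t_stat,
       p_value = stats::pt(t_stat, df = R - 1L, lower.tail = FALSE),
       df = R - 1L, mean = m, sd = s)
}

#' Ground-truth offspring fraction of a labeled cohort
#'
#' For cohorts simulated with `label_events = TRUE`, the fraction of events
#' in `[0, L)` that the simulator labeled `"offspring"` (triggered) rather
#' than `"immigrant"` (baseline). This is the ground truth against which
#' the model's estimated triggering proportion can be compared.
#'
#' @param cohort a labeled `tpp_cohort`.
#' @param horizon window `L`; `Inf` uses all events.
#' @return fraction in `[0, 1]`.
#' @export
offspring_fraction <- function(cohort, horizon = Inf) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  off <- 0L; tot <- 0L
  for (r in cohort$recipients) {
    lab <- attr(r, "labels")
    if (is.null(lab))
      stop("cohort has no event labels; simulate with label_events = TRUE",
           call. = FALSE)
    keep <- r$event_times < horizon
    off <- off + sum(lab[keep] == "offspring")
    tot <- tot + sum(keep)
  }
  if (tot == 0L) return(NaN)
  off / tot
}

#' Export an evaluation report
#'
#' Writes the per-replication table as CSV and the per-window summary
#' (MAE, MAPE, triggering share, the `beta-hat` series and its t-test) as
#' JSON.
#'
#' @param report a `tpp_eval`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "tpp_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, sprintf("replications_%s.csv", report$model))
  utils::write.csv(report$per_replication, csv, row.names = FALSE)
  summ <- list(model = report$model,
               windows = report$windows,
               n_replications = report$n_replications,
               n_failed = report$n_failed,
               mae = as.list(report$mae),
               mape = as.list(report$mape),
               triggering_proportion = as.list(report$triggering_proportion))
  if (length(report$beta_hats) >= 2) {
    ts <- triggering_significance(report$beta_hats)
    summ$beta_hat <- list(values = report$beta_hats,
                          t_stat = ts$t_stat, p_value = ts$p_value)
  }
  js <- file.path(dir, sprintf("summary_%s.json", report$model))
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
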