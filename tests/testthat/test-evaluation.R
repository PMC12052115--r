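test_that("MAE and MAPE follow their definitions", {
  expect_equal(mae(10, 12), 2.0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(mae(c(0, 10), c(5, 5)), 5.0)
  expect_equal(mape(10, 12), 100 * 2 / 12)
  expect_equal(mape(c(1, 2), c(1, 2)), 0)
  expect_equal(mape(c(5, 15), c(10, 10)), 50)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  expect_error(mape(c(1, 2), c(1, 0)), "zero")
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("MAE scales linearly and MAPE is scale invariant", {
  set.seed(8)
  pred <- runif(20, 5, 50); act <- runif(20, 5, 50)
  perm <- sample(20)
  expect_equal(mae(pred[perm], act[perm]), mae(pred, act))
  expect_equal(mape(pred[perm], act[perm]), mape(pred, act))
  expect_equal(mae(3 * pred, 3 * act), 3 * mae(pred, act))
  expect_equal(mape(3 * pred, 3 * act), mape(pred, act))
})

test_that("plug-in count prediction decomposes exactly and matches quadrature", {
  # beta = 0: all baseline
  p0 <- model_params(theta = 0.8, alpha = c(0.2, -0.1), beta = 0, gamma = 1)
  co <- make_cohort(list(c(5, 20), numeric(0)), 100,
                    X = matrix(c(1, 0, 0, 1), 2, 2))
  pc0 <- predict_counts(p0, co, 50)
  expect_identical(pc0[["triggering_part"]], 0)
  expect_identical(pc0[["total"]], pc0[["baseline_part"]])
  # fast-decay limit: each in-window event contributes ~ beta
  pfast <- model_params(theta = 1, alpha = numeric(0), beta = 1, gamma = 500)
  co1 <- make_cohort(list(c(3, 7, 11)), 100)
  L <- 30
  expect_equal(predict_counts(pfast, co1, L)[["total"]], L + 3, tolerance = 1e-3)
  # randomized case against per-recipient quadrature of the intensity
  set.seed(19)
  inst <- rand_small_instance()
  L <- 0.8 * inst$cohort$recipients[[1]]$obs_length
  pc <- suppressWarnings(predict_counts(inst$params, inst$cohort, L))
  quad <- sum(vapply(inst$cohort$recipients, function(r) {
    rl <- recipient_history(r$recipient_id, r$event_times[r$event_times < L],
                            r$covariates, obs_length = max(L, r$obs_length))
    quad_Lambda(inst$params, rl, L)
  }, numeric(1)))
  expect_equal(pc[["total"]], quad, tolerance = 1e-6)
  # additivity is exact by construction
  expect_identical(pc[["total"]], pc[["baseline_part"]] + pc[["triggering_part"]])
  # horizons beyond the observation window warn
  expect_warning(predict_counts(p0, co, 150), "extrapolates")
  expect_error(predict_counts(p0, co, -5), "positive")
})

test_that("actual counts respect the prediction window", {
  co <- make_cohort(list(c(5, 20, 80), c(10, 45)), c(100, 50))
  expect_equal(actual_counts(co, 30), 3)   # 5, 20, 10
  expect_equal(actual_counts(co, 60), 4)   # + 45
  expect_equal(actual_counts(co, 200), 5)
})

test_that("recipient-level split sizes reproduce the 80/20 arithmetic", {
  s <- split_sizes(1186, 0.8)
  expect_identical(s[["train"]], 949L)
  expect_identical(s[["test"]], 237L)
  expect_error(split_sizes(100, 1.2), "train_frac")
})

test_that("replicated evaluation is reproducible and internally consistent", {
  tp <- model_params(theta = 0.6, alpha = c(0.3, -0.2), beta = 0.4, gamma = 0.15)
  co <- simulate_cohort(sim_config(80, 120, tp,
                                   covariate_spec = binary2_spec(), seed = 12))
  r1 <- run_replications(co, windows = c(30, 60), n_reps = 2, seed = 99)
  r2 <- run_replications(co, windows = c(30, 60), n_reps = 2, seed = 99)
  expect_identical(r1$per_replication, r2$per_replication)
  expect_identical(r1$mae, r2$mae)
  # exact additivity in every row
  with(r1$per_replication,
       expect_identical(predicted, baseline_part + triggering_part))
  expect_true(all(r1$triggering_proportion >= 0 & r1$triggering_proportion <= 1))
  expect_identical(length(r1$beta_hats), 2L)
  expect_error(run_replications(co, windows = -3, n_reps = 1), "positive")
})

test_that("a null cohort yields a small estimated triggering share", {
  tp <- model_params(theta = 0.8, alpha = numeric(0), beta = 0, gamma = 0.1)
  co <- simulate_cohort(sim_config(150, 120, tp, covariate_spec = list(),
                                   seed = 21))
  rep0 <- run_replications(co, windows = 90, n_reps = 3, seed = 7)
  expect_lte(mean(rep0$triggering_proportion), 0.05)
})

test_that("triggering significance matches the textbook one-sided t-test", {
  x <- c(0.5, 0.6, 0.4, 0.5, 0.5)
  ts <- triggering_significance(x)
  # hand-computed: t = mean / (sd / sqrt(R)), upper-tail p on R - 1 df
  expect_equal(ts$t_stat, mean(x) / (sd(x) / sqrt(5)))
  expect_equal(ts$p_value, pt(ts$t_stat, 4, lower.tail = FALSE))
  # cross-check against stats::t.test
  tt <- t.test(x, mu = 0, alternative = "greater")
  expect_equal(ts$t_stat, unname(tt$statistic))
  expect_equal(ts$p_value, tt$p.value)
  # degenerate branches
  expect_warning(z <- triggering_significance(rep(0, 5)), "zero variance")
  expect_equal(z$p_value, 1)
  expect_warning(o <- triggering_significance(rep(0.3, 5)), "zero variance")
  expect_equal(o$p_value, 0)
  expect_error(triggering_significance(0.5), "at least 2")
})

test_that("evaluation reports export per-replication and summary files", {
  tp <- model_params(theta = 0.7, alpha = numeric(0), beta = 0.3, gamma = 0.2)
  co <- simulate_cohort(sim_config(60, 90, tp, covariate_spec = list(),
                                   seed = 14))
  rep1 <- run_replications(co, windows = c(30, 60), n_reps = 2, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_eval_report(rep1, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_identical(nrow(back), nrow(rep1$per_replication))
  summ <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(unname(unlist(summ$mae)), unname(rep1$mae))
})
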