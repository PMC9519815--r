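test_that("3-SD reaction-time exclusion removes exactly the planted outlier", {
  rec <- data.frame(participant_id = "p001",
                    rt_ms = c(rep(800, 100), 30000), correct = TRUE)
  ex <- exclude_rt_outliers(rec, k = 3)
  expect_equal(ex$n_excluded, 1L)
  expect_true(all(ex$records$rt_ms == 800))
  # identical RTs: SD is zero, nothing excluded
  same <- data.frame(participant_id = "p001", rt_ms = rep(700, 50))
  expect_equal(exclude_rt_outliers(same)$n_excluded, 0L)
  # k = Inf is the identity
  expect_equal(exclude_rt_outliers(rec, k = Inf)$n_excluded, 0L)
  # conservation at the filtering stage
  expect_equal(nrow(ex$records) + ex$n_excluded, nrow(rec))
  # a single-row scope warns and keeps the row
  expect_warning(one <- exclude_rt_outliers(rec[1, , drop = FALSE]),
                 "SD undefined")
  expect_equal(one$n_excluded, 0L)
})

test_that("per-participant exclusion scope operates within participants", {
  rec <- data.frame(
    participant_id = rep(c("a", "b"), each = 51),
    rt_ms = c(rep(500, 50), 21000, rep(12000, 50), 21000))
  per <- exclude_rt_outliers(rec, k = 3, scope = "per_participant")
  expect_equal(per$n_excluded, 2L)
  # the pooled SD is inflated by between-participant spread: nothing excluded
  glob <- exclude_rt_outliers(rec, k = 3, scope = "global")
  expect_equal(glob$n_excluded, 0L)
})

test_that("full and halved datasets carry the chance offset and row accounting", {
  des <- generate_design(design_spec(seed = 17))
  rec <- simulate_cohort(des, 30, participant_config(contamination_rate = 0,
                                                     seed = 2))
  ds <- make_datasets(rec)
  # even without contamination the lognormal tail can shed a few trials
  expect_equal(nrow(ds$full$rows) + ds$full$n_excluded, 720L)
  expect_equal(nrow(ds$halved$rows) + ds$halved$n_excluded, 360L)
  expect_true(all(ds$halved$rows$repetition == 1L))
  expect_equal(ds$full$offset, log(1 / 3), tolerance = 1e-12)
  expect_equal(ds$halved$offset, stats::qlogis(0.25))
  # exclusion applied independently per variant, with conservation
  rec2 <- simulate_cohort(des, 30, participant_config(seed = 2))
  ds2 <- make_datasets(rec2)
  expect_equal(nrow(ds2$full$rows) + ds2$full$n_excluded, 720L)
  expect_equal(nrow(ds2$halved$rows) + ds2$halved$n_excluded, 360L)
  # a participant missing repetition 2 leaves the halved dataset unaffected
  rec3 <- rec[!(rec$participant_id == "p001" & rec$repetition == 2L), ]
  ds3 <- make_datasets(rec3)
  expect_equal(ds3$halved$rows, ds$halved$rows)
})

test_that("frequentist chance-offset model recovers generative parameters", {
  des <- generate_design(design_spec(seed = 17))
  cfg <- participant_config(beta0 = 1.5, delta_pp_plus = 0.4,
                            tau_participant = 0.8, tau_stimulus = 0.2,
                            contamination_rate = 0, seed = 33)
  rec <- simulate_cohort(des, 60, cfg)
  dsr <- make_datasets(rec)
  fit <- fit_glmm_frequentist(dsr$full)
  expect_s3_class(fit, "glmm_result")
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_identical(fit$fixed$term, c("intercept_PPminus", "PPplus"))
  # odds ratio = exp(log-odds estimate)
  expect_equal(fit$fixed$odds_ratio, exp(fit$fixed$estimate))
  # Wald interval should comfortably contain the truth at this effect size
  expect_gt(fit$fixed$ci_high[1], exp(1.5) * 0.5)
  expect_lt(fit$fixed$ci_low[1], exp(1.5) * 2)
  expect_true(fit$fixed$ci_low[1] > 1)   # clearly above chance
  expect_equal(fit$sigma2_residual, pi^2 / 3)
  expect_true(fit$icc >= 0 && fit$icc <= 1)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_equal(fit$n_obs + dsr$full$n_excluded, 1440L)
})

test_that("degenerate all-correct data raises the separation flag", {
  des <- generate_design(design_spec(seed = 17))
  rec <- simulate_cohort(des, 4, participant_config(learner = "associative",
                                                    softmax_temperature = 0,
                                                    contamination_rate = 0,
                                                    seed = 1))
  expect_true(all(rec$correct))
  fit <- fit_glmm_frequentist(make_datasets(rec)$full)
  expect_true(fit$separation)
})

test_that("odds combination multiplies intercept and PP+ odds", {
  expect_equal(round(combine_odds(7.61, 1.19), 2), 9.06)
  expect_equal(round(combine_odds(6.25, 1.56), 2), 9.75)
  expect_equal(combine_odds(4.2, 1), 4.2)
  expect_error(combine_odds(-1, 2), "positive")
})

test_that("latent-scale ICC reproduces the printed variance-component arithmetic", {
  expect_equal(round(icc_logistic(c(2.35, 0.21)), 2), 0.44)
  expect_equal(round(icc_logistic(c(1.45, 0.09)), 2), 0.32)
  expect_equal(icc_logistic(c(0, 0)), 0)
  expect_equal(round(pi^2 / 3, 2), 3.29)
  expect_error(icc_logistic(-0.1), ">= 0")
})

test_that("marginal/conditional R2 follow the variance decomposition", {
  # no fixed-effect variance: marginal 0, conditional equals the ICC
  r2 <- r2_nakagawa(0, c(2.35, 0.21))
  expect_equal(r2$marginal, 0)
  expect_equal(r2$conditional, icc_logistic(c(2.35, 0.21)))
  # no random variance and fixed variance equal to residual: both 0.5
  r2b <- r2_nakagawa(pi^2 / 3, 0)
  expect_equal(r2b$marginal, 0.5)
  expect_equal(r2b$conditional, 0.5)
  # conditional >= marginal over random inputs
  set.seed(42)
  for (i in 1:50) {
    r <- r2_nakagawa(runif(1, 0, 5), runif(2, 0, 5))
    expect_gte(r$conditional, r$marginal)
    expect_true(r$marginal >= 0 && r$conditional <= 1)
  }
  expect_error(r2_nakagawa(-1, 0), ">= 0")
})

test_that("bootstrap accuracy summaries behave at the degenerate ends", {
  des <- generate_design(design_spec(seed = 17))
  rec <- simulate_cohort(des, 10, participant_config(learner = "associative",
                                                     softmax_temperature = 0,
                                                     seed = 5))
  acc <- accuracy_summary(rec, n_boot = 500, seed = 1)
  expect_equal(acc$mean, c(1, 1))
  expect_equal(acc$ci_low, c(1, 1))
  expect_equal(acc$ci_high, c(1, 1))      # zero-width interval
  rec2 <- simulate_cohort(des, 40, participant_config(learner = "guesser",
                                                      seed = 6))
  acc2 <- accuracy_summary(rec2, n_boot = 500, seed = 1)
  for (i in 1:2) {
    expect_lte(acc2$ci_low[i], acc2$mean[i])
    expect_gte(acc2$ci_high[i], acc2$mean[i])
    expect_true(acc2$ci_low[i] <= 0.25 && acc2$ci_high[i] >= 0.25)
  }
  # deterministic under seed
  expect_identical(accuracy_summary(rec2, n_boot = 200, seed = 9),
                   accuracy_summary(rec2, n_boot = 200, seed = 9))
})

test_that("one-sample t power follows the noncentral t distribution", {
  expect_gt(power_one_sample_t(4.37, 30), 0.80)
  expect_gt(power_one_sample_t(4.37, 30), 0.999)    # effectively 1
  expect_equal(power_one_sample_t(0, 30), 0.05, tolerance = 1e-10)
  expect_equal(power_one_sample_t(0, 10, alpha = 0.01), 0.01,
               tolerance = 1e-10)
  # monotone nondecreasing in n at fixed positive d
  pw <- vapply(2:40, function(n) power_one_sample_t(0.5, n), numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
  expect_error(power_one_sample_t(1, 1), "n must be")
})
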