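# Standardized design construction and the coefficient-to-parameter mapping.

test_that("design rows implement the stated transforms", {
  tr <- toy_trials()
  d <- build_design(tr)

  # dReward flags exactly the zero-reward offers; log term is 0 there
  expect_equal(d$d_reward, as.numeric(tr$reward == 0))
  expect_equal(d$d_averse, as.numeric(tr$aversiveness == 0))

  # hand-computed z-scores of the log-reward column for rewards 0..5
  raw_log <- c(0, log(1), log(2), log(3), log(4), log(5))
  expect_equal(d$log_reward_z, (raw_log - mean(raw_log)) / sd(raw_log))
  expect_equal(mean(d$log_reward_z), 0, tolerance = 1e-8)
  expect_equal(sd(d$log_reward_z), 1, tolerance = 1e-8)

  # conflict is |reward - aversiveness| on the raw offers, then z-scored
  raw_con <- abs(tr$reward - tr$aversiveness)
  expect_equal(d$conflict_z, (raw_con - mean(raw_con)) / sd(raw_con))

  # dummies untouched
  expect_equal(d$pavlovian, tr$pavlovian)
})

test_that("conflict of an equal offer is zero before scaling", {
  tr <- toy_trials(rewards = c(3, 1, 5), aversiveness = c(3, 4, 0))
  expect_equal(abs(tr$reward - tr$aversiveness)[1], 0)
  d <- build_design(tr)
  expect_lt(d$conflict_z[1], 0)  # zero raw conflict sits below the mean
})

test_that("degenerate designs are rejected naming subject and column", {
  tr <- toy_trials(rewards = rep(2, 6), aversiveness = c(1, 2, 3, 0, 4, 5))
  expect_error(build_design(tr), "log_reward.*S01|S01.*log_reward")
  tr2 <- toy_trials()
  tr2$reward <- 0
  tr2$aversiveness <- 0
  expect_error(build_design(tr2), "inadmissible")
})

test_that("pooled standardization scope is honoured", {
  tr <- toy_trials(n_subj = 3)
  d <- build_design(tr, scope = "pooled")
  expect_equal(mean(d$aversiveness_z), 0, tolerance = 1e-8)
  expect_equal(sd(d$aversiveness_z), 1, tolerance = 1e-8)
  # per-subject means need not vanish under pooled scaling
  bysub <- tapply(d$caudate, tr$subject_id, mean)
  expect_false(all(abs(bysub) < 1e-8))
})

test_that("coefficient sets enforce the canonical slot structure", {
  expect_error(coef_set(threshold = c(intercept = 2, bogus = 1),
                        ndt = c(intercept = 0.4),
                        drift = c(intercept = 0),
                        start = c(intercept = 0.5)), "unknown")
  expect_error(coef_set(threshold = c(stn = 1),
                        ndt = c(intercept = 0.4),
                        drift = c(intercept = 0),
                        start = c(intercept = 0.5)), "intercept")
  sl <- coef_slot_names()
  expect_equal(lengths(sl)[c("drift", "threshold", "start", "ndt")],
               c(drift = 8L, threshold = 4L, start = 4L, ndt = 1L))
})

test_that("mapping arithmetic matches the published coefficient table", {
  # all slopes zero: drift equals its intercept on non-zero-reward trials
  co <- coef_set(threshold = c(intercept = 2.244),
                 ndt = c(intercept = 0.737),
                 drift = c(intercept = 0.665),
                 start = c(intercept = 0.536))
  p <- compute_trial_params(co, design_row())
  expect_equal(p$v, 0.665)
  expect_equal(p$a, 2.244)
  expect_equal(p$z, 0.536)
  expect_equal(p$ndt, 0.737)

  # reference means, one unit of standardized log reward
  hc <- reference_coefficients("HC")
  p2 <- compute_trial_params(hc, design_row(log_reward_z = 1))
  expect_equal(p2$v, 0.665 + 0.701)

  # dummy off, regressors at their mean: z equals its intercept
  p3 <- compute_trial_params(hc, design_row())
  expect_equal(p3$z, 0.536)
})

test_that("the mapping is linear in every regressor", {
  hc <- reference_coefficients("HC")
  base <- compute_trial_params(hc, design_row())
  one <- compute_trial_params(hc, design_row(aversiveness_z = 1))
  two <- compute_trial_params(hc, design_row(aversiveness_z = 2))
  expect_equal(two$v - base$v, 2 * (one$v - base$v))
  onec <- compute_trial_params(hc, design_row(conflict_z = 1))
  twoc <- compute_trial_params(hc, design_row(conflict_z = 2))
  expect_equal(twoc$a - base$a, 2 * (onec$a - base$a))
})

test_that("interaction terms expand to the full published row set", {
  d <- build_design(toy_trials())
  mm <- aacddm:::.design_matrices(d, ddm_model_spec("final"))
  expect_setequal(colnames(mm$Xv),
                  c("Intercept", "reward", "aversiveness", "caudate",
                    "pacc", "reward:caudate", "aversiveness:pacc",
                    "d_reward"))
  expect_setequal(colnames(mm$Xa),
                  c("Intercept", "stn", "conflict", "conflict:stn"))
  expect_setequal(colnames(mm$Xz),
                  c("Intercept", "pavlovian", "accumbens",
                    "accumbens:pavlovian"))
  # interaction columns are elementwise products of their main effects
  expect_equal(mm$Xv[, "reward:caudate"],
               mm$Xv[, "reward"] * mm$Xv[, "caudate"])
  expect_equal(mm$Xa[, "conflict:stn"],
               mm$Xa[, "conflict"] * mm$Xa[, "stn"])
})

test_that("constraint violations are flagged with offending trials", {
  co <- coef_set(threshold = c(intercept = 0.1, stn = 1),
                 ndt = c(intercept = 0.4),
                 drift = c(intercept = 0),
                 start = c(intercept = 0.5))
  bad <- design_row(stn = -2)
  expect_error(compute_trial_params(co, bad), "constraint violation")
  expect_silent(compute_trial_params(co, bad, validate = FALSE))
})
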