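# Task design, ROI series and dataset generation.

test_that("task design respects the offer grid and counterbalancing", {
  d <- generate_task(105, 3, seed = 1)
  expect_equal(nrow(d), 105)
  expect_false(any(d$reward == 0 & d$aversiveness == 0))
  expect_true(all(d$reward %in% seq(0, 5, length.out = 16)))
  expect_true(all(d$aversiveness %in% seq(0, 5, length.out = 6)))
  expect_lte(abs(sum(d$pavlovian == 1) - sum(d$pavlovian == 0)), 1)
  expect_equal(as.integer(table(d$run)), c(35, 35, 35))

  d2 <- generate_task(2, 1, seed = 2)
  expect_setequal(d2$pavlovian, c(0, 1))

  expect_error(generate_task(0), ">= 1")
})

test_that("offer sampling is uniform over the 95 admissible cells", {
  d <- generate_task(20000, 1, seed = 3)
  counts <- table(interaction(d$reward, d$aversiveness, drop = TRUE))
  expect_equal(length(counts), 95)
  gof <- chisq.test(as.integer(counts))
  expect_gt(gof$p.value, 1e-3)
})

test_that("ROI series are standardized and couple to offers as specified", {
  d <- generate_task(105, 3, seed = 4)
  roi <- generate_roi_signals(d, seed = 5)
  expect_equal(colnames(roi), c("caudate", "pacc", "nacc", "stn"))
  expect_equal(unname(colMeans(roi)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(roi, 2, sd)), rep(1, 4), tolerance = 1e-10)

  # uncoupled: correlation with offers within the sampling bound
  dd <- generate_task(5000, 1, seed = 6)
  roi0 <- generate_roi_signals(dd, seed = 7)
  expect_lt(abs(cor(roi0[, "caudate"], dd$reward)), 3 / sqrt(5000))

  # coupled: cor(caudate, z(reward)) ~ w / sqrt(w^2 + noise^2)
  big <- generate_task(1e5, 1, seed = 8)
  roi1 <- generate_roi_signals(big, coupling = list(caudate = c(reward = 0.5)),
                               noise_sd = 1, seed = 9)
  r_obs <- cor(roi1[, "caudate"], scale(big$reward))
  expect_equal(as.numeric(r_obs), 0.5 / sqrt(1.25), tolerance = 0.02)

  expect_error(generate_roi_signals(d, noise_sd = 0), "positive")
})

test_that("datasets are reproducible, admissible, and carry the truth", {
  ds1 <- generate_dataset(hc_spec(), 3, seed = 42)
  ds2 <- generate_dataset(hc_spec(), 3, seed = 42)
  expect_identical(ds1$trials, ds2$trials)

  # all RTs exceed the subject's true non-decision time
  tr <- merge(ds1$trials, ds1$truth$subjects[, c("subject_id", "ndt")],
              by = "subject_id")
  expect_true(all(tr$rt > tr$ndt))

  # round-trip: the mapping reproduces the generating trial parameters
  sub <- ds1$truth$subjects[1, ]
  idx <- ds1$trials$subject_id == sub$subject_id
  drows <- build_design(ds1$trials[idx, ])
  co <- reference_coefficients("HC")
  co$threshold[["intercept"]] <- sub$a_intercept
  co$drift[["intercept"]] <- sub$v_intercept
  co$start[["intercept"]] <- sub$z_intercept
  co$ndt[["intercept"]] <- sub$ndt
  pars <- compute_trial_params(co, drows)
  truth <- ds1$truth$trial_params[
    ds1$truth$trial_params$subject_id == sub$subject_id, ]
  expect_equal(pars$v, truth$v)
  expect_equal(pars$a, truth$a)
  expect_equal(pars$z, truth$z)
  expect_true(all(pars$a > 0 & pars$z > 0 & pars$z < 1))
})

test_that("zero between-subject sd collapses the hierarchy", {
  sdz <- c(a_intercept = 0, v_intercept = 0, z_intercept = 0, ndt = 0)
  ds <- generate_dataset(hc_spec(subject_sd = sdz), 3, seed = 1)
  expect_equal(length(unique(ds$truth$subjects$a_intercept)), 1)
  expect_equal(ds$truth$subjects$ndt,
               rep(reference_coefficients("HC")$ndt[["intercept"]], 3))
})

test_that("identically specified groups have matching approach rates", {
  g1 <- group_spec("A", reference_coefficients("HC"))
  g2 <- group_spec("B", reference_coefficients("HC"))
  ds <- generate_dataset(list(g1, g2), 10, seed = 77)
  x <- tapply(ds$trials$choice, ds$trials$group, sum)
  n <- tapply(ds$trials$choice, ds$trials$group, length)
  pt <- prop.test(x, n)
  expect_gt(pt$p.value, 1e-3)
})

test_that("reward discriminability rises monotonically with the slope", {
  # the generating reward slope governs how sharply approach depends on the
  # offered reward: the approach-rate gap between high- and low-reward
  # offers must grow monotonically with it (overall approach fraction does
  # not, since at a positive drift intercept a steeper slope also pushes
  # low-reward offers below zero drift)
  gaps <- vapply(c(0.1, 0.7, 1.4), function(b) {
    co <- reference_coefficients("HC")
    co$drift[["reward"]] <- b
    sdz <- c(a_intercept = 0, v_intercept = 0, z_intercept = 0, ndt = 0)
    ds <- generate_dataset(group_spec("HC", co, subject_sd = sdz), 2,
                           n_trials = 1000, seed = 55)
    hi <- ds$trials$reward > 2.5
    mean(ds$trials$choice[hi]) - mean(ds$trials$choice[!hi])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("trial tables round-trip through the canonical CSV", {
  ds <- generate_dataset(hc_spec(), 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_trials(ds, path)
  back <- read_trials(path)
  expect_equal(back$rt, ds$trials$rt, tolerance = 1e-12)
  expect_equal(back$choice, ds$trials$choice)
  expect_equal(back$subject_id, ds$trials$subject_id)
  sidecar <- sub("\\.csv$", "_truth.json", path)
  expect_true(file.exists(sidecar))
  unlink(c(path, sidecar))
})
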