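# Hierarchical estimation: diagnostics, determinism, recovery, DIC.

test_that("Gelman-Rubin statistic behaves at its analytic anchors", {
  set.seed(1)
  n <- 1000
  base <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p1", "p2")))

  # exact copies: zero between-chain variance -> sqrt((n-1)/n)
  rh <- compute_rhat(list(base, base, base))
  expect_equal(unname(rh), rep(sqrt((n - 1) / n), 2), tolerance = 1e-12)

  # independent chains from one distribution: ~1
  ch <- lapply(1:4, function(i)
    matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p1", "p2"))))
  expect_lt(max(compute_rhat(ch)), 1.05)

  # gross non-convergence: means shifted by 5 within-chain sds
  ch2 <- list(base, base + 5)
  expect_gt(min(compute_rhat(ch2)), 1.1)

  expect_error(compute_rhat(list(base)), "2 chains")
})

test_that("fits are deterministic under a fixed seed", {
  ds <- generate_dataset(hc_spec(), 2, n_trials = 40, seed = 8)
  spec <- ddm_model_spec("final-behavioral")
  f1 <- suppressWarnings(fit_ddm(ds, spec, n_chains = 2, n_samples = 150,
                                 n_burn = 50, seed = 3))
  f2 <- suppressWarnings(fit_ddm(ds, spec, n_chains = 2, n_samples = 150,
                                 n_burn = 50, seed = 3))
  expect_identical(f1$chains, f2$chains)
  f3 <- suppressWarnings(fit_ddm(ds, spec, n_chains = 2, n_samples = 150,
                                 n_burn = 50, seed = 4))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("null-generated slopes are recovered as credibly zero", {
  co <- coef_set(threshold = c(intercept = 2.2),
                 ndt = c(intercept = 0.5),
                 drift = c(intercept = 0.4),
                 start = c(intercept = 0.5))
  ds <- generate_dataset(group_spec("HC", co), 6, seed = 21)
  fit <- suppressWarnings(
    fit_ddm(ds, ddm_model_spec("final"), n_chains = 2, n_samples = 800,
            n_burn = 300, seed = 22))
  m <- posterior_draws(fit)
  slopes <- setdiff(grep("^(v|a|z)_", group_level_names(fit), value = TRUE),
                    c())
  slopes <- slopes[!grepl("Intercept|^mu_|^sd_", slopes)]
  covered <- vapply(slopes, function(par) {
    h <- hdi(m[, par])
    h[1] < 0 && h[2] > 0
  }, logical(1))
  # per-slope 95% coverage: with 13 slopes an occasional exclusion is the
  # expected behaviour of correct intervals, so allow at most two misses
  expect_gte(sum(covered), length(slopes) - 2)
})

test_that("subject intercepts shrink from their MLEs toward the group mean", {
  fit <- small_hc_fit()
  ds <- small_hc_dataset()
  m <- posterior_draws(fit)
  post <- colMeans(m)
  sids <- fit$prep$subject_ids
  mu <- post[["mu_v_Intercept[all]"]]
  n_between <- 0
  for (k in seq_along(sids)) {
    s <- fit$prep$subjects[[k]]
    # profile MLE of the drift intercept, other parameters at posterior means
    others <- vapply(colnames(s$Xv)[-1], function(cn)
      post[[paste0("v_", cn)]], numeric(1))
    grid <- seq(-1.5, 2.5, by = 0.02)
    ll <- vapply(grid, function(b0) {
      v <- as.numeric(s$Xv %*% c(b0, others))
      a <- as.numeric(s$Xa %*% c(post[[paste0("a_Intercept[", sids[k], "]")]],
        vapply(colnames(s$Xa)[-1], function(cn) post[[paste0("a_", cn)]],
               numeric(1))))
      z <- as.numeric(s$Xz %*% c(post[[paste0("z_Intercept[", sids[k], "]")]],
        vapply(colnames(s$Xz)[-1], function(cn) post[[paste0("z_", cn)]],
               numeric(1))))
      nd <- rep(post[[paste0("ndt[", sids[k], "]")]], length(v))
      aacddm:::wfpt_loglik_cpp(s$rt, s$upper, v, a, z, nd,
                               log(1e-12), 1e-7)$loglik
    }, numeric(1))
    mle <- grid[which.max(ll)]
    pm <- post[[paste0("v_Intercept[", sids[k], "]")]]
    between <- (pm >= min(mle, mu) - 0.02) && (pm <= max(mle, mu) + 0.02)
    n_between <- n_between + between
  }
  expect_gte(n_between, length(sids) - 1)
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  fit <- small_hc_fit()
  flat <- fit
  post <- colMeans(posterior_draws(fit))
  row <- matrix(rep(post, each = 10), nrow = 10,
                dimnames = list(NULL, names(post)))
  # deviance column must be consistent with the plugged-in draws
  dhat <- compute_dic(fit)$dhat
  row[, "deviance"] <- dhat
  flat$chains <- list(row)
  d <- compute_dic(flat)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, dhat, tolerance = 1e-8)
})

test_that("separate-groups and mixed-effect fits agree on difference sign", {
  hc <- reference_coefficients("HC")
  lo <- reference_coefficients("HC")
  lo$drift[["reward"]] <- 0.25
  ds <- generate_dataset(list(group_spec("HC", hc), group_spec("MDD", lo)),
                         6, seed = 31)
  spec_sep <- ddm_model_spec("final-behavioral",
                             grouping = "separate-groups")
  fits <- suppressWarnings(fit_ddm(ds, spec_sep, n_chains = 1,
                                   n_samples = 700, n_burn = 300,
                                   seed = 32))
  cmp <- compare_groups(fits$HC, fits$MDD, "v_reward")
  expect_gt(cmp$p_a_gt_b, 0.5)

  spec_mix <- ddm_model_spec("final-behavioral", grouping = "mixed-effect")
  fit_mix <- suppressWarnings(fit_ddm(ds, spec_mix, n_chains = 1,
                                      n_samples = 700, n_burn = 300,
                                      seed = 33))
  off <- posterior_draws(fit_mix, "v_reward:grpMDD")[, 1]
  expect_lt(mean(off), 0)  # MDD offset negative, same direction
})

test_that("a one-model ladder trivially ranks itself first", {
  ds <- generate_dataset(hc_spec(), 2, n_trials = 40, seed = 41)
  tab <- suppressWarnings(
    run_model_ladder(ds, list(only = ddm_model_spec("final-behavioral")),
                     n_chains = 1, n_samples = 200, n_burn = 100,
                     seed = 42))
  expect_equal(nrow(tab), 1)
  expect_true(tab$winner[1])
  expect_true(is.finite(tab$dic[1]))
})

test_that("group-level recovery holds at nominal coverage across replicates", {
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    ds <- generate_dataset(hc_spec(), 6, seed = 500 + r)
    fit <- suppressWarnings(
      fit_ddm(ds, ddm_model_spec("final-behavioral"), n_chains = 1,
              n_samples = 700, n_burn = 300, seed = 600 + r))
    h <- hdi(posterior_draws(fit, "v_reward")[, 1])
    hits <- hits + (h[1] <= 0.701 && 0.701 <= h[2])
  }
  # binomial test against nominal 95% coverage at alpha = 0.01
  expect_gt(binom.test(hits, n_rep, 0.95)$p.value, 0.01)
})
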