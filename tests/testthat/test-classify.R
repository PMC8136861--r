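# Feature assembly, the CV classifier, transfer and leave-one-subject-out.

brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("rank AUC equals brute-force pairwise comparison exactly", {
  set.seed(1)
  for (r in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(rnorm(40), 1))  # rounded scores force ties
    expect_identical(auc_score(y, s), brute_force_auc(y, s))
  }
  expect_equal(auc_score(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(auc_score(c(1, 1, 0, 0), c(1, 2, 3, 4)), 0)
})

test_that("behavioral features summarize the trial table", {
  tr <- toy_trials(rewards = c(1, 2, 3, 4), aversiveness = c(1, 2, 3, 4))
  tr$choice <- c(1, 1, 1, 0)
  ft <- extract_features(data = tr, mode = "behavioral+roi")
  expect_equal(ft$approach_rate, 0.75)
  expect_equal(ft$mean_rt, mean(tr$rt))
  expect_setequal(setdiff(names(ft), c("subject_id", "label")),
                  c("mean_rt", "approach_rate", "caudate", "pacc", "nacc",
                    "stn"))
})

test_that("computational features demand an unbiased single-population fit", {
  expect_error(extract_features(small_hc_fit(), small_hc_dataset(),
                                "computational+neural"),
               "bias protection")
})

test_that("computational-only mode excludes every ROI feature", {
  ds <- generate_dataset(list(hc_spec(), mdd_spec()), 3, seed = 71)
  fit <- suppressWarnings(
    fit_ddm(ds, ddm_model_spec("final", grouping = "single-population"),
            n_chains = 1, n_samples = 500, n_burn = 200, seed = 72))
  full <- extract_features(fit, ds, "computational+neural")
  slim <- extract_features(fit, ds, "computational-only")
  expect_false(any(grepl("caudate|pacc|accumbens|stn",
                         names(slim))))
  expect_true(any(grepl("caudate", names(full))))
  expect_equal(nrow(full), 6)
  expect_true(all(c("v_reward", "z_Intercept", "ndt") %in% names(slim)))
})

test_that("separable features classify perfectly; labels drive the signal", {
  sep <- feature_table_sim(12, 3, delta = 8, seed = 2)
  rep <- train_and_evaluate(sep, n_repeats = 3, n_splits = 3, seed = 3)
  expect_equal(rep$holdout_auc, 1)

  # permuted labels: chance-level held-out AUC on average
  set.seed(4)
  aucs <- vapply(1:15, function(i) {
    tab <- feature_table_sim(12, 3, delta = 8, seed = 100 + i)
    tab$label <- sample(tab$label)
    train_and_evaluate(tab, n_repeats = 2, n_splits = 2,
                       seed = 200 + i)$holdout_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("no leakage: a label canary wins only when injected", {
  tab <- feature_table_sim(15, 4, delta = 0, seed = 5)
  base <- train_and_evaluate(tab, n_repeats = 3, n_splits = 4, seed = 6)
  expect_lt(base$holdout_auc, 0.85)  # noise features stay near chance

  canary <- tab
  canary$leak <- as.numeric(canary$label == "MDD")
  leaked <- train_and_evaluate(canary, n_repeats = 3, n_splits = 4,
                               seed = 6)
  expect_equal(leaked$holdout_auc, 1)
  expect_equal(leaked$importance$feature[1], "leak")
})

test_that("importance ranking is invariant to feature column order", {
  tab <- feature_table_sim(15, 5, delta = 1, seed = 7)
  fc <- setdiff(names(tab), c("subject_id", "label"))
  perm <- tab[, c("subject_id", "label", rev(fc))]
  attr(perm, "feature_set") <- "synthetic"
  r1 <- train_and_evaluate(tab, n_repeats = 3, n_splits = 3, seed = 8)
  r2 <- train_and_evaluate(perm, n_repeats = 3, n_splits = 3, seed = 8)
  expect_equal(r1$importance$feature, r2$importance$feature)
  expect_equal(sort(r1$coefficients), sort(r2$coefficients),
               tolerance = 0.02)
})

test_that("frozen transfer reproduces training predictions and relabeling", {
  tab <- feature_table_sim(12, 4, delta = 2, seed = 9)
  rep <- train_and_evaluate(tab, n_repeats = 3, n_splits = 3, seed = 10)
  tr <- transfer_evaluate(rep, tab)
  expect_equal(unname(tr$predictions),
               unname(aacddm:::.predict_frozen(rep$final_model, tab)))

  # no remitters present: flag is a no-op
  scores <- setNames(rep_len(20, nrow(tab)), tab$subject_id)
  tr2 <- transfer_evaluate(rep, tab, relabel_remitters = TRUE,
                           depression_scores = scores)
  expect_equal(tr$accuracy, tr2$accuracy)
  expect_equal(tr$auc, tr2$auc)

  # remitters move to the healthy class before scoring
  scores[tab$label == "MDD"][1:3] <- 5
  tr3 <- transfer_evaluate(rep, tab, relabel_remitters = TRUE,
                           depression_scores = scores)
  expect_equal(sum(tr3$labels == "HC"), sum(tab$label == "HC") + 3)

  bad <- tab
  names(bad)[names(bad) == "f1"] <- "other"
  expect_error(transfer_evaluate(rep, bad), "feature mismatch")
})

test_that("transfer from the same generative population beats the null", {
  train <- feature_table_sim(25, 4, delta = 1.5, seed = 11)
  follow <- feature_table_sim(25, 4, delta = 1.5, seed = 12)
  rep <- train_and_evaluate(train, n_repeats = 3, n_splits = 3, seed = 13)
  tr <- transfer_evaluate(rep, follow)
  expect_gt(tr$auc, 0.7)
})

test_that("leave-one-subject-out runs one retrain per follow-up subject", {
  base <- feature_table_sim(6, 3, delta = 6, seed = 14)
  follow <- base
  follow$f1 <- follow$f1 + rnorm(nrow(follow), sd = 0.1)
  attr(follow, "feature_set") <- "synthetic"
  out <- leave_one_subject_out(base, follow, seed = 15)
  expect_equal(length(out$predictions), nrow(follow))
  expect_equal(out$accuracy, 1)

  # pure noise: accuracy hovers around chance, with the pessimistic bias
  # characteristic of leave-one-out on balanced labels
  accs <- vapply(1:3, function(i) {
    noise <- feature_table_sim(10, 3, delta = 0, seed = 16 + i)
    leave_one_subject_out(noise, noise, seed = 17 + i)$accuracy
  }, numeric(1))
  expect_true(mean(accs) >= 0.15 && mean(accs) <= 0.8)

  stray <- follow
  stray$subject_id[1] <- "GHOST"
  expect_error(leave_one_subject_out(base, stray), "missing from baseline")
})
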