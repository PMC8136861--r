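# Shared fixtures, built in code. Expensive fits are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

hc_spec <- function(...) group_spec("HC", reference_coefficients("HC"), ...)
mdd_spec <- function(...) group_spec("MDD", reference_coefficients("MDD"), ...)

# small single-group dataset + final-model fit reused across test files
small_hc_dataset <- function() {
  cached("small_hc_ds",
         generate_dataset(hc_spec(), 6, seed = 301))
}

small_hc_fit <- function() {
  cached("small_hc_fit", suppressWarnings(
    fit_ddm(small_hc_dataset(), ddm_model_spec("final"),
            n_chains = 2, n_samples = 1000, n_burn = 400, seed = 302)))
}

# a toy trial table with hand-set offers for design/mapping tests
toy_trials <- function(n_subj = 1, rewards = c(0, 1, 2, 3, 4, 5),
                       aversiveness = c(1, 2, 3, 0, 4, 5)) {
  n <- length(rewards)
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    set.seed(100 + s)
    data.frame(subject_id = sprintf("S%02d", s), group = "HC", session = 1,
               run = 1, trial = seq_len(n),
               reward = rewards, aversiveness = aversiveness,
               pavlovian = rep_len(c(0, 1), n),
               choice = rep_len(c(1, 0), n), rt = runif(n, 0.8, 2),
               caudate = rnorm(n), pacc = rnorm(n), nacc = rnorm(n),
               stn = rnorm(n))
  }))
}

# a design row with every regressor at a chosen value (defaults 0)
design_row <- function(log_reward_z = 0, reward_z = 0, aversiveness_z = 0,
                       conflict_z = 0, d_reward = 0, d_averse = 0,
                       pavlovian = 0, caudate = 0, pacc = 0, nacc = 0,
                       stn = 0) {
  data.frame(log_reward_z = log_reward_z, reward_z = reward_z,
             aversiveness_z = aversiveness_z, conflict_z = conflict_z,
             d_reward = d_reward, d_averse = d_averse,
             pavlovian = pavlovian, caudate = caudate, pacc = pacc,
             nacc = nacc, stn = stn)
}

# synthetic gaussian feature tables for classifier tests
feature_table_sim <- function(n_per_class = 20, n_features = 5, delta = 0,
                              seed = 1, label_levels = c("HC", "MDD")) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * n_features), n_per_class),
    matrix(rnorm(n_per_class * n_features, mean = delta), n_per_class))
  tab <- data.frame(
    subject_id = sprintf("S%03d", seq_len(2 * n_per_class)),
    label = rep(label_levels, each = n_per_class))
  for (j in seq_len(n_features)) tab[[paste0("f", j)]] <- x[, j]
  attr(tab, "feature_set") <- "synthetic"
  class(tab) <- c("feature_table", "data.frame")
  tab
}
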