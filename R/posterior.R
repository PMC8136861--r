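#' Highest density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' (sorted-window method).
#'
#' @param draws numeric vector of posterior draws.
#' @param mass probability mass in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e4))
hdi <- function(draws, mass = 0.95) {
  if (length(draws) == 0) stop("draws must be nonempty")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- max(1, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior difference between two groups
#'
#' Forms the posterior distribution of the difference A - B by pairing
#' equal-length thinned draw sequences elementwise (the shorter sequence is
#' resampled with replacement if lengths differ), and reports the proportion
#' of the difference above 0 (exact ties count half, preserving
#' `p(A>B) + p(B>A) = 1`) with its 95% HDI.
#'
#' @param draws_a,draws_b posterior draws for the two groups.
#' @param parameter optional parameter name carried into the result.
#' @param mass HDI mass.
#' @return List of class `group_comparison`: `parameter`, `diff` (draws),
#'   `p_a_gt_b`, `hdi95`, group means.
#' @export
#' @examples
#' group_difference(rnorm(1000, 1), rnorm(1000, 0))$p_a_gt_b
group_difference <- function(draws_a, draws_b, parameter = "",
                             mass = 0.95) {
  if (length(draws_a) == 0 || length(draws_b) == 0)
    stop("draw sets must be nonempty")
  n <- max(length(draws_a), length(draws_b))
  if (length(draws_a) < n)
    draws_a <- sample(draws_a, n, replace = TRUE)
  if (length(draws_b) < n)
    draws_b <- sample(draws_b, n, replace = TRUE)
  d <- draws_a - draws_b
  p <- mean(d > 0) + 0.5 * mean(d == 0)
  structure(list(parameter = parameter, diff = d, p_a_gt_b = p,
                 hdi95 = hdi(d, mass), mean_a = mean(draws_a),
                 mean_b = mean(draws_b)),
            class = "group_comparison")
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: p(A>B) = %.3f, diff HDI [%.3f, %.3f]\n",
              x$parameter, x$p_a_gt_b, x$hdi95[1], x$hdi95[2]))
  invisible(x)
}

#' Compare a parameter across two separately fitted groups
#'
#' Convenience wrapper applying [group_difference()] to the draws of one
#' parameter from two fits (e.g. the HC and MDD fits of an
#' `"separate-groups"` estimation).
#'
#' @param fit_a,fit_b `aac_fit` objects.
#' @param parameter parameter name present in both fits.
#' @return A `group_comparison`.
#' @export
compare_groups <- function(fit_a, fit_b, parameter) {
  group_difference(posterior_draws(fit_a, parameter)[, 1],
                   posterior_draws(fit_b, parameter)[, 1],
                   parameter = parameter)
}

# per-subject coefficient vectors for one posterior draw
.draw_params <- function(fit, draw) {
  prep <- fit$prep
  lapply(seq_along(prep$subjects), function(k) {
    s <- prep$subjects[[k]]
    sid <- prep$subject_ids[k]
    lp <- list()
    for (f in c("v", "a", "z")) {
      X <- s[[paste0("X", f)]]
      cn <- colnames(X)
      lev <- prep$lev[[f]]
      b <- vapply(seq_along(cn), function(j) {
        nm <- if (lev[j] == 1) paste0(f, "_", cn[j], "[", sid, "]") else
          paste0(f, "_", cn[j])
        draw[[nm]]
      }, numeric(1))
      lp[[f]] <- as.numeric(X %*% b)
    }
    lp$ndt <- draw[[paste0("ndt[", sid, "]")]]
    lp
  })
}

#' Posterior predictive check of choice and response-time patterns
#'
#' Draws parameter vectors from the posterior, simulates full replicate
#' datasets on the observed designs, and compares observed and replicated
#' approach proportions and signed response times (avoid decisions carry
#' negative RTs) per offer cell. Cells bin the aversiveness levels against
#' equal-width reward bins.
#'
#' @param fit an `aac_fit`.
#' @param data the trial table the model was fit to.
#' @param n_replicates posterior draws to simulate (default 100).
#' @param reward_bins number of equal-width reward bins (default 6).
#' @param interval posterior-predictive interval mass (default 0.95).
#' @param dt simulator step size.
#' @param seed integer seed.
#' @return Object of class `aac_ppc`: per-cell data.frame (`$cells`) with
#'   observed and replicated approach proportions, interval bounds and a
#'   coverage flag; signed-RT summaries (`$signed_rt`); and the fraction of
#'   cells inside their predictive interval (`$coverage`).
#' @export
posterior_predictive_check <- function(fit, data, n_replicates = 100,
                                       reward_bins = 6, interval = 0.95,
                                       dt = 1e-3, seed = NULL) {
  stopifnot(inherits(fit, "aac_fit"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  trials <- if (inherits(data, "aac_dataset")) data$trials else data
  if (!is.null(seed)) set.seed(seed)

  prep <- fit$prep
  ord <- unlist(lapply(prep$subject_ids,
                       function(s) which(trials$subject_id == s)))
  trials <- trials[ord, ]
  m <- posterior_draws(fit)
  rows <- sample.int(nrow(m), n_replicates, replace = n_replicates > nrow(m))

  breaks <- seq(0, max(trials$reward), length.out = reward_bins + 1)
  rbin <- cut(trials$reward, breaks, include.lowest = TRUE)
  abin <- factor(trials$aversiveness)
  cell <- interaction(rbin, abin, drop = TRUE, sep = " x ")

  obs_prop <- tapply(trials$choice, cell, mean)
  rep_prop <- matrix(NA_real_, n_replicates, nlevels(cell))
  rep_signed <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    pars <- .draw_params(fit, m[rows[r], ])
    v <- unlist(lapply(pars, `[[`, "v"))
    a <- unlist(lapply(pars, `[[`, "a"))
    z <- unlist(lapply(pars, `[[`, "z"))
    ndt <- unlist(lapply(seq_along(pars), function(k)
      rep(pars[[k]]$ndt, length(pars[[k]]$v))))
    sim <- simulate_trials(v, a, z, ndt, dt = dt,
                           seed = sample.int(.Machine$integer.max, 1))
    app <- as.integer(sim$choice == "approach")
    rep_prop[r, ] <- tapply(app, cell, mean)
    rep_signed[[r]] <- ifelse(app == 1, sim$rt, -sim$rt)
  }
  alpha <- (1 - interval) / 2
  lo <- apply(rep_prop, 2, quantile, alpha, na.rm = TRUE)
  hi <- apply(rep_prop, 2, quantile, 1 - alpha, na.rm = TRUE)
  cells <- data.frame(cell = levels(cell),
                      n = as.integer(table(cell)),
                      observed = as.numeric(obs_prop),
                      predicted = colMeans(rep_prop, na.rm = TRUE),
                      lower = lo, upper = hi)
  cells$inside <- cells$observed >= cells$lower - 1e-12 &
    cells$observed <= cells$upper + 1e-12

  obs_signed <- ifelse(trials$choice == 1, trials$rt, -trials$rt)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  rep_q <- t(vapply(rep_signed, quantile, numeric(length(qs)), probs = qs))
  signed_rt <- data.frame(quantile = qs,
                          observed = quantile(obs_signed, qs),
                          predicted = colMeans(rep_q),
                          lower = apply(rep_q, 2, quantile, alpha),
                          upper = apply(rep_q, 2, quantile, 1 - alpha))
  structure(list(cells = cells, signed_rt = signed_rt,
                 coverage = mean(cells$inside),
                 observed_signed_rt = obs_signed,
                 observed_choice = trials$choice,
                 replicated_signed_rt = rep_signed[[1]],
                 n_replicates = n_replicates),
            class = "aac_ppc")
}

#' @exportS3Method base::print
print.aac_ppc <- function(x, ...) {
  cat(sprintf(
    "<aac_ppc> %d replicates, %d offer cells, %.1f%% inside interval\n",
    x$n_replicates, nrow(x$cells), 100 * x$coverage))
  invisible(x)
}

#' Plot a posterior predictive check
#'
#' Observed vs predicted approach proportions per offer cell with
#' posterior-predictive intervals (requires ggplot2).
#'
#' @param x an `aac_ppc`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.aac_ppc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- x$cells
  d$idx <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = idx)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "salmon", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = predicted), color = "red") +
    ggplot2::geom_point(ggplot2::aes(y = observed)) +
    ggplot2::labs(x = "offer cell (reward bin x aversiveness)",
                  y = "approach proportion") +
    ggplot2::theme_minimal()
}

#' Tabulate group posteriors side by side
#'
#' Builds the standard comparison table for two separately fitted groups:
#' per parameter, each group's posterior mean and 95% HDI bounds and the
#' posterior probability that the first group's value exceeds the
#' second's.
#'
#' @param fit_a,fit_b `aac_fit` objects (e.g. the HC and MDD fits).
#' @param parameters parameter names; default: all group-level parameters
#'   shared by the two fits.
#' @param labels group labels for the column names.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns `parameter`, `mean_<A>`, `lower_<A>`,
#'   `upper_<A>`, the same for B, and `p_a_gt_b`.
#' @export
comparison_table <- function(fit_a, fit_b, parameters = NULL,
                             labels = c("A", "B"), file = NULL) {
  if (is.null(parameters))
    parameters <- intersect(group_level_names(fit_a),
                            group_level_names(fit_b))
  rows <- lapply(parameters, function(p) {
    da <- posterior_draws(fit_a, p)[, 1]
    db <- posterior_draws(fit_b, p)[, 1]
    ha <- hdi(da); hb <- hdi(db)
    g <- group_difference(da, db, parameter = p)
    out <- data.frame(parameter = p, mean_a = mean(da), lower_a = ha[1],
                      upper_a = ha[2], mean_b = mean(db), lower_b = hb[1],
                      upper_b = hb[2], p_a_gt_b = g$p_a_gt_b)
    rownames(out) <- NULL
    out
  })
  tab <- do.call(rbind, rows)
  names(tab) <- c("parameter",
                  paste0(c("mean_", "lower_", "upper_"), labels[1]),
                  paste0(c("mean_", "lower_", "upper_"), labels[2]),
                  "p_a_gt_b")
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE)
  tab
}

#' Hierarchical Bayesian group regressions of approach rate and RT
#'
#' Logistic regression of choice and linear regression of RT on group, with
#' subject-level random intercepts, fitted by MCMC (JAGS). The group
#' predictor is coded +1/2 for the first group and -1/2 for the second, so
#' the reported `p_a_gt_b` is the posterior probability that the first group
#' exceeds the second.
#'
#' @param data an `aac_dataset` or trial data.frame with exactly two groups.
#' @param n_samples posterior samples per chain after adaptation.
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @return List with `approach_rate` and `rt` `group_comparison` objects.
#' @export
behavioral_group_tests <- function(data, n_samples = 2000, n_chains = 2,
                                   seed = 1) {
  trials <- if (inherits(data, "aac_dataset")) data$trials else data
  glabs <- unique(trials$group)
  if (length(glabs) < 2) stop("need two groups for a group comparison")
  if (length(glabs) > 2) stop("only two-group comparisons are supported")
  counts <- table(trials$group, trials$subject_id)
  if (any(rowSums(counts > 0) < 2))
    stop("need at least 2 subjects per group")

  sid <- as.integer(factor(trials$subject_id))
  x <- ifelse(trials$group == glabs[1], 0.5, -0.5)
  logistic_model <- "model {
    for (t in 1:N) {
      y[t] ~ dbern(ilogit(b0 + bg * x[t] + u[s[t]]))
    }
    for (j in 1:S) { u[j] ~ dnorm(0, tau_u) }
    b0 ~ dnorm(0, 0.25)
    bg ~ dnorm(0, 0.25)
    tau_u <- pow(sd_u, -2)
    sd_u ~ dt(0, 1, 3) T(0,)
  }"
  linear_model <- "model {
    for (t in 1:N) {
      y[t] ~ dnorm(b0 + bg * x[t] + u[s[t]], tau)
    }
    for (j in 1:S) { u[j] ~ dnorm(0, tau_u) }
    b0 ~ dnorm(0, 0.01)
    bg ~ dnorm(0, 0.01)
    tau <- pow(sd_e, -2)
    sd_e ~ dt(0, 1, 3) T(0,)
    tau_u <- pow(sd_u, -2)
    sd_u ~ dt(0, 1, 3) T(0,)
  }"
  run_jags <- function(model, y) {
    m <- rjags::jags.model(
      textConnection(model),
      data = list(y = y, x = x, s = sid, N = nrow(trials),
                  S = max(sid)),
      inits = lapply(seq_len(n_chains), function(i)
        list(.RNG.name = "base::Mersenne-Twister",
             .RNG.seed = seed + i)),
      n.chains = n_chains, quiet = TRUE)
    s <- rjags::coda.samples(m, "bg", n.iter = n_samples)
    unlist(lapply(s, function(ch) as.numeric(ch[, "bg"])))
  }
  bg_choice <- run_jags(logistic_model, trials$choice)
  bg_rt <- run_jags(linear_model, trials$rt)
  half <- function(d, param) {
    p <- mean(d > 0) + 0.5 * mean(d == 0)
    structure(list(parameter = param, diff = d, p_a_gt_b = p,
                   hdi95 = hdi(d), mean_a = NA_real_, mean_b = NA_real_),
              class = "group_comparison")
  }
  list(approach_rate = half(bg_choice,
                            paste0("approach_rate: ", glabs[1], " - ",
                                   glabs[2])),
       rt = half(bg_rt, paste0("rt: ", glabs[1], " - ", glabs[2])))
}

#' Two-way intraclass correlation for test-retest reliability
#'
#' Two-way mixed-effects, consistency, single-measures ICC (ICC(C,1)) of
#' paired per-subject parameter estimates across two sessions, with its
#' F-test.
#'
#' @param session1,session2 numeric vectors of per-subject values, paired by
#'   position (same subjects, same order).
#' @return List with `icc`, `F`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' s <- rnorm(20)
#' icc_two_way(s + rnorm(20, sd = .5), s + rnorm(20, sd = .5))
icc_two_way <- function(session1, session2) {
  if (length(session1) != length(session2))
    stop("sessions must be paired (equal length, same subjects)")
  n <- length(session1)
  if (n < 3) stop("need at least 3 paired subjects")
  if (anyNA(session1) || anyNA(session2)) stop("missing values in input")
  k <- 2
  y <- c(session1, session2)
  subj <- rep(seq_len(n), k)
  sess <- rep(seq_len(k), each = n)
  grand <- mean(y)
  ms <- tapply(y, subj, mean)
  mc <- tapply(y, sess, mean)
  ssb <- k * sum((ms - grand)^2)          # between subjects
  ssc <- n * sum((mc - grand)^2)          # between sessions
  sst <- sum((y - grand)^2)
  sse <- sst - ssb - ssc
  msr <- ssb / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  Fv <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  list(icc = icc, F = Fv, df1 = df1, df2 = df2, p_value = p)
}
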