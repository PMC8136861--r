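#' Specify a model variant and grouping mode
#'
#' A model variant selects which components enter the three trial-level
#' parameter regressions (the model-comparison ladder): linear vs log
#' reward, zero-offer dummies, conflict on threshold, the Pavlovian dummy on
#' starting point, and the ROI regressors. The grouping mode controls the
#' hierarchical structure: `"single-group"` fits one population
#' (subject-level intercepts, group-level slopes); `"separate-groups"` fits
#' each group independently with the same priors; `"mixed-effect"` fits both
#' groups jointly with group offsets on every coefficient;
#' `"single-population"` estimates *all* coefficients at the subject level
#' under one population distribution (the classification variant, which
#' avoids diagnosis-dependent shrinkage).
#'
#' @param variant `"final"` (log reward + dReward + conflict-on-a +
#'   Pavlovian-on-z + ROI regressors), `"final-behavioral"` (final without
#'   ROI regressors), `"base"` (linear reward only), or `"custom"`.
#' @param grouping hierarchical grouping mode.
#' @param reward_fn,d_reward,d_averse,conflict_on_a,pavlovian_on_z,roi
#'   component flags, used when `variant = "custom"` (and overridable
#'   otherwise).
#' @return A list of class `ddm_model_spec`.
#' @export
#' @examples
#' ddm_model_spec("final")
#' ddm_model_spec("custom", reward_fn = "linear", roi = FALSE)
ddm_model_spec <- function(variant = c("final", "final-behavioral", "base",
                                       "custom"),
                           grouping = c("single-group", "separate-groups",
                                        "mixed-effect", "single-population"),
                           reward_fn = NULL, d_reward = NULL,
                           d_averse = NULL, conflict_on_a = NULL,
                           pavlovian_on_z = NULL, roi = NULL) {
  variant <- match.arg(variant)
  grouping <- match.arg(grouping)
  base <- switch(variant,
    "final" = list(reward_fn = "log", d_reward = TRUE, d_averse = FALSE,
                   conflict_on_a = TRUE, pavlovian_on_z = TRUE, roi = TRUE),
    "final-behavioral" = list(reward_fn = "log", d_reward = TRUE,
                              d_averse = FALSE, conflict_on_a = TRUE,
                              pavlovian_on_z = TRUE, roi = FALSE),
    "base" = list(reward_fn = "linear", d_reward = FALSE, d_averse = FALSE,
                  conflict_on_a = FALSE, pavlovian_on_z = FALSE,
                  roi = FALSE),
    "custom" = list(reward_fn = "log", d_reward = TRUE, d_averse = FALSE,
                    conflict_on_a = TRUE, pavlovian_on_z = TRUE,
                    roi = FALSE))
  ovr <- list(reward_fn = reward_fn, d_reward = d_reward,
              d_averse = d_averse, conflict_on_a = conflict_on_a,
              pavlovian_on_z = pavlovian_on_z, roi = roi)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) base[[nm]] <- ovr[[nm]]
  stopifnot(base$reward_fn %in% c("log", "linear"))
  structure(c(list(variant = variant, grouping = grouping), base),
            class = "ddm_model_spec")
}

#' The model-comparison ladder
#'
#' Named list of behavioral model variants, from a linear-reward base model
#' to the full model, for [run_model_ladder()]. ROI regressors are excluded
#' throughout (components are compared on behavior), matching how the
#' behavioral model was selected before neural regressors were added.
#'
#' @return Named list of [ddm_model_spec()] objects.
#' @export
model_ladder <- function() {
  v <- function(...) ddm_model_spec("custom", roi = FALSE, ...)
  list(
    base_linear   = v(reward_fn = "linear", d_reward = FALSE,
                      conflict_on_a = FALSE, pavlovian_on_z = FALSE),
    log_reward    = v(reward_fn = "log", d_reward = FALSE,
                      conflict_on_a = FALSE, pavlovian_on_z = FALSE),
    log_dreward   = v(reward_fn = "log", d_reward = TRUE,
                      conflict_on_a = FALSE, pavlovian_on_z = FALSE),
    plus_daverse  = v(reward_fn = "log", d_reward = TRUE, d_averse = TRUE,
                      conflict_on_a = FALSE, pavlovian_on_z = FALSE),
    plus_conflict = v(reward_fn = "log", d_reward = TRUE,
                      conflict_on_a = TRUE, pavlovian_on_z = FALSE),
    full          = v(reward_fn = "log", d_reward = TRUE,
                      conflict_on_a = TRUE, pavlovian_on_z = TRUE)
  )
}

#' Prior settings for hierarchical estimation
#'
#' Weakly informative priors on the intercept-type parameters (scaled to the
#' unit-diffusion DDM convention), noninformative zero-centered normals on
#' all slope coefficients, and half-normal priors on the between-subject
#' sds. All settings are configurable.
#'
#' @param a_intercept,v_intercept,z_intercept,ndt lists with `mean`, `sd`
#'   and support bounds `lb`, `ub` for the subject-level intercepts.
#' @param slope_sd sd of the zero-centered normal prior on slopes.
#' @param sigma_scale scale of the half-normal prior on between-subject sds.
#' @return A list of class `ddm_priors`.
#' @export
ddm_priors <- function(a_intercept = list(mean = 1.5, sd = 0.75, lb = 0,
                                          ub = Inf),
                       v_intercept = list(mean = 0, sd = 2, lb = -Inf,
                                          ub = Inf),
                       z_intercept = list(mean = 0.5, sd = 0.25, lb = 0,
                                          ub = 1),
                       ndt = list(mean = 0.4, sd = 0.35, lb = 0, ub = Inf),
                       slope_sd = 10, sigma_scale = 1) {
  structure(list(a_intercept = a_intercept, v_intercept = v_intercept,
                 z_intercept = z_intercept, ndt = ndt,
                 slope_sd = slope_sd, sigma_scale = sigma_scale),
            class = "ddm_priors")
}

# Split a trial table into per-subject sampler inputs under a model spec.
.prepare_data <- function(trials, spec, scope = "subject") {
  stopifnot(is.data.frame(trials))
  if (!"rt" %in% names(trials) || !"choice" %in% names(trials))
    stop("trial table must contain observed 'choice' and 'rt'")
  design <- build_design(trials, scope = scope)
  sids <- unique(trials$subject_id)
  glabs <- unique(trials$group)
  mixed <- spec$grouping == "mixed-effect"
  n_groups <- if (mixed) length(glabs) else 1L

  subjects <- vector("list", length(sids))
  for (k in seq_along(sids)) {
    idx <- trials$subject_id == sids[k]
    mm <- .design_matrices(design[idx, , drop = FALSE], spec)
    if (mixed && length(glabs) > 1) {
      gl <- trials$group[idx][1]
      for (fam in c("Xv", "Xa", "Xz")) {
        X <- mm[[fam]]
        slopes <- setdiff(colnames(X), "Intercept")
        if (length(slopes)) {
          for (g in glabs[-1]) {
            ext <- X[, slopes, drop = FALSE] * as.numeric(gl == g)
            colnames(ext) <- paste0(slopes, ":grp", g)
            X <- cbind(X, ext)
          }
          mm[[fam]] <- X
        }
      }
    }
    grp <- if (mixed) match(trials$group[idx][1], glabs) else 1L
    subjects[[k]] <- list(rt = trials$rt[idx],
                          upper = as.integer(trials$choice[idx]),
                          Xv = mm$Xv, Xa = mm$Xa, Xz = mm$Xz,
                          group = grp)
  }
  lev <- lapply(c(v = "Xv", a = "Xa", z = "Xz"), function(fam) {
    cn <- colnames(subjects[[1]][[fam]])
    if (spec$grouping == "single-population") rep(1L, length(cn))
    else as.integer(cn == "Intercept")
  })
  list(subjects = subjects, lev = lev, subject_ids = sids,
       group_labels = if (mixed) glabs else "all", n_groups = n_groups)
}

.prior_lists <- function(prep, priors, spec) {
  int_pr <- list(v = priors$v_intercept, a = priors$a_intercept,
                 z = priors$z_intercept)
  group <- list(); hyper <- list()
  for (f in c("v", "a", "z")) {
    cn <- colnames(prep$subjects[[1]][[paste0("X", f)]])
    p <- length(cn)
    gm <- rep(0, p); gs <- rep(priors$slope_sd, p)
    hm <- rep(0, p); hs <- rep(priors$slope_sd, p)
    hl <- rep(-Inf, p); hu <- rep(Inf, p)
    i <- which(cn == "Intercept")
    hm[i] <- int_pr[[f]]$mean; hs[i] <- int_pr[[f]]$sd
    hl[i] <- int_pr[[f]]$lb; hu[i] <- int_pr[[f]]$ub
    group[[f]] <- list(mean = gm, sd = gs)
    hyper[[f]] <- list(mean = hm, sd = hs, lb = hl, ub = hu)
  }
  list(group = group, hyper = hyper,
       ndt = list(mean = priors$ndt$mean, sd = priors$ndt$sd),
       sigma_scale = priors$sigma_scale)
}

.init_state <- function(prep) {
  S <- length(prep$subjects)
  G <- prep$n_groups
  init <- list()
  for (f in c("v", "a", "z")) {
    cn <- colnames(prep$subjects[[1]][[paste0("X", f)]])
    p <- length(cn)
    base <- switch(f, v = 0.5, a = 2.0, z = 0.5)
    jit <- switch(f, v = 0.3, a = 0.2, z = 0.03)
    B <- matrix(0, S, p, dimnames = list(NULL, cn))
    icol <- which(cn == "Intercept")
    B[, icol] <- base + rnorm(S, 0, jit)
    if (f == "a") B[, icol] <- pmax(B[, icol], 0.5)
    if (f == "z") B[, icol] <- pmin(pmax(B[, icol], 0.2), 0.8)
    slope_cols <- setdiff(seq_len(p), icol)
    for (j in slope_cols) B[, j] <- rnorm(1, 0, 0.05)
    init[[paste0("B", f)]] <- B
    mu <- matrix(0, p, G)
    mu[icol, ] <- mean(B[, icol])
    for (j in slope_cols) mu[j, ] <- B[1, j]
    init[[paste0("mu_", f)]] <- mu
    sdv <- rep(0.3, p); sdv[icol] <- switch(f, v = 0.3, a = 0.3, z = 0.05)
    init[[paste0("sd_", f)]] <- sdv
  }
  min_rt <- vapply(prep$subjects, function(s) min(s$rt), 0)
  init$ndt <- pmax(0.8 * min_rt * runif(S, 0.9, 1.0), 1e-3)
  init$mu_ndt <- rep(mean(init$ndt), G)
  init$sd_ndt <- 0.1
  init
}

# Parameter names mirroring the sampler's recording order exactly.
.param_names <- function(prep) {
  glabs <- prep$group_labels
  sids <- prep$subject_ids
  nm_g <- c(); nm_h <- c(); nm_s <- c()
  for (f in c("v", "a", "z")) {
    cn <- colnames(prep$subjects[[1]][[paste0("X", f)]])
    lev <- prep$lev[[f]]
    if (any(lev == 0))
      nm_g <- c(nm_g, paste0(f, "_", cn[lev == 0]))
    for (j in which(lev == 1)) {
      nm_h <- c(nm_h, paste0("mu_", f, "_", cn[j], "[", glabs, "]"),
                paste0("sd_", f, "_", cn[j]))
      nm_s <- c(nm_s, paste0(f, "_", cn[j], "[", sids, "]"))
    }
  }
  nm_h <- c(nm_h, paste0("mu_ndt[", glabs, "]"), "sd_ndt")
  nm_s <- c(nm_s, paste0("ndt[", sids, "]"))
  c(nm_g, nm_h, nm_s, "deviance")
}

.sampler_scales <- function(prep) {
  sc_g <- list(); sc_s <- list()
  for (f in c("v", "a", "z")) {
    cn <- colnames(prep$subjects[[1]][[paste0("X", f)]])
    icol <- cn == "Intercept"
    g <- rep(switch(f, v = 0.05, a = 0.03, z = 0.01), length(cn))
    s <- rep(switch(f, v = 0.1, a = 0.08, z = 0.02), length(cn))
    s[icol] <- switch(f, v = 0.25, a = 0.15, z = 0.03)
    sc_g[[f]] <- g; sc_s[[f]] <- s
  }
  list(group = sc_g, subject = sc_s, ndt = 0.02)
}

#' Fit the hierarchical affective DDM
#'
#' Hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs
#' MCMC. Subject-level parameters (always including the four intercept-type
#' parameters) are drawn from population normals with unknown means and sds;
#' group-level slopes get zero-centered normal priors; the likelihood is the
#' Wiener first-passage-time density of the per-trial parameters with a
#' density floor. Chains are run sequentially from overdispersed starts;
#' proposal adaptation is confined to burn-in. With grouping
#' `"separate-groups"` each group is fit independently and a list of fits is
#' returned.
#'
#' A non-fatal warning is issued when any group-level parameter's
#' Gelman-Rubin statistic is at or above `rhat_threshold`.
#'
#' @param data an `aac_dataset` or canonical trial data.frame.
#' @param spec a [ddm_model_spec()].
#' @param n_chains number of chains (paper protocol: 5).
#' @param n_samples total samples per chain including burn-in (paper
#'   protocol: 5000).
#' @param n_burn burn-in samples discarded per chain (paper protocol: 2500).
#' @param seed integer seed; identical seeds give identical draws.
#' @param priors a [ddm_priors()].
#' @param scope standardization scope passed to [build_design()].
#' @param rhat_threshold convergence warning threshold (default 1.1).
#' @param err,floor series truncation error and likelihood floor.
#' @return An object of class `aac_fit` with per-chain draw matrices
#'   (`$chains`), diagnostics (`$diagnostics$rhat`, `$diagnostics$ess`,
#'   DIC via [compute_dic()]), and the prepared data (`$prep`).
#' @export
fit_ddm <- function(data, spec = ddm_model_spec(), n_chains = 3,
                    n_samples = 1500, n_burn = 500, seed = 1,
                    priors = ddm_priors(), scope = "subject",
                    rhat_threshold = 1.1, err = 1e-7, floor = 1e-12) {
  trials <- if (inherits(data, "aac_dataset")) data$trials else data
  stopifnot(n_samples > n_burn, n_chains >= 1)

  if (spec$grouping == "separate-groups") {
    glabs <- unique(trials$group)
    sub_spec <- spec; sub_spec$grouping <- "single-group"
    fits <- lapply(seq_along(glabs), function(i)
      fit_ddm(trials[trials$group == glabs[i], , drop = FALSE], sub_spec,
              n_chains = n_chains, n_samples = n_samples, n_burn = n_burn,
              seed = seed + i, priors = priors, scope = scope,
              rhat_threshold = rhat_threshold, err = err, floor = floor))
    names(fits) <- glabs
    return(structure(fits, class = "aac_fit_list"))
  }

  prep <- .prepare_data(trials, spec, scope = scope)
  pr <- .prior_lists(prep, priors, spec)
  scales <- .sampler_scales(prep)
  control <- list(n_iter = as.integer(n_samples),
                  n_burn = as.integer(n_burn),
                  adapt_interval = 50L, target_acc = 0.44,
                  err = err, log_floor = log(floor),
                  n_groups = as.integer(prep$n_groups),
                  scale_group = scales$group, scale_subject = scales$subject,
                  scale_ndt = scales$ndt)
  pnames <- .param_names(prep)

  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, n_chains)
  chains <- vector("list", n_chains)
  n_floor <- 0
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    init <- .init_state(prep)
    res <- run_sampler_cpp(prep$subjects, prep$lev, pr, init, control)
    m <- res$draws
    colnames(m) <- pnames
    chains[[ch]] <- m
    n_floor <- n_floor + res$n_floor
  }

  fit <- structure(list(
    chains = chains, spec = spec, prep = prep, priors = priors,
    param_names = pnames, n_samples = n_samples, n_burn = n_burn,
    n_chains = n_chains, seed = seed, n_floor = n_floor
  ), class = "aac_fit")

  rh <- if (n_chains >= 2) compute_rhat(fit) else NULL
  ess <- tryCatch(
    colSums(do.call(rbind, lapply(chains, function(m)
      coda::effectiveSize(coda::mcmc(m))))),
    error = function(e) NULL)
  gl <- group_level_names(fit)
  fit$diagnostics <- list(
    rhat = rh, ess = ess, n_floor = n_floor,
    max_rhat_group = if (!is.null(rh)) max(rh[gl], na.rm = TRUE) else NA_real_)
  fit$diagnostics$dic <- compute_dic(fit)
  if (!is.null(rh) && is.finite(fit$diagnostics$max_rhat_group) &&
      fit$diagnostics$max_rhat_group >= rhat_threshold)
    warning(sprintf("convergence: max group-level Rhat = %.3f (threshold %g)",
                    fit$diagnostics$max_rhat_group, rhat_threshold))
  fit
}

#' @exportS3Method base::print
print.aac_fit <- function(x, ...) {
  cat("<aac_fit> ", x$spec$variant, " model (", x$spec$grouping, "), ",
      length(x$prep$subject_ids), " subjects, ", x$n_chains, " chains x ",
      x$n_samples, " samples (", x$n_burn, " burn-in)\n", sep = "")
  if (!is.null(x$diagnostics$rhat))
    cat("  max group-level Rhat: ",
        round(x$diagnostics$max_rhat_group, 4), "\n", sep = "")
  cat("  DIC: ", round(x$diagnostics$dic$dic, 1), " (pD = ",
      round(x$diagnostics$dic$pd, 1), ")\n", sep = "")
  invisible(x)
}

#' Names of group-level parameters of a fit
#'
#' Group-level slope coefficients plus the population means and sds of the
#' subject-level parameters (everything except per-subject values and the
#' deviance).
#'
#' @param fit an `aac_fit`.
#' @return Character vector of parameter names.
#' @export
group_level_names <- function(fit) {
  nm <- fit$param_names
  keep <- (!grepl("\\[", nm) | grepl("^mu_", nm)) & nm != "deviance"
  nm[keep]
}

#' Extract posterior draws
#'
#' @param fit an `aac_fit`.
#' @param pars parameter names (default: all).
#' @param chain chain index, or `NULL` to pool chains (rbind).
#' @return Matrix of draws (iterations x parameters).
#' @export
posterior_draws <- function(fit, pars = NULL, chain = NULL) {
  stopifnot(inherits(fit, "aac_fit"))
  m <- if (is.null(chain)) do.call(rbind, fit$chains) else
    fit$chains[[chain]]
  if (is.null(pars)) m else {
    miss <- setdiff(pars, colnames(m))
    if (length(miss)) stop("unknown parameter(s): ",
                           paste(miss, collapse = ", "))
    m[, pars, drop = FALSE]
  }
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic (non-split) Gelman-Rubin statistic per parameter, computed from
#' the post-burn-in draws of two or more chains:
#' `sqrt(((n-1)/n * W + B/n) / W)`. Chains that are exact copies give
#' `sqrt((n-1)/n)`, just below 1.
#'
#' @param x an `aac_fit` or list of chain draw matrices with equal columns.
#' @return Named vector of Rhat values.
#' @export
compute_rhat <- function(x) {
  chains <- if (inherits(x, "aac_fit")) x$chains else x
  if (length(chains) < 2) stop("need at least 2 chains for Rhat")
  n <- nrow(chains[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    draws <- vapply(chains, function(m) m[, j], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_n <- var(colMeans(draws))  # B/n
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B_n) / W)
  }, numeric(1)) -> rh
  names(rh) <- colnames(chains[[1]])
  rh
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(posterior means)` the effective number of parameters,
#' computed on the same likelihood (with floor) as the sampler.
#'
#' @param fit an `aac_fit`.
#' @return List with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "aac_fit"))
  m <- posterior_draws(fit)
  dbar <- mean(m[, "deviance"])
  post <- colMeans(m)
  prep <- fit$prep
  dhat <- 0
  for (k in seq_along(prep$subjects)) {
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
        post[[nm]]
      }, numeric(1))
      lp[[f]] <- as.numeric(X %*% b)
    }
    ndt_i <- post[[paste0("ndt[", sid, "]")]]
    ll <- wfpt_loglik_cpp(s$rt, s$upper, lp$v, lp$a, lp$z,
                          rep(ndt_i, length(s$rt)), log(1e-12), 1e-7)
    if (!ll$valid) stop("non-finite deviance at posterior means")
    dhat <- dhat - 2 * ll$loglik
  }
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Fit a ladder of model variants and rank them by DIC
#'
#' Fits each spec to the same data and returns the DIC table sorted
#' ascending (lower is better), flagging the winner. Failed fits are kept in
#' the table with an annotation.
#'
#' @param data an `aac_dataset` or trial data.frame.
#' @param ladder named list of [ddm_model_spec()]s (default [model_ladder()]).
#' @param ... passed to [fit_ddm()].
#' @return data.frame with columns `model`, `dic`, `pd`, `winner`, `note`,
#'   sorted by DIC; fits attached as attribute `fits`.
#' @export
run_model_ladder <- function(data, ladder = model_ladder(), ...) {
  stopifnot(length(ladder) >= 1)
  if (is.null(names(ladder)))
    names(ladder) <- paste0("model_", seq_along(ladder))
  fits <- vector("list", length(ladder))
  names(fits) <- names(ladder)
  rows <- lapply(names(ladder), function(nm) {
    f <- tryCatch(fit_ddm(data, ladder[[nm]], ...), error = identity)
    if (inherits(f, "error"))
      return(data.frame(model = nm, dic = NA_real_, pd = NA_real_,
                        note = conditionMessage(f)))
    fits[[nm]] <<- f
    data.frame(model = nm, dic = f$diagnostics$dic$dic,
               pd = f$diagnostics$dic$pd, note = "")
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dic), ]
  tab$winner <- !is.na(tab$dic) & tab$dic == min(tab$dic, na.rm = TRUE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
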