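.zscore <- function(x) (x - mean(x)) / sd(x)

#' Build the standardized trial-level design
#'
#' Computes the regressors of the three parameter regressions from a trial
#' table: the log-reward term (`log(reward)` for positive reward, 0 at zero
#' reward, with the `d_reward` dummy absorbing the zero-offer offset), the
#' linear reward term, aversiveness, conflict (absolute difference of the raw
#' offers), zero-offer dummies, the Pavlovian mapping dummy, and the four ROI
#' series. All non-dummy regressors are z-transformed (mean 0, sd 1) within
#' subject by default, or across the pooled sample with `scope = "pooled"`;
#' dummies are left untouched.
#'
#' @param trials data.frame with columns `subject_id`, `reward`,
#'   `aversiveness`, `pavlovian` and the ROI columns `caudate`, `pacc`,
#'   `nacc`, `stn`.
#' @param scope standardization scope, `"subject"` (default) or `"pooled"`.
#' @return data.frame of design rows aligned with `trials`, with columns
#'   `log_reward_z`, `reward_z`, `aversiveness_z`, `conflict_z`, `d_reward`,
#'   `d_averse`, `pavlovian`, `caudate`, `pacc`, `nacc`, `stn`.
#' @export
build_design <- function(trials, scope = c("subject", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  need <- c("subject_id", "reward", "aversiveness", "pavlovian", .rois)
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(trials$reward == 0 & trials$aversiveness == 0))
    stop("inadmissible trial: reward and aversiveness both 0")

  raw <- data.frame(
    log_reward   = ifelse(trials$reward > 0, log(trials$reward), 0),
    reward       = trials$reward,
    aversiveness = trials$aversiveness,
    conflict     = abs(trials$reward - trials$aversiveness),
    caudate      = trials$caudate,
    pacc         = trials$pacc,
    nacc         = trials$nacc,
    stn          = trials$stn
  )
  groups <- if (scope == "subject") trials$subject_id else
    rep("all", nrow(trials))
  scaled <- raw
  for (col in names(raw)) {
    for (s in unique(groups)) {
      idx <- groups == s
      if (sd(raw[idx, col]) < 1e-12)
        stop("degenerate design: regressor '", col,
             "' is constant for subject '", s, "'")
      scaled[idx, col] <- .zscore(raw[idx, col])
    }
  }
  data.frame(
    log_reward_z   = scaled$log_reward,
    reward_z       = scaled$reward,
    aversiveness_z = scaled$aversiveness,
    conflict_z     = scaled$conflict,
    d_reward       = as.numeric(trials$reward == 0),
    d_averse       = as.numeric(trials$aversiveness == 0),
    pavlovian      = as.numeric(trials$pavlovian),
    caudate        = scaled$caudate,
    pacc           = scaled$pacc,
    nacc           = scaled$nacc,
    stn            = scaled$stn
  )
}

#' Map a coefficient set and design rows to trial-level DDM parameters
#'
#' Applies the three linear parameter regressions with identity links:
#' \deqn{v_t = \beta_0^v + \beta_r \,\mathrm{logreward}_t +
#'   \beta_s \,\mathrm{aversiveness}_t + \beta_c \,\mathrm{caudate}_t +
#'   \beta_p \,\mathrm{pACC}_t + \beta_{rc}\, \mathrm{logreward}_t\,
#'   \mathrm{caudate}_t + \beta_{sp}\,\mathrm{aversiveness}_t\,
#'   \mathrm{pACC}_t + \beta_d\, \mathrm{dReward}_t}
#' and analogously for threshold (`intercept`, STN, conflict, conflict:STN)
#' and starting point (`intercept`, Pavlovian dummy, accumbens,
#' accumbens:Pavlovian); the non-decision time is the subject-level constant
#' `ndt["intercept"]`.
#'
#' @param coeffs a [coef_set()].
#' @param design design rows from [build_design()].
#' @param validate error if any trial's `a <= 0` or `z` outside (0,1)
#'   (samplers instead treat such parameter vectors as zero posterior mass).
#' @return data.frame with per-trial columns `v`, `a`, `z`, `ndt`.
#' @export
compute_trial_params <- function(coeffs, design, validate = TRUE) {
  stopifnot(inherits(coeffs, "coef_set"))
  d <- coeffs$drift; a <- coeffs$threshold; s <- coeffs$start
  v_t <- d[["intercept"]] +
    d[["reward"]] * design$log_reward_z +
    d[["aversiveness"]] * design$aversiveness_z +
    d[["caudate"]] * design$caudate +
    d[["pacc"]] * design$pacc +
    d[["reward:caudate"]] * design$log_reward_z * design$caudate +
    d[["aversiveness:pacc"]] * design$aversiveness_z * design$pacc +
    d[["d_reward"]] * design$d_reward
  a_t <- a[["intercept"]] +
    a[["stn"]] * design$stn +
    a[["conflict"]] * design$conflict_z +
    a[["conflict:stn"]] * design$conflict_z * design$stn
  z_t <- s[["intercept"]] +
    s[["pavlovian"]] * design$pavlovian +
    s[["accumbens"]] * design$nacc +
    s[["accumbens:pavlovian"]] * design$nacc * design$pavlovian
  bad <- a_t <= 0 | z_t <= 0 | z_t >= 1
  if (validate && any(bad))
    stop("constraint violation (a <= 0 or z outside (0,1)) on trial(s): ",
         paste(head(which(bad), 10), collapse = ", "))
  data.frame(v = v_t, a = a_t, z = z_t,
             ndt = rep(coeffs$ndt[["intercept"]], nrow(design)))
}

# Model matrices for one subject's design under a model variant.
# Returns Xv/Xa/Xz with named columns; intercept first.
.design_matrices <- function(design, variant) {
  rew <- if (variant$reward_fn == "log") design$log_reward_z else
    design$reward_z
  Xv <- cbind(Intercept = 1, reward = rew,
              aversiveness = design$aversiveness_z)
  if (variant$roi) {
    Xv <- cbind(Xv, caudate = design$caudate, pacc = design$pacc,
                "reward:caudate" = rew * design$caudate,
                "aversiveness:pacc" = design$aversiveness_z * design$pacc)
  }
  if (variant$d_reward) Xv <- cbind(Xv, d_reward = design$d_reward)
  if (variant$d_averse) Xv <- cbind(Xv, d_averse = design$d_averse)

  Xa <- cbind(Intercept = rep(1, nrow(design)))
  if (variant$roi) Xa <- cbind(Xa, stn = design$stn)
  if (variant$conflict_on_a) {
    Xa <- cbind(Xa, conflict = design$conflict_z)
    if (variant$roi)
      Xa <- cbind(Xa, "conflict:stn" = design$conflict_z * design$stn)
  }

  Xz <- cbind(Intercept = rep(1, nrow(design)))
  if (variant$pavlovian_on_z) Xz <- cbind(Xz, pavlovian = design$pavlovian)
  if (variant$roi) {
    Xz <- cbind(Xz, accumbens = design$nacc)
    if (variant$pavlovian_on_z)
      Xz <- cbind(Xz, "accumbens:pavlovian" = design$nacc * design$pavlovian)
  }
  list(Xv = Xv, Xa = Xa, Xz = Xz)
}
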