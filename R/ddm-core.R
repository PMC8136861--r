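#' Construct and validate a set of trial-level DDM parameters
#'
#' Bundles the four decision parameters entering the Wiener first-passage-time
#' likelihood: drift rate `v` (evidence/s, positive toward approach), boundary
#' separation `a` (> 0), relative starting point `z` (fraction of `a`, in
#' (0,1)) and non-decision time `ndt` (s, >= 0). The intra-trial diffusion
#' coefficient is fixed at 1, so all parameters are on that scale.
#'
#' @param v drift rate.
#' @param a boundary separation, must be positive.
#' @param z relative starting point, must lie strictly between 0 and 1.
#' @param ndt non-decision time in seconds, must be non-negative.
#' @return A list of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(v = 0.7, a = 2, z = 0.5, ndt = 0.3)
ddm_params <- function(v, a, z, ndt) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(z), is.numeric(ndt))
  if (any(!is.finite(c(v, a, z, ndt))))
    stop("ddm parameters must be finite")
  if (any(a <= 0)) stop("boundary separation 'a' must be positive")
  if (any(z <= 0 | z >= 1)) stop("starting point 'z' must be in (0, 1)")
  if (any(ndt < 0)) stop("non-decision time 'ndt' must be non-negative")
  structure(list(v = v, a = a, z = z, ndt = ndt), class = "ddm_params")
}

.as_upper <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    choice <- as.character(choice)
    bad <- !choice %in% c("approach", "avoid")
    if (any(bad)) stop("choice must be 'approach' or 'avoid'")
    as.integer(choice == "approach")
  } else {
    if (any(!choice %in% c(0, 1))) stop("numeric choice must be 0/1")
    as.integer(choice)
  }
}

#' Wiener first-passage-time density
#'
#' Density of the DDM's joint choice/response-time distribution at `rt` for
#' the named absorbing bound (`"approach"` = upper, `"avoid"` = lower),
#' computed with the small-time/large-time series expansions and automatic
#' regime selection; the truncation error of the series is bounded by `err`.
#' The lower-bound density is obtained by the reflection `v -> -v`,
#' `z -> 1 - z`. Response times at or below the non-decision time have zero
#' density.
#'
#' @param rt response time(s) in seconds.
#' @param choice `"approach"`/`"avoid"` (or 1/0); recycled against `rt`.
#' @param params a [ddm_params()] object.
#' @param err absolute truncation error bound for the series.
#' @return Numeric vector of densities.
#' @export
#' @examples
#' p <- ddm_params(v = 0.7, a = 2, z = 0.5, ndt = 0.3)
#' wfpt_density(seq(0.4, 2, by = 0.4), "approach", p)
wfpt_density <- function(rt, choice, params, err = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  wfpt_pdf_cpp(rt, .as_upper(choice), params$v, params$a, params$z,
               params$ndt, err)
}

#' Analytic probability of absorption at the upper (approach) bound
#'
#' Closed form `(1 - exp(-2 v z a)) / (1 - exp(-2 v a))` for `v != 0`, with
#' the continuous limit `z` at `v = 0`.
#'
#' @inheritParams wfpt_density
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' upper_bound_probability(ddm_params(v = 0.5, a = 2, z = 0.5, ndt = 0))
upper_bound_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  v <- params$v; a <- params$a; z <- params$z
  ifelse(abs(v) < 1e-9,
         z,
         (1 - exp(-2 * v * z * a)) / (1 - exp(-2 * v * a)))
}

#' Simulate DDM trials by Euler-Maruyama integration
#'
#' Integrates the diffusion from `z * a` between absorbing bounds 0 and `a`
#' with drift `v` and unit diffusion coefficient; the response time is the
#' first-crossing time plus `ndt`. By default an exact Brownian-bridge
#' crossing probability is applied inside each step, which removes most of
#' the first-passage discretization bias of the plain scheme. Paths that
#' exceed `max_t` are resampled (the count is returned); if a path still
#' fails after `max_retries` resamples an error names the parameter set.
#'
#' `simulate_trial` draws one trial at fixed parameters; `simulate_trials`
#' draws one trial per row of trial-varying parameters.
#'
#' @inheritParams wfpt_density
#' @param n number of trials to simulate.
#' @param dt Euler step size in seconds.
#' @param max_t cap on the decision time in seconds.
#' @param max_retries resamples allowed per trial when the cap is exceeded.
#' @param bridge apply the within-step bridge crossing correction.
#' @param seed integer seed for the simulator's own RNG; if `NULL`, one is
#'   drawn from R's RNG stream.
#' @return A data.frame with columns `rt` and `choice` (`"approach"` /
#'   `"avoid"`), with attribute `n_resampled`.
#' @export
#' @examples
#' simulate_trial(ddm_params(v = 0.7, a = 2, z = 0.5, ndt = 0.3), n = 5,
#'                seed = 1)
simulate_trial <- function(params, n = 1, dt = 1e-3, max_t = 20,
                           max_retries = 10, bridge = TRUE, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), dt > 0, n >= 1)
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  out <- sim_fpt_batch_cpp(as.integer(n), params$v, params$a, params$z,
                           params$ndt, dt, max_t, as.integer(max_retries),
                           bridge, as.double(seed))
  res <- data.frame(rt = out$rt,
                    choice = ifelse(out$choice == 1, "approach", "avoid"))
  attr(res, "n_resampled") <- out$n_resampled
  res
}

#' @rdname simulate_trial
#' @param v,a,z,ndt numeric vectors of per-trial parameters (recycled to a
#'   common length).
#' @export
simulate_trials <- function(v, a, z, ndt, dt = 1e-3, max_t = 20,
                            max_retries = 10, bridge = TRUE, seed = NULL) {
  stopifnot(dt > 0)
  n <- max(length(v), length(a), length(z), length(ndt))
  v <- rep_len(v, n); a <- rep_len(a, n)
  z <- rep_len(z, n); ndt <- rep_len(ndt, n)
  if (any(a <= 0) || any(z <= 0 | z >= 1) || any(ndt < 0))
    stop("invalid trial parameters passed to simulator")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  out <- sim_trials_cpp(v, a, z, ndt, dt, max_t, as.integer(max_retries),
                        bridge, as.double(seed))
  res <- data.frame(rt = out$rt,
                    choice = ifelse(out$choice == 1, "approach", "avoid"))
  attr(res, "n_resampled") <- out$n_resampled
  res
}

#' Trial log-likelihood with a density floor
#'
#' Log of [wfpt_density()], floored at `log(floor)` so that samplers remain
#' finite when a trial's density underflows (e.g. `rt <= ndt`).
#'
#' @inheritParams wfpt_density
#' @param floor density floor (default `1e-12`).
#' @return Numeric vector of log densities.
#' @export
trial_loglik <- function(rt, choice, params, floor = 1e-12, err = 1e-7) {
  d <- wfpt_density(rt, choice, params, err = err)
  pmax(log(d), log(floor))
}
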