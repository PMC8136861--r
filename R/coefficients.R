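.coef_slots <- list(
  threshold = c("intercept", "stn", "conflict", "conflict:stn"),
  ndt       = "intercept",
  drift     = c("intercept", "reward", "aversiveness", "caudate", "pacc",
                "reward:caudate", "aversiveness:pacc", "d_reward"),
  start     = c("intercept", "pavlovian", "accumbens", "accumbens:pavlovian")
)

#' Coefficient set of the three trial-level parameter regressions
#'
#' Intercepts and slopes mapping the standardized trial design onto the DDM
#' parameters: 4 threshold coefficients, 1 non-decision-time intercept,
#' 8 drift coefficients and 4 starting-point coefficients. Slot names are
#' checked against the canonical list; missing slopes default to 0, but each
#' regression's intercept must be supplied.
#'
#' @param threshold,ndt,drift,start named numeric vectors; see
#'   `coef_slot_names()` for the slot names of each regression.
#' @return A list of class `coef_set`.
#' @export
#' @examples
#' coef_set(threshold = c(intercept = 2), ndt = c(intercept = 0.4),
#'          drift = c(intercept = 0.5, reward = 0.7),
#'          start = c(intercept = 0.5))
coef_set <- function(threshold, ndt, drift, start) {
  given <- list(threshold = threshold, ndt = ndt, drift = drift,
                start = start)
  out <- lapply(names(.coef_slots), function(block) {
    slots <- .coef_slots[[block]]
    x <- given[[block]]
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("coefficients for '", block, "' must be named")
    bad <- setdiff(names(x), slots)
    if (length(bad))
      stop("unknown ", block, " coefficient(s): ", paste(bad, collapse = ", "))
    if (!"intercept" %in% names(x))
      stop("'", block, "' needs an intercept")
    full <- setNames(numeric(length(slots)), slots)
    full[names(x)] <- x
    full
  })
  names(out) <- names(.coef_slots)
  structure(out, class = "coef_set")
}

#' @rdname coef_set
#' @export
coef_slot_names <- function() .coef_slots

#' Reference group-mean coefficient sets
#'
#' Published group posterior means of the final model for the healthy-control
#' (HC) and depressed (MDD) groups, usable as generating values in
#' simulation studies.
#'
#' @param group `"HC"` or `"MDD"`.
#' @return A [coef_set()].
#' @export
#' @examples
#' reference_coefficients("HC")$drift[["reward"]]
reference_coefficients <- function(group = c("HC", "MDD")) {
  group <- match.arg(group)
  if (group == "HC") {
    coef_set(
      threshold = c(intercept = 2.244, stn = 0.055, conflict = 0.182,
                    "conflict:stn" = 0.042),
      ndt = c(intercept = 0.737),
      drift = c(intercept = 0.665, reward = 0.701, aversiveness = -0.564,
                caudate = 0.012, pacc = 0.035, "reward:caudate" = -0.027,
                "aversiveness:pacc" = -0.006, d_reward = -1.105),
      start = c(intercept = 0.536, pavlovian = 0.018, accumbens = 0.009,
                "accumbens:pavlovian" = -0.001))
  } else {
    coef_set(
      threshold = c(intercept = 2.259, stn = 0.058, conflict = 0.145,
                    "conflict:stn" = 0.008),
      ndt = c(intercept = 0.661),
      drift = c(intercept = 0.783, reward = 0.577, aversiveness = -0.571,
                caudate = -0.035, pacc = 0.100, "reward:caudate" = 0.014,
                "aversiveness:pacc" = -0.017, d_reward = -0.974),
      start = c(intercept = 0.497, pavlovian = -0.014, accumbens = -0.014,
                "accumbens:pavlovian" = 0.011))
  }
}

#' Specification of a simulated group
#'
#' Group label, group-mean coefficients, and between-subject standard
#' deviations of the subject-level intercept parameters (threshold, drift and
#' starting-point intercepts and the non-decision time), mirroring the
#' estimation model's hierarchical structure in which only intercept-type
#' parameters vary by subject.
#'
#' @param label group name, e.g. `"HC"`.
#' @param coefficients a [coef_set()] of group means.
#' @param subject_sd named non-negative numeric vector with entries
#'   `a_intercept`, `v_intercept`, `z_intercept`, `ndt`.
#' @return A list of class `group_spec`.
#' @export
#' @examples
#' group_spec("HC", reference_coefficients("HC"))
group_spec <- function(label, coefficients,
                       subject_sd = c(a_intercept = 0.3, v_intercept = 0.4,
                                      z_intercept = 0.04, ndt = 0.1)) {
  stopifnot(inherits(coefficients, "coef_set"))
  need <- c("a_intercept", "v_intercept", "z_intercept", "ndt")
  if (!all(need %in% names(subject_sd)))
    stop("subject_sd must name: ", paste(need, collapse = ", "))
  subject_sd <- subject_sd[need]
  if (any(subject_sd < 0)) stop("subject_sd entries must be non-negative")
  structure(list(label = label, coefficients = coefficients,
                 subject_sd = subject_sd), class = "group_spec")
}
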