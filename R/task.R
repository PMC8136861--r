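#' Generate an approach-avoidance conflict task design
#'
#' Draws trials from the offer grid of the task: 16 reward levels crossed
#' with 6 aversiveness levels, both equally spaced on `[0, 5]`, excluding the
#' cell where both offers are 0. Offers are sampled uniformly over the 95
#' admissible cells; the Pavlovian response-mapping dummy (1 = push to
#' approach) is assigned randomly and counterbalanced to within one trial.
#' Trials are split into consecutive runs of (near-)equal length.
#'
#' @param n_trials number of trials (default 105).
#' @param n_runs number of runs (default 3).
#' @param seed optional integer seed.
#' @param reward_levels,aversiveness_levels offer level sets.
#' @return A data.frame of class `task_design` with columns `run`, `trial`,
#'   `reward`, `aversiveness`, `pavlovian`, and the level sets as attributes.
#' @export
#' @examples
#' d <- generate_task(seed = 1)
#' table(d$pavlovian)
generate_task <- function(n_trials = 105, n_runs = 3, seed = NULL,
                          reward_levels = seq(0, 5, length.out = 16),
                          aversiveness_levels = seq(0, 5, length.out = 6)) {
  if (n_trials < 1 || n_runs < 1) stop("n_trials and n_runs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(reward = reward_levels,
                      aversiveness = aversiveness_levels)
  grid <- grid[!(grid$reward == 0 & grid$aversiveness == 0), ]
  cells <- grid[sample.int(nrow(grid), n_trials, replace = TRUE), ]
  out <- data.frame(
    run = sort(rep(seq_len(n_runs), length.out = n_trials)),
    trial = seq_len(n_trials),
    reward = cells$reward,
    aversiveness = cells$aversiveness,
    pavlovian = sample(rep(c(0, 1), length.out = n_trials)),
    row.names = NULL
  )
  attr(out, "reward_levels") <- reward_levels
  attr(out, "aversiveness_levels") <- aversiveness_levels
  class(out) <- c("task_design", "data.frame")
  out
}

#' Generate per-trial ROI activation estimates
#'
#' Emulates trial-by-trial activation estimates for the four regions of
#' interest (caudate, pACC, nucleus accumbens, STN). Each series is Gaussian
#' noise, optionally linearly coupled to the z-scored offers, and is
#' z-scored across the design's trials (the within-subject scale of
#' single-trial estimates). With all couplings 0 (the default) the series
#' are independent standard normals.
#'
#' @param design a [generate_task()] design.
#' @param coupling named list with entries among `caudate`, `pacc`, `nacc`,
#'   `stn`, each a named numeric vector with weights for `reward` and/or
#'   `aversiveness` applied to the z-scored offers before noise is added.
#' @param noise_sd positive noise standard deviation.
#' @param seed optional integer seed.
#' @return Matrix with one row per trial and columns `caudate`, `pacc`,
#'   `nacc`, `stn`, each with mean 0 and sd 1.
#' @export
generate_roi_signals <- function(design, coupling = NULL, noise_sd = 1,
                                 seed = NULL) {
  stopifnot(nrow(design) > 0)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  rz <- .zscore(design$reward)
  az <- .zscore(design$aversiveness)
  out <- sapply(.rois, function(roi) {
    w <- coupling[[roi]]
    signal <- (if (!is.null(w) && "reward" %in% names(w))
      w[["reward"]] * rz else 0) +
      (if (!is.null(w) && "aversiveness" %in% names(w))
        w[["aversiveness"]] * az else 0)
    .zscore(signal + rnorm(n, sd = noise_sd))
  })
  colnames(out) <- .rois
  out
}

.draw_subject_intercepts <- function(spec, max_tries = 1000) {
  m <- spec$coefficients
  s <- spec$subject_sd
  for (k in seq_len(max_tries)) {
    x <- c(a_intercept = rnorm(1, m$threshold[["intercept"]],
                               s[["a_intercept"]]),
           v_intercept = rnorm(1, m$drift[["intercept"]],
                               s[["v_intercept"]]),
           z_intercept = rnorm(1, m$start[["intercept"]],
                               s[["z_intercept"]]),
           ndt = rnorm(1, m$ndt[["intercept"]], s[["ndt"]]))
    if (x[["a_intercept"]] > 0 && x[["z_intercept"]] > 0 &&
        x[["z_intercept"]] < 1 && x[["ndt"]] >= 0)
      return(x)
  }
  stop("could not draw admissible subject intercepts for group ",
       spec$label)
}

#' Generate a synthetic approach-avoidance dataset from the model
#'
#' For each subject: subject-level intercepts (threshold, drift and
#' starting-point intercepts, non-decision time) are drawn from the group
#' means with the group's between-subject sds (redrawn if inadmissible); a
#' fresh task design and ROI series are generated; the standardized design
#' is mapped to per-trial DDM parameters via [compute_trial_params()]; and
#' each trial's choice and RT is simulated by Euler-Maruyama integration.
#' True generating parameters are recorded for recovery testing.
#'
#' @param groups a [group_spec()] or list of them.
#' @param n_subjects_per_group subjects per group (recycled over groups).
#' @param n_trials,n_runs task design size per subject.
#' @param roi_coupling,noise_sd passed to [generate_roi_signals()].
#' @param dt simulator step size (s).
#' @param seed integer seed; fixed seeds give bit-identical datasets.
#' @param session session index recorded in the trial table.
#' @return Object of class `aac_dataset`: list with `trials` (the canonical
#'   trial table), `truth` (per-subject intercepts and the generating group
#'   coefficients) and `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(group_spec("HC", reference_coefficients("HC")),
#'                        n_subjects_per_group = 2, seed = 1)
#' head(ds$trials)
generate_dataset <- function(groups, n_subjects_per_group, n_trials = 105,
                             n_runs = 3, roi_coupling = NULL, noise_sd = 1,
                             dt = 1e-3, seed = NULL, session = 1) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "group_spec")))
  n_subjects_per_group <- rep_len(n_subjects_per_group, length(groups))
  if (any(n_subjects_per_group <= 0)) stop("n_subjects_per_group must be > 0")
  if (!is.null(seed)) set.seed(seed)

  trials <- list()
  subj_truth <- list()
  trial_truth <- list()
  idx <- 0
  for (gi in seq_along(groups)) {
    spec <- groups[[gi]]
    for (si in seq_len(n_subjects_per_group[gi])) {
      idx <- idx + 1
      sid <- sprintf("%s_%02d", spec$label, si)
      ints <- .draw_subject_intercepts(spec)
      design <- generate_task(n_trials = n_trials, n_runs = n_runs)
      roi <- generate_roi_signals(design, coupling = roi_coupling,
                                  noise_sd = noise_sd)
      tab <- data.frame(subject_id = sid, group = spec$label,
                        session = session, design, roi)
      drows <- build_design(tab)
      co <- spec$coefficients
      co$threshold[["intercept"]] <- ints[["a_intercept"]]
      co$drift[["intercept"]] <- ints[["v_intercept"]]
      co$start[["intercept"]] <- ints[["z_intercept"]]
      co$ndt[["intercept"]] <- ints[["ndt"]]
      pars <- tryCatch(
        compute_trial_params(co, drows),
        error = function(e) stop("inadmissible generated parameters for ",
                                 sid, ": ", conditionMessage(e)))
      sim <- simulate_trials(pars$v, pars$a, pars$z, pars$ndt, dt = dt,
                             seed = sample.int(.Machine$integer.max, 1))
      tab$choice <- as.integer(sim$choice == "approach")
      tab$rt <- sim$rt
      trials[[idx]] <- tab
      trial_truth[[idx]] <- data.frame(subject_id = sid, pars)
      subj_truth[[idx]] <- data.frame(subject_id = sid, group = spec$label,
                                      t(ints))
    }
  }
  structure(list(
    trials = do.call(rbind, trials),
    truth = list(subjects = do.call(rbind, subj_truth),
                 trial_params = do.call(rbind, trial_truth),
                 groups = lapply(groups, function(g) g$coefficients),
                 group_labels = vapply(groups, `[[`, "", "label")),
    seed = seed, session = session
  ), class = "aac_dataset")
}

#' @exportS3Method base::print
print.aac_dataset <- function(x, ...) {
  cat("<aac_dataset> ", length(unique(x$trials$subject_id)), " subjects, ",
      nrow(x$trials), " trials, groups: ",
      paste(unique(x$trials$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.trial_cols <- c("subject_id", "group", "session", "run", "trial", "reward",
                 "aversiveness", "pavlovian", "choice", "rt", .rois)

#' Read and write the canonical trial table
#'
#' The canonical CSV has one row per trial with columns `subject_id`,
#' `group`, `session`, `run`, `trial`, `reward`, `aversiveness`,
#' `pavlovian`, `choice` (1 = approach, 0 = avoid), `rt` (s) and the four
#' ROI columns `caudate`, `pacc`, `nacc`, `stn`. `write_trials` also writes
#' a JSON sidecar of true generating parameters when given an `aac_dataset`
#' (requires the jsonlite package).
#'
#' @param x an `aac_dataset` or trial data.frame.
#' @param path CSV file path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(x, path) {
  trials <- if (inherits(x, "aac_dataset")) x$trials else x
  stopifnot(all(.trial_cols %in% names(trials)))
  write.csv(trials[, .trial_cols], path, row.names = FALSE)
  if (inherits(x, "aac_dataset") &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      list(subjects = x$truth$subjects,
           groups = lapply(x$truth$groups, unclass),
           seed = x$seed),
      paste0(side, "_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.trial_cols, names(tab))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
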