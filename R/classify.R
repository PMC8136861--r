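#' Rank-based area under the ROC curve
#'
#' AUC via the Mann-Whitney statistic with average ranks, which equals the
#' probability interpretation exactly: the proportion of (positive,
#' negative) pairs in which the positive scores higher, ties counting half.
#'
#' @param labels binary labels (logical, 0/1, or a 2-level factor whose
#'   *second* level is the positive class).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0, 0, 1, 1), c(.1, .4, .35, .8))
auc_score <- function(labels, scores) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.roi_feature_pattern <- "caudate|pacc|accumbens|nacc|stn"

#' Assemble per-subject feature tables for classification
#'
#' Computational features are per-subject posterior means of the model
#' coefficients from a single-population fit (all coefficients estimated at
#' subject level under one population distribution, so that individual
#' estimates are not shrunk toward diagnosis-specific means). A fit with
#' group-specific structure is rejected to prevent shrinkage leakage.
#' `"computational-only"` drops every ROI-modulation feature;
#' `"behavioral+roi"` instead summarizes the raw trial table (mean RT,
#' approach rate, mean ROI activation).
#'
#' @param fit an `aac_fit` with `grouping = "single-population"`
#'   (computational modes).
#' @param data trial table or `aac_dataset` (for labels, and for the
#'   `"behavioral+roi"` mode).
#' @param mode feature set id.
#' @return data.frame of class `feature_table`: `subject_id`, `label`, and
#'   one column per feature; feature set id kept as attribute
#'   `feature_set`.
#' @export
extract_features <- function(fit = NULL, data,
                             mode = c("computational+neural",
                                      "computational-only",
                                      "behavioral+roi")) {
  mode <- match.arg(mode)
  trials <- if (inherits(data, "aac_dataset")) data$trials else data
  labels <- tapply(as.character(trials$group), trials$subject_id,
                   function(g) g[1])

  if (mode == "behavioral+roi") {
    agg <- function(col) tapply(trials[[col]], trials$subject_id, mean)
    tab <- data.frame(subject_id = names(labels),
                      label = as.character(labels),
                      mean_rt = as.numeric(agg("rt")),
                      approach_rate = as.numeric(agg("choice")),
                      caudate = as.numeric(agg("caudate")),
                      pacc = as.numeric(agg("pacc")),
                      nacc = as.numeric(agg("nacc")),
                      stn = as.numeric(agg("stn")),
                      row.names = NULL)
  } else {
    stopifnot(inherits(fit, "aac_fit"))
    if (fit$spec$grouping != "single-population")
      stop("bias protection: computational features require a ",
           "single-population fit (got '", fit$spec$grouping, "')")
    m <- posterior_draws(fit)
    post <- colMeans(m)
    sids <- fit$prep$subject_ids
    feats <- grep("\\[", names(post), value = TRUE)
    feats <- feats[!grepl("^mu_|^sd_", feats)]
    fnames <- unique(sub("\\[.*$", "", feats))
    if (mode == "computational-only")
      fnames <- fnames[!grepl(.roi_feature_pattern, fnames)]
    tab <- data.frame(subject_id = sids,
                      label = as.character(labels[sids]),
                      row.names = NULL)
    for (fn in fnames)
      tab[[fn]] <- as.numeric(post[paste0(fn, "[", sids, "]")])
  }
  if (anyNA(tab)) stop("missing values in assembled features")
  attr(tab, "feature_set") <- mode
  class(tab) <- c("feature_table", "data.frame")
  tab
}

.feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

.stratified_split <- function(labels, fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  holdout <- unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, max(1, round(fraction * length(idx))))
  }))
  sort(holdout)
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- sample(which(labels == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_ridge <- function(x, y, lambda) {
  # glmnet warns about small per-class counts on CV folds; expected here
  suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE))
}

# scale with training statistics only
.scale_train <- function(x_tr, x_te) {
  ctr <- colMeans(x_tr)
  scl <- apply(x_tr, 2, sd)
  scl[scl < 1e-12] <- 1
  list(tr = scale(x_tr, ctr, scl), te = scale(x_te, ctr, scl),
       center = ctr, scale = scl)
}

#' Train and evaluate the diagnosis classifier
#'
#' L2-regularized logistic regression of clinical status on the feature
#' table. For each of `n_splits` stratified holdout splits, the training
#' portion undergoes `n_repeats` repetitions of stratified `k`-fold
#' cross-validation over a grid of regularization strengths; the
#' best-performing configuration (highest mean CV AUC) is refit on the full
#' training portion and evaluated on the held-out fraction. Feature
#' standardization always uses training-fold statistics only. Reported
#' coefficients are means over splits, ranked by absolute magnitude.
#'
#' @param table a [extract_features()] feature table.
#' @param n_repeats CV repetitions per split (default 100).
#' @param k folds (default 10, capped at the training size).
#' @param holdout_fraction held-out fraction (default 0.3).
#' @param n_splits independent stratified holdout splits (default 10).
#' @param lambda_grid regularization strength grid.
#' @param seed integer seed.
#' @return Object of class `classifier_report`: `holdout_auc` (mean over
#'   splits), `auc_splits`, `holdout_accuracy`, `cv_auc` (per lambda),
#'   `best_lambda`, `coefficients`, `importance` (sorted), and the frozen
#'   `final_model` (coefficients plus scaling) for transfer.
#' @export
train_and_evaluate <- function(table, n_repeats = 100, k = 10,
                               holdout_fraction = 0.3, n_splits = 10,
                               lambda_grid = 10^seq(3, -3, length.out = 13),
                               seed = 1) {
  stopifnot(inherits(table, "data.frame"))
  fc <- .feature_cols(table)
  y_all <- factor(table$label)
  if (nlevels(y_all) != 2) stop("need exactly two classes")
  if (min(table(y_all)) < 2) stop("need >= 2 subjects per class")
  x_all <- as.matrix(table[, fc, drop = FALSE])
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(seed)

  auc_splits <- numeric(n_splits)
  acc_splits <- numeric(n_splits)
  coef_splits <- matrix(NA_real_, n_splits, length(fc) + 1,
                        dimnames = list(NULL, c("Intercept", fc)))
  cv_auc_acc <- matrix(0, n_splits, length(lambda_grid))
  best_lambdas <- numeric(n_splits)

  for (sp in seq_len(n_splits)) {
    hold <- .stratified_split(y_all, holdout_fraction)
    x_tr <- x_all[-hold, , drop = FALSE]
    y_tr <- y_all[-hold]
    kk <- min(k, min(table(y_tr)))
    cv <- matrix(NA_real_, n_repeats, length(lambda_grid))
    for (r in seq_len(n_repeats)) {
      fold <- .stratified_folds(y_tr, kk)
      preds <- matrix(NA_real_, length(y_tr), length(lambda_grid))
      for (f in seq_len(kk)) {
        tr <- fold != f
        if (length(unique(y_tr[tr])) < 2) next
        sc <- .scale_train(x_tr[tr, , drop = FALSE],
                           x_tr[!tr, , drop = FALSE])
        fitg <- .fit_ridge(sc$tr, y_tr[tr], lambda_grid)
        preds[!tr, ] <- predict(fitg, sc$te, type = "response",
                                s = lambda_grid)
      }
      ok <- !is.na(preds[, 1])
      cv[r, ] <- apply(preds[ok, , drop = FALSE], 2, function(p)
        auc_score(y_tr[ok], p))
    }
    mean_cv <- colMeans(cv, na.rm = TRUE)
    cv_auc_acc[sp, ] <- mean_cv
    # ties (e.g. perfectly separable folds) break toward the least-shrunk fit
    best <- min(lambda_grid[mean_cv >= max(mean_cv) - 1e-12])
    best_lambdas[sp] <- best
    sc <- .scale_train(x_tr, x_all[hold, , drop = FALSE])
    fitg <- .fit_ridge(sc$tr, y_tr, lambda_grid)
    p_hold <- as.numeric(predict(fitg, sc$te, type = "response", s = best))
    auc_splits[sp] <- auc_score(y_all[hold], p_hold)
    acc_splits[sp] <- mean((p_hold > 0.5) ==
                             (y_all[hold] == levels(y_all)[2]))
    cf <- as.numeric(coef(fitg, s = best))
    coef_splits[sp, ] <- cf
  }

  # frozen model for transfer: refit on all data at the modal best lambda
  lam <- best_lambdas[which.max(tabulate(match(best_lambdas,
                                               unique(best_lambdas))))]
  ctr <- colMeans(x_all)
  scl <- apply(x_all, 2, sd); scl[scl < 1e-12] <- 1
  x_sc <- scale(x_all, ctr, scl)
  fit_full <- .fit_ridge(x_sc, y_all, lambda_grid)
  cf_full <- as.numeric(coef(fit_full, s = lam))

  mean_coef <- colMeans(coef_splits)
  imp <- mean_coef[-1]
  importance <- data.frame(feature = fc, coefficient = imp,
                           row.names = NULL)
  importance <- importance[order(-abs(importance$coefficient)), ]
  rownames(importance) <- NULL

  structure(list(
    holdout_auc = mean(auc_splits), auc_splits = auc_splits,
    holdout_accuracy = mean(acc_splits),
    cv_auc = setNames(colMeans(cv_auc_acc), signif(lambda_grid, 3)),
    best_lambda = lam, coefficients = mean_coef,
    coef_splits = coef_splits, importance = importance,
    positive_class = levels(y_all)[2], classes = levels(y_all),
    final_model = list(coef = cf_full, features = fc, center = ctr,
                       scale = scl, lambda = lam,
                       positive_class = levels(y_all)[2]),
    feature_set = attr(table, "feature_set")
  ), class = "classifier_report")
}

#' @exportS3Method base::print
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> [%s] held-out AUC = %.3f (%d splits)\n",
              x$feature_set %||% "features", x$holdout_auc,
              length(x$auc_splits)))
  cat("  top features:",
      paste(head(x$importance$feature, 4), collapse = ", "), "\n")
  invisible(x)
}

.predict_frozen <- function(model, table) {
  miss <- setdiff(model$features, .feature_cols(table))
  extra <- setdiff(.feature_cols(table), model$features)
  if (length(miss) || length(extra))
    stop("feature mismatch: missing [", paste(miss, collapse = ", "),
         "], extra [", paste(extra, collapse = ", "), "]")
  x <- as.matrix(table[, model$features, drop = FALSE])
  x <- scale(x, model$center, model$scale)
  eta <- model$coef[1] + as.numeric(x %*% model$coef[-1])
  1 / (1 + exp(-eta))
}

#' Apply a frozen classifier to follow-up data
#'
#' Scores a follow-up feature table with the trained (frozen) classifier.
#' Optionally relabels remitters (follow-up depression score at or below
#' `remitter_threshold`) as healthy before scoring.
#'
#' @param report a [train_and_evaluate()] report.
#' @param followup_table feature table with the same feature set.
#' @param relabel_remitters relabel remitters as the healthy class.
#' @param depression_scores named numeric vector (by `subject_id`) of
#'   follow-up depression ratings; required if `relabel_remitters`.
#' @param remitter_threshold score at or below which a subject counts as
#'   remitted (default 7).
#' @param healthy_class label to assign to remitters (default `"HC"`).
#' @return List with `accuracy`, `auc`, `predictions`, `labels`.
#' @export
transfer_evaluate <- function(report, followup_table,
                              relabel_remitters = FALSE,
                              depression_scores = NULL,
                              remitter_threshold = 7,
                              healthy_class = "HC") {
  stopifnot(inherits(report, "classifier_report"))
  labels <- as.character(followup_table$label)
  if (relabel_remitters) {
    if (is.null(depression_scores))
      stop("relabel_remitters requires depression_scores")
    sc <- depression_scores[followup_table$subject_id]
    labels[!is.na(sc) & sc <= remitter_threshold] <- healthy_class
  }
  p <- .predict_frozen(report$final_model, followup_table)
  pos <- report$final_model$positive_class
  y <- labels == pos
  list(accuracy = mean((p > 0.5) == y),
       auc = auc_score(y, p),
       predictions = setNames(p, followup_table$subject_id),
       labels = setNames(labels, followup_table$subject_id))
}

#' Leave-one-subject-out transfer accuracy
#'
#' For each follow-up subject, retrains the classifier on the baseline table
#' excluding that subject and predicts the held-out subject's follow-up row;
#' reports aggregate accuracy. Regularization is selected by stratified CV
#' within each training set.
#'
#' @param baseline_table,followup_table feature tables sharing feature
#'   columns; subjects matched by `subject_id`.
#' @param k inner CV folds (default 5).
#' @param lambda_grid regularization grid.
#' @param seed integer seed.
#' @return List with `accuracy`, per-subject `predictions` and `correct`.
#' @export
leave_one_subject_out <- function(baseline_table, followup_table, k = 5,
                                  lambda_grid = 10^seq(3, -3,
                                                       length.out = 13),
                                  seed = 1) {
  fc <- .feature_cols(baseline_table)
  if (!setequal(fc, .feature_cols(followup_table)))
    stop("feature mismatch between baseline and follow-up tables")
  if (!all(followup_table$subject_id %in% baseline_table$subject_id))
    stop("follow-up subjects missing from baseline table: ",
         paste(setdiff(followup_table$subject_id,
                       baseline_table$subject_id), collapse = ", "))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(seed)
  y_all <- factor(baseline_table$label)
  pos <- levels(y_all)[2]
  preds <- numeric(nrow(followup_table))
  correct <- logical(nrow(followup_table))
  for (i in seq_len(nrow(followup_table))) {
    sid <- followup_table$subject_id[i]
    keep <- baseline_table$subject_id != sid
    x_tr <- as.matrix(baseline_table[keep, fc, drop = FALSE])
    y_tr <- y_all[keep]
    kk <- min(k, min(table(y_tr)))
    fold <- .stratified_folds(y_tr, kk)
    cvp <- matrix(NA_real_, length(y_tr), length(lambda_grid))
    for (f in seq_len(kk)) {
      tr <- fold != f
      if (length(unique(y_tr[tr])) < 2) next
      sc <- .scale_train(x_tr[tr, , drop = FALSE],
                         x_tr[!tr, , drop = FALSE])
      fitg <- .fit_ridge(sc$tr, y_tr[tr], lambda_grid)
      cvp[!tr, ] <- predict(fitg, sc$te, type = "response", s = lambda_grid)
    }
    ok <- !is.na(cvp[, 1])
    cv_auc <- apply(cvp[ok, , drop = FALSE], 2,
                    function(p) auc_score(y_tr[ok], p))
    best <- min(lambda_grid[cv_auc >= max(cv_auc) - 1e-12])
    sc <- .scale_train(x_tr, as.matrix(followup_table[i, fc,
                                                      drop = FALSE]))
    fitg <- .fit_ridge(sc$tr, y_tr, lambda_grid)
    p <- as.numeric(predict(fitg, sc$te, type = "response", s = best))
    preds[i] <- p
    correct[i] <- (p > 0.5) == (followup_table$label[i] == pos)
  }
  list(accuracy = mean(correct),
       predictions = setNames(preds, followup_table$subject_id),
       correct = setNames(correct, followup_table$subject_id))
}
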