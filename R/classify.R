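# Lasso survival classifier: preprocessing, L1-penalized logistic
# regression with repeated stratified 5-fold cross-validation, feature
# inclusion stability, and the ROC of the best model.

#' Lasso pipeline configuration
#'
#' @param n_repeats repetitions of k-fold cross-validation (default 250).
#' @param k_folds folds per repetition (default 5; stratified by
#'   outcome).
#' @param nlambda length of the geometric shrinkage path fitted by
#'   glmnet.
#' @param variance_filter drop features whose 0-1-rescaled variance is
#'   below this (default 0.025, i.e. 2.5\%).
#' @param missing_filter drop features with a larger missing fraction
#'   (default 0.25).
#' @param imputation `"group_mean"` (outcome-class mean; note this leaks
#'   the label into the imputed value and is provided for fidelity to the
#'   original workflow) or `"overall_mean"`.
#' @param seed root seed for fold assignment.
#' @return list of class `lasso_config`.
#' @export
lasso_config <- function(n_repeats = 250L, k_folds = 5L, nlambda = 60L,
                         variance_filter = 0.025, missing_filter = 0.25,
                         imputation = c("group_mean", "overall_mean"),
                         seed = 1L) {
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  structure(list(n_repeats = as.integer(n_repeats),
                 k_folds = as.integer(k_folds),
                 nlambda = as.integer(nlambda),
                 variance_filter = variance_filter,
                 missing_filter = missing_filter,
                 imputation = match.arg(imputation),
                 seed = as.integer(seed)),
            class = "lasso_config")
}

.minmax_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Preprocess a feature table for classification
#'
#' In order: (1) drop features whose variance on the 0-1 rescaled column
#' falls below `variance_filter` (the rescaling makes the threshold
#' unit-free); (2) drop features with more than `missing_filter` missing
#' values; (3) impute remaining missing values with the outcome-group
#' mean (falling back to the overall mean for a group with no scored
#' value, with a warning); (4) min-max scale every column to \[0, 1\].
#' Rows (embryos) are never dropped.
#'
#' @param feature_table data.frame from [feature_table()] with an
#'   `outcome` column in `{alive, dead}`.
#' @param config a [lasso_config()].
#' @return list of class `lasso_data`: `x` (numeric matrix), `y` (0/1,
#'   1 = dead), `embryo_id`, and `report` (dropped/imputed counts).
#' @export
preprocess_features <- function(feature_table, config = lasso_config()) {
  stopifnot(all(feature_table$outcome %in% c("alive", "dead")))
  y <- as.integer(feature_table$outcome == "dead")
  if (length(unique(y)) < 2L)
    stop("binary outcome required: both classes must be present",
         call. = FALSE)
  X <- .feature_matrix(feature_table)

  scaled_var <- apply(X, 2, function(col) {
    if (sum(is.finite(col)) < 2L) return(0)
    stats::var(.minmax_scale(col)[is.finite(col)])
  })
  low_var <- scaled_var < config$variance_filter
  X <- X[, !low_var, drop = FALSE]

  miss_frac <- colMeans(is.na(X))
  too_missing <- miss_frac > config$missing_filter
  X <- X[, !too_missing, drop = FALSE]

  n_imputed <- 0L
  for (j in seq_len(ncol(X))) {
    na_idx <- which(is.na(X[, j]))
    if (!length(na_idx)) next
    n_imputed <- n_imputed + length(na_idx)
    if (config$imputation == "group_mean") {
      for (cls in unique(y[na_idx])) {
        fill <- mean(X[y == cls, j], na.rm = TRUE)
        if (!is.finite(fill)) {
          warning("feature '", colnames(X)[j], "': no scored value in a ",
                  "group; falling back to the overall mean")
          fill <- mean(X[, j], na.rm = TRUE)
        }
        X[na_idx[y[na_idx] == cls], j] <- fill
      }
    } else {
      X[na_idx, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  X <- apply(X, 2, .minmax_scale)

  structure(list(x = X, y = y, embryo_id = feature_table$embryo_id,
                 report = list(n_features_in = length(scaled_var),
                               n_low_variance = sum(low_var),
                               n_too_missing = sum(too_missing),
                               n_imputed = n_imputed,
                               n_features_out = ncol(X))),
            class = "lasso_data")
}

# stratified fold assignment: classes distributed evenly over folds
.stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  foldid
}

#' Repeated cross-validated Lasso classification
#'
#' Per repetition: a stratified random k-fold split; along a shared
#' geometric lambda path, L1-penalized logistic regression is fitted on
#' the training folds and evaluated by held-out mean squared error
#' between the predicted probability and the 0/1 outcome; the lambda
#' minimizing the CV MSE is chosen, the selected features are read from
#' a refit on the full data at that lambda, and the CV accuracy is the
#' fraction of held-out embryos classified correctly at threshold 0.5.
#' The best model is the repetition with the globally minimal CV error.
#'
#' @param data a `lasso_data` from [preprocess_features()].
#' @param config a [lasso_config()].
#' @return list of class `lasso_result`: `repetitions` (per-repetition
#'   lambda, CV MSE, CV accuracy, model size), `inclusion` (per-feature
#'   inclusion frequency), `accuracy_mean`, `accuracy_sd`,
#'   `model_sizes`, and `best` (coefficients, ROC, operating points).
#' @export
lasso_cv <- function(data, config = lasso_config()) {
  x <- data$x; y <- data$y
  if (min(table(y)) < config$k_folds)
    stop("need at least k_folds embryos per class", call. = FALSE)
  path_fit <- glmnet::glmnet(x, y, family = "binomial",
                             standardize = FALSE,
                             nlambda = config$nlambda)
  lambda_path <- path_fit$lambda

  reps <- vector("list", config$n_repeats)
  sel_sets <- vector("list", config$n_repeats)
  best_fits <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    foldid <- with_seed(derive_seed(config$seed, "cv-folds", r),
                        .stratified_folds(y, config$k_folds))
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(x, y, family = "binomial", type.measure = "mse",
                        foldid = foldid, lambda = lambda_path,
                        standardize = FALSE, keep = TRUE))
    i_min <- which.min(cvfit$cvm)
    lam <- cvfit$lambda[i_min]
    preval <- stats::plogis(cvfit$fit.preval[, i_min])
    acc <- mean((preval > 0.5) == (y == 1))
    cf <- as.matrix(stats::coef(cvfit$glmnet.fit, s = lam))
    nz <- rownames(cf)[-1][cf[-1, 1] != 0]
    reps[[r]] <- data.frame(rep = r, lambda = lam,
                            cv_mse = cvfit$cvm[i_min], cv_accuracy = acc,
                            model_size = length(nz))
    sel_sets[[r]] <- nz
    best_fits[[r]] <- list(coef = cf, lambda = lam)
  }
  repetitions <- do.call(rbind, reps)
  inclusion <- table(factor(unlist(sel_sets), levels = colnames(x)))
  inclusion <- as.numeric(inclusion) / config$n_repeats
  names(inclusion) <- colnames(x)

  i_best <- which.min(repetitions$cv_mse)
  best_cf <- best_fits[[i_best]]$coef
  scores <- stats::plogis(cbind(1, x) %*% best_cf)[, 1]
  roc <- roc_points(scores, y)

  structure(list(
    repetitions = repetitions, inclusion = inclusion,
    accuracy_mean = mean(repetitions$cv_accuracy),
    accuracy_sd = stats::sd(repetitions$cv_accuracy),
    model_sizes = table(repetitions$model_size),
    lambda_path = lambda_path,
    best = list(rep = i_best, lambda = best_fits[[i_best]]$lambda,
                cv_mse = repetitions$cv_mse[i_best],
                coefficients = best_cf[best_cf[, 1] != 0, 1],
                scores = scores, roc = roc$curve,
                auc = roc$auc, youden = roc$youden,
                at_0.5 = roc$at_threshold)),
    class = "lasso_result")
}

#' ROC curve by threshold enumeration
#'
#' Sensitivity / specificity over the sorted unique predicted
#' probabilities, the operating point maximizing Youden's J, and the
#' point at threshold 0.5.
#'
#' @param scores predicted probabilities of the positive class.
#' @param y 0/1 outcomes (1 = positive).
#' @return list: `curve` (data.frame `threshold`, `sensitivity`,
#'   `specificity`), `auc` (trapezoidal), `youden`, `at_threshold`.
#' @export
roc_points <- function(scores, y) {
  if (length(unique(y)) < 2L)
    stop("ROC undefined: single-class input", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- which.max(sens + spec - 1)
  at05 <- c(sensitivity = mean(scores[y == 1] > 0.5),
            specificity = mean(scores[y == 0] <= 0.5))
  list(curve = curve, auc = auc,
       youden = curve[j, ], at_threshold = at05)
}

#' Per-stage classification report
#'
#' Runs preprocessing and repeated-CV Lasso on the feature tables of
#' several developmental stages, restricted to the embryos scored at all
#' stages, and collects accuracy distributions, model-size histograms
#' and inclusion frequencies per stage.
#'
#' @param stage_tables named list of feature tables (names = stages).
#' @param config a [lasso_config()].
#' @return named list of `lasso_result` with attribute `embryos` (ids
#'   used).
#' @export
stage_report <- function(stage_tables, config = lasso_config()) {
  ids <- Reduce(intersect, lapply(stage_tables, function(t) t$embryo_id))
  if (!length(ids)) stop("no embryos shared across stages", call. = FALSE)
  dropped <- unique(unlist(lapply(stage_tables, function(t)
    setdiff(t$embryo_id, ids))))
  if (length(dropped))
    message("restricting to ", length(ids),
            " embryos scored at all stages (dropped: ",
            paste(dropped, collapse = ", "), ")")
  out <- lapply(stage_tables, function(tab) {
    tab <- tab[match(ids, tab$embryo_id), , drop = FALSE]
    lasso_cv(preprocess_features(tab, config), config)
  })
  attr(out, "embryos") <- ids
  out
}
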