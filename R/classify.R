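#' Stratified train/test split
#'
#' Splits a measurement table at the bone level with a test set of exactly
#' `test_size` bones, allocated across the joint strata of the requested
#' factors proportionally (largest-remainder rounding, so each stratum's test
#' share is within one bone of proportionality). Per-side models stratify by
#' sex and age group; combined-side models additionally by side. Bones, not
#' individuals, are the sampling unit, so the two bones of one individual can
#' straddle the boundary of a combined-side split.
#'
#' @param table measurement table.
#' @param test_size number of bones in the test set.
#' @param stratify_by character vector of stratification factors from
#'   `c("sex", "age_group", "side")`.
#' @param age_cutoff age-group cut-off for the `age_group` factor.
#' @param seed integer seed for the within-stratum sampling.
#' @return List with elements `train` and `test` (disjoint data.frames
#'   covering `table`).
#' @export
stratified_split <- function(table, test_size,
                             stratify_by = c("sex", "age_group"),
                             age_cutoff = 45, seed = 1L) {
  if (test_size >= nrow(table))
    stop("test_size must be smaller than the table")
  bad <- setdiff(stratify_by, c("sex", "age_group", "side"))
  if (length(bad))
    stop("unknown stratification factor(s): ", paste(bad, collapse = ", "))
  fac <- lapply(stratify_by, function(f) {
    if (f == "age_group") ifelse(table$age <= age_cutoff, "young", "old")
    else table[[f]]
  })
  strata <- do.call(paste, c(fac, sep = "/"))
  counts <- table(strata)
  quota_raw <- as.numeric(counts) / nrow(table) * test_size
  quota <- floor(quota_raw)
  rem <- test_size - sum(quota)
  if (rem > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  names(quota) <- names(counts)
  short <- quota > as.numeric(counts)
  if (any(short))
    stop("stratum smaller than its test quota: ",
         paste(names(quota)[short], collapse = ", "))
  set.seed(seed)
  test_idx <- integer(0)
  for (s in names(quota)) {
    idx <- which(strata == s)
    test_idx <- c(test_idx, sample(idx, quota[[s]]))
  }
  test_idx <- sort(test_idx)
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

# y: factor with levels c("F","M"); decision values are oriented so that
# positive predicts "M"
fit_linear_classifier <- function(Xs, y, algorithm, C) {
  n <- nrow(Xs)
  if (algorithm %in% c("lr_l1", "lr_l2")) {
    lam <- 1 / (n * C)
    lam_path <- lam * c(100, 10, 1)   # short decreasing path for a stable fit
    fit <- glmnet::glmnet(Xs, y, family = "binomial",
                          alpha = if (algorithm == "lr_l1") 1 else 0,
                          lambda = lam_path, standardize = FALSE)
    list(coef = as.numeric(fit$beta[, 3L]), intercept = as.numeric(fit$a0[3L]))
  } else {
    fit <- e1071::svm(Xs, y, kernel = "linear", cost = C, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    # libsvm orients decision values toward its internal first label; flip
    # if needed so positive always means "M"
    dv <- drop(Xs %*% w) + b
    agree <- mean((dv > 0) == (stats::predict(fit, Xs) == "M"))
    if (agree < 0.5) {
      w <- -w; b <- -b
    }
    list(coef = w, intercept = b)
  }
}

decision_values <- function(cls, Xs) {
  drop(Xs %*% cls$coef) + cls$intercept
}

# repeated stratified k-fold CV accuracy for every C candidate.
# For glmnet the whole C path is fitted per fold in one call.
cv_accuracy <- function(X, y, algorithm, C_grid, repeats, folds, seed) {
  set.seed(seed)
  n <- length(y)
  acc <- matrix(NA_real_, nrow = repeats * folds, ncol = length(C_grid))
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- fold_id != f
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], scaler)
      Xte <- apply_scaler(X[!tr, , drop = FALSE], scaler)
      yte <- y[!tr]
      if (algorithm %in% c("lr_l1", "lr_l2")) {
        lam <- 1 / (sum(tr) * C_grid)           # decreasing in C
        ord <- order(lam, decreasing = TRUE)
        fit <- glmnet::glmnet(Xtr, y[tr], family = "binomial",
                              alpha = if (algorithm == "lr_l1") 1 else 0,
                              lambda = lam[ord], standardize = FALSE)
        pred <- stats::predict(fit, Xte, s = lam[ord], type = "class")
        acc[row, ord] <- colMeans(pred == as.character(yte))
      } else {
        for (j in seq_along(C_grid)) {
          cls <- fit_linear_classifier(Xtr, y[tr], algorithm, C_grid[j])
          pred <- ifelse(decision_values(cls, Xte) > 0, "M", "F")
          acc[row, j] <- mean(pred == as.character(yte))
        }
      }
    }
  }
  acc
}

#' Tune and fit a sex-estimation model
#'
#' The full training protocol: per-feature standardization fitted on training
#' data only (and refitted inside every cross-validation fold), a log-uniform
#' random search of `n_candidates` values of the inverse-regularization /
#' margin-tradeoff hyperparameter C over `c_range`, scored by mean accuracy
#' under `repeats` x `folds`-fold stratified cross-validation, then a final
#' refit on the whole training set at the best C (smallest C on ties). The
#' reported training accuracy is the CV mean at the chosen C with a normal
#' 95% confidence interval over the fold scores.
#'
#' @param train training measurement table with a `sex` column ("M"/"F").
#' @param algorithm `"lr_l1"`, `"lr_l2"` (logistic regression with L1/L2
#'   penalty), or `"svm_linear"` (linear support vector machine).
#' @param features measurement columns to use (default: all, typically after
#'   [sex_significant_features()] screening).
#' @param seed integer seed (drives the C search and the CV folds).
#' @param n_candidates number of C values searched.
#' @param c_range search range for C (log-uniform), default `c(1e-3, 1e2)`.
#' @param repeats,folds cross-validation scheme (default 10 x 5).
#' @return A `sex_model` object: scaler, coefficients, selected C, CV record,
#'   and training metrics (percent).
#' @export
tune_and_fit <- function(train, algorithm = c("lr_l1", "lr_l2", "svm_linear"),
                         features = NULL, seed = 1L, n_candidates = 50L,
                         c_range = c(1e-3, 1e2), repeats = 10L, folds = 5L) {
  algorithm <- match.arg(algorithm)
  if (is.null(features)) features <- measurement_columns(train)
  if (!length(features)) stop("no features to train on")
  y <- factor(train$sex, levels = c("F", "M"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both sexes")
  X <- as.matrix(train[, features, drop = FALSE])
  set.seed(seed)
  C_grid <- sort(exp(stats::runif(n_candidates, log(c_range[1L]),
                                  log(c_range[2L]))))
  acc <- cv_accuracy(X, y, algorithm, C_grid, repeats, folds,
                     seed = seed + 1L)
  mean_acc <- colMeans(acc)
  best <- which(mean_acc == max(mean_acc))[1L]   # smallest C on ties
  C <- C_grid[best]
  scaler <- fit_scaler(X)
  cls <- fit_linear_classifier(apply_scaler(X, scaler), y, algorithm, C)
  # Platt-style probability mapping fitted on training decision values
  dv <- decision_values(cls, apply_scaler(X, scaler))
  platt <- fit_platt(dv, y)
  fold_scores <- acc[, best]
  se <- stats::sd(fold_scores) / sqrt(length(fold_scores))
  model <- list(
    algorithm = algorithm, C = C, c_range = c_range,
    features = features, scaler = scaler,
    coef = stats::setNames(cls$coef, features), intercept = cls$intercept,
    platt = platt, classes = c("F", "M"),
    cv = list(C_grid = C_grid, mean_accuracy = mean_acc,
              repeats = repeats, folds = folds),
    train_accuracy_pct = 100 * mean(fold_scores),
    train_accuracy_ci_pct = 100 * (mean(fold_scores) + c(-1, 1) * 1.96 * se),
    n_train = nrow(train)
  )
  class(model) <- "sex_model"
  model
}

# logistic sigmoid on the decision value; for logistic regression the
# decision value is already a log-odds so the mapping is fitted but
# near-identity
fit_platt <- function(dv, y) {
  df <- data.frame(dv = dv, y = y)
  fit <- suppressWarnings(
    stats::glm(y ~ dv, data = df, family = stats::binomial()))
  c(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]))
}

#' @export
print.sex_model <- function(x, ...) {
  cat(sprintf(
    "<sex_model> %s, C = %.4g, %d feature(s); CV training accuracy %.1f%% [%.1f, %.1f]\n",
    x$algorithm, x$C, length(x$features), x$train_accuracy_pct,
    x$train_accuracy_ci_pct[1L], x$train_accuracy_ci_pct[2L]))
  invisible(x)
}

check_features <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    stop("table is missing model feature(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Predict sex labels
#' @param object a `sex_model`.
#' @param newdata measurement table containing the model's features.
#' @param ... unused.
#' @return Factor of predicted sexes with levels `c("F", "M")`.
#' @export
predict.sex_model <- function(object, newdata, ...) {
  check_features(object, newdata)
  Xs <- apply_scaler(as.matrix(newdata[, object$features, drop = FALSE]),
                     object$scaler)
  factor(ifelse(decision_values(object, Xs) > 0, "M", "F"),
         levels = c("F", "M"))
}

#' Predict per-class sex probabilities
#'
#' For logistic regression the probability is the logistic transform of the
#' linear predictor; for the linear SVM the decision value is mapped through
#' the sigmoid calibrated on the training data. Rows sum to 1.
#'
#' @param model a `sex_model`.
#' @param newdata measurement table containing the model's features.
#' @return Numeric matrix with columns `F` and `M`.
#' @export
predict_proba <- function(model, newdata) {
  check_features(model, newdata)
  Xs <- apply_scaler(as.matrix(newdata[, model$features, drop = FALSE]),
                     model$scaler)
  dv <- decision_values(model, Xs)
  p_m <- if (model$algorithm == "svm_linear") {
    stats::plogis(model$platt[["a"]] * dv + model$platt[["b"]])
  } else {
    stats::plogis(dv)
  }
  cbind(F = 1 - p_m, M = p_m)
}

#' Evaluate a sex model on a test table
#'
#' @param model a `sex_model`.
#' @param test measurement table with true `sex` labels.
#' @return List with `accuracy_pct`, per-class `precision_pct`, `recall_pct`,
#'   `f1_pct` (named vectors over `F` and `M`), and the 2 x 2 `confusion`
#'   matrix (rows = truth, columns = prediction).
#' @export
evaluate_model <- function(model, test) {
  truth <- factor(test$sex, levels = c("F", "M"))
  pred <- predict(model, test)
  confusion <- table(truth = truth, prediction = pred)
  acc <- 100 * mean(pred == truth)
  prec <- rec <- f1 <- stats::setNames(numeric(2L), c("F", "M"))
  for (cl in c("F", "M")) {
    tp <- confusion[cl, cl]
    prec[cl] <- 100 * safe_div(tp, sum(confusion[, cl]))
    rec[cl] <- 100 * safe_div(tp, sum(confusion[cl, ]))
    f1[cl] <- safe_div(2 * prec[cl] * rec[cl], prec[cl] + rec[cl])
  }
  list(accuracy_pct = acc, precision_pct = prec, recall_pct = rec,
       f1_pct = f1, confusion = confusion, n_test = nrow(test))
}

safe_div <- function(a, b) if (b == 0) 0 else a / b

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Within each of `folds` stratified CV folds, features are eliminated one at
#' a time by lowest importance from a 100-tree random forest fitted on the
#' fold's training portion, recording held-out accuracy at every feature
#' count. The count maximizing mean CV accuracy (smallest on ties) is then
#' reproduced by a final elimination pass on the full table, whose surviving
#' features are returned.
#'
#' @param train training measurement table with a `sex` column.
#' @param features candidate measurement columns (default all).
#' @param seed integer seed (forest and fold seeds derive from it).
#' @param folds number of CV folds (default 5).
#' @param num_trees forest size (default 100).
#' @return Character vector of selected feature names, with attribute
#'   `"cv_accuracy"` (mean CV accuracy per feature count, descending counts).
#' @export
rfecv_select <- function(train, features = NULL, seed = 1L, folds = 5L,
                         num_trees = 100L) {
  if (is.null(features)) features <- measurement_columns(train)
  if (length(features) < 2L) return(features)
  y <- factor(train$sex, levels = c("F", "M"))
  X <- as.data.frame(train[, features, drop = FALSE])
  names(X) <- make.names(names(X))          # ranger needs syntactic names
  key <- stats::setNames(features, names(X))
  set.seed(seed)
  fold_id <- integer(nrow(X))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  p <- length(features)
  acc <- matrix(NA_real_, nrow = folds, ncol = p)  # col j: j features kept
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    keep <- names(X)
    repeat {
      k <- length(keep)
      rf <- ranger::ranger(
        x = X[tr, keep, drop = FALSE], y = y[tr],
        num.trees = num_trees, importance = "impurity",
        seed = seed + 1000L * f + k)
      pred <- stats::predict(rf, X[!tr, keep, drop = FALSE])$predictions
      acc[f, k] <- mean(pred == y[!tr])
      if (k == 1L) break
      keep <- keep[-which.min(rf$variable.importance)]
    }
  }
  mean_acc <- colMeans(acc)
  best_k <- which(mean_acc == max(mean_acc))[1L]   # smallest count on ties
  # final elimination pass on the full table down to best_k features
  keep <- names(X)
  while (length(keep) > best_k) {
    rf <- ranger::ranger(x = X[, keep, drop = FALSE], y = y,
                         num.trees = num_trees, importance = "impurity",
                         seed = seed + length(keep))
    keep <- keep[-which.min(rf$variable.importance)]
  }
  out <- unname(key[keep])
  out <- features[features %in% out]               # original order
  attr(out, "cv_accuracy") <- mean_acc
  out
}

#' Persist and reload fitted sex models
#'
#' `save_model()` writes the model as an RDS artifact plus a JSON sidecar
#' (`<path>.json`) holding the feature names, hyperparameter, and training
#' metrics for language-neutral inspection. `load_model()` restores the model;
#' a save/load round trip reproduces predictions exactly.
#'
#' @param model a `sex_model`.
#' @param path artifact path (e.g. `model.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `sex_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sex_model"))
  saveRDS(model, path)
  sidecar <- list(
    algorithm = model$algorithm, C = model$C, features = model$features,
    n_train = model$n_train,
    train_accuracy_pct = model$train_accuracy_pct,
    train_accuracy_ci_pct = model$train_accuracy_ci_pct)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sex_model"))
    stop("file does not contain a sex_model artifact")
  model
}
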