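#' Bayesian ridge regression via evidence maximization
#'
#' Linear regression with an L2 (Gaussian) prior on the weights whose
#' precision, together with the noise precision, is estimated from the data by
#' maximizing the marginal likelihood (empirical Bayes). This is the
#' data-driven-shrinkage base learner used by the iterative landmark imputer.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y numeric response vector.
#' @param max_iter maximum evidence-update iterations.
#' @param tol convergence tolerance on the weight precision updates.
#' @return List with `coef` (length p), `intercept`, `alpha` (noise
#'   precision), `lambda` (weight precision), and `predict(newX)` closure.
#' @export
bayesian_ridge <- function(X, y, max_iter = 300L, tol = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  sv <- svd(Xc, nu = 0L)
  eig <- sv$d^2                       # eigenvalues of Xc'Xc
  Vty <- crossprod(Xc, yc)            # p vector
  UtY <- drop(t(sv$v) %*% Vty)        # coordinates in right-singular basis
  alpha <- 1 / max(stats::var(yc), .Machine$double.eps)  # noise precision
  lambda <- 1                                            # weight precision
  # weak Gamma hyperpriors keep the updates finite when n <= p drives the
  # residual to zero
  eps <- 1e-6
  for (it in seq_len(max_iter)) {
    # posterior mean in the singular basis
    denom <- lambda + alpha * eig
    w_svd <- alpha * UtY / denom
    gamma <- sum(alpha * eig / denom)          # effective dof
    w_norm2 <- sum(w_svd^2)
    resid2 <- sum((yc - Xc %*% (sv$v %*% w_svd))^2)
    lambda_new <- (gamma + 2 * eps) / (w_norm2 + 2 * eps)
    alpha_new <- (max(n - gamma, 0) + 2 * eps) / (resid2 + 2 * eps)
    if (abs(lambda_new - lambda) < tol * lambda &&
        abs(alpha_new - alpha) < tol * alpha) {
      lambda <- lambda_new; alpha <- alpha_new
      break
    }
    lambda <- lambda_new; alpha <- alpha_new
  }
  denom <- lambda + alpha * eig
  w <- drop(sv$v %*% (alpha * UtY / denom))
  intercept <- ym - sum(xm * w)
  list(
    coef = w, intercept = intercept, alpha = alpha, lambda = lambda,
    predict = function(newX) drop(as.matrix(newX) %*% w) + intercept
  )
}

#' Impute missing landmarks by iterative conditional regression
#'
#' Fills in missing landmark coordinates per side by cycling over incomplete
#' coordinate columns: each missing scalar coordinate is regressed (Bayesian
#' ridge) on all other 101 coordinates of the same bone, using bones where the
#' coordinate is observed as training rows, and the predictions replace the
#' current fill. Columns are initialized at their observed mean and visited in
#' descending missing count; the cycle repeats until the largest relative
#' change of any imputed value drops below `tolerance` or `max_iterations` is
#' reached. Observed coordinates are never modified.
#'
#' @param cohort a `landmark_cohort`; each record may miss at most 3 landmarks.
#' @param max_iterations maximum sweeps over the incomplete columns.
#' @param tolerance relative-change stopping threshold.
#' @param allow_excess_missing if `TRUE`, records missing more than 3
#'   landmarks are imputed anyway instead of raising an error.
#' @return A list with `cohort` (completed) and `diagnostics` (per-side
#'   iterations used, convergence flag, number of imputed cells, and a warning
#'   flag when complete training rows are scarce).
#' @export
impute_cohort <- function(cohort, max_iterations = 10L, tolerance = 1e-3,
                          allow_excess_missing = FALSE) {
  n_miss <- vapply(missing_landmarks(cohort), length, integer(1))
  if (any(n_miss > 3L) && !allow_excess_missing)
    stop(sprintf(
      "%d record(s) have more than 3 missing landmarks; outside the supported imputation regime",
      sum(n_miss > 3L)))
  if (all(n_miss == 0L)) {
    return(list(cohort = cohort,
                diagnostics = data.frame(side = character(), iterations = integer(),
                                         converged = logical(), n_imputed = integer(),
                                         few_complete_rows = logical())))
  }
  flat <- flatten_coords(cohort)
  diags <- list()
  for (sd_ in unique(cohort$meta$side)) {
    rows <- which(cohort$meta$side == sd_)
    sub <- flat[rows, , drop = FALSE]
    res <- impute_matrix(sub, max_iterations, tolerance)
    flat[rows, ] <- res$mat
    diags[[sd_]] <- data.frame(side = sd_, iterations = res$iterations,
                               converged = res$converged,
                               n_imputed = res$n_imputed,
                               few_complete_rows = res$few_complete_rows)
  }
  out <- cohort
  out$coords <- unflatten_coords(flat)
  list(cohort = out, diagnostics = do.call(rbind, c(diags, list(make.row.names = FALSE))))
}

impute_matrix <- function(mat, max_iterations, tolerance) {
  miss <- is.na(mat)
  n_imputed <- sum(miss)
  if (n_imputed == 0L)
    return(list(mat = mat, iterations = 0L, converged = TRUE,
                n_imputed = 0L, few_complete_rows = FALSE))
  col_miss <- colSums(miss)
  if (any(col_miss == nrow(mat)))
    stop("impute_cohort: column(s) with no observed values: ",
         paste(colnames(mat)[col_miss == nrow(mat)], collapse = ", "))
  few <- sum(rowSums(miss) == 0L) < ncol(mat)
  if (few)
    warning("fewer complete bones than coordinate columns; imputation may be unstable")
  # initial fill: column means of observed values
  fill <- matrix(rep(colMeans(mat, na.rm = TRUE), each = nrow(mat)),
                 nrow = nrow(mat))
  mat[miss] <- fill[miss]
  visit <- order(col_miss, decreasing = TRUE)
  visit <- visit[col_miss[visit] > 0L]
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    max_rel <- 0
    for (j in visit) {
      obs <- !miss[, j]
      fit <- bayesian_ridge(mat[obs, -j, drop = FALSE], mat[obs, j])
      pred <- fit$predict(mat[!obs, -j, drop = FALSE])
      # guard against degenerate fits on very small training sets
      pred[!is.finite(pred)] <- mean(mat[obs, j])
      old <- mat[!obs, j]
      mat[!obs, j] <- pred
      scale <- max(abs(old), stats::sd(mat[obs, j]), 1)
      max_rel <- max(max_rel, max(abs(pred - old)) / scale)
    }
    if (max_rel < tolerance) {
      converged <- TRUE
      break
    }
  }
  list(mat = mat, iterations = iterations, converged = converged,
       n_imputed = n_imputed, few_complete_rows = few)
}
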