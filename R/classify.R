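# Diagnostic classifiers over selected pathway (or metabolite) features
# and the evaluation metric suite.

# Internal: ridge-penalized logistic regression by IRLS.  Features are
# standardized internally; the intercept is not penalized.  The penalty
# keeps coefficients finite on separable data.
ridge_logistic <- function(X, y01, lambda = 1e-4, max_iter = 100L,
                           tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  Z <- cbind(1, Xs)
  pen <- diag(c(0, rep(lambda, p)), nrow = p + 1L)
  beta <- rep(0, p + 1L)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Z %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zresp <- eta + (y01 - mu) / w
    A <- crossprod(Z, Z * w) + 2 * pen
    b <- crossprod(Z, w * zresp)
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta <- as.numeric(beta)
  coef_std <- beta[-1]
  coef_orig <- coef_std / scl
  list(intercept = beta[1] - sum(coef_std * ctr / scl),
       coefficients = setNames(coef_orig, colnames(X)),
       center = ctr, scale = scl, lambda = lambda)
}

#' Train a diagnostic classifier on selected features
#'
#' Logistic regression (the headline model) is fitted by ridge-penalized
#' maximum likelihood so that separable data still yields finite
#' coefficients; SVM (radial kernel, probability model) and random
#' forest are available for model comparison.  All fits are
#' deterministic given `seed`.
#'
#' An empty feature set yields an intercept-only logistic model (a
#' constant, no-skill predictor): the pipeline's declaration that no
#' stable signal was found.
#'
#' @param X Samples-by-features data frame (a `sample_id` column is
#'   ignored) or matrix.
#' @param y Class labels (`"case"`/`"control"`, logical, or 0/1).
#' @param kind `"logistic"` (default), `"svm"`, or `"random_forest"`.
#' @param features Feature names to use; defaults to all columns.
#' @param lambda Ridge penalty for the logistic fit (default 1e-4, on
#'   standardized features).
#' @param seed Integer seed for the stochastic learners.
#' @return An object of class `pds_classifier`.
#' @export
train_classifier <- function(X, y, kind = c("logistic", "svm",
                                            "random_forest"),
                             features = NULL, lambda = 1e-4, seed = 1L) {
  kind <- match.arg(kind)
  X <- selection_matrix(X)
  y01 <- as_case01(y)
  if (length(unique(y01)) < 2L) abort("both classes must be present")
  features <- features %||% colnames(X)
  if (length(features) > 0L && !all(features %in% colnames(X))) {
    missing <- setdiff(features, colnames(X))
    abort(paste0("feature not present in the data: ", missing[1]))
  }
  Xf <- X[, features, drop = FALSE]
  fit <- if (length(features) == 0L) {
    if (kind != "logistic") {
      abort("an empty feature set is only supported for kind = 'logistic'")
    }
    p0 <- mean(y01)
    list(intercept = stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6)),
         coefficients = setNames(numeric(0), character(0)),
         lambda = lambda)
  } else if (kind == "logistic") {
    ridge_logistic(Xf, y01, lambda = lambda)
  } else if (kind == "svm") {
    set.seed(seed)
    e1071::svm(Xf, factor(y01, levels = c(0, 1)), probability = TRUE,
               kernel = "radial")
  } else {
    set.seed(seed)
    randomForest::randomForest(Xf, factor(y01, levels = c(0, 1)))
  }
  structure(list(kind = kind, features = features, fit = fit,
                 lambda = lambda, seed = seed),
            class = "pds_classifier")
}

#' Predict case probabilities
#'
#' @param object A `pds_classifier`.
#' @param newdata Data frame or matrix containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of case probabilities in `(0, 1)`.
#' @export
predict.pds_classifier <- function(object, newdata, ...) {
  X <- selection_matrix(newdata)
  if (length(object$features) == 0L) {
    return(rep(plogis(object$fit$intercept), nrow(X)))
  }
  missing <- setdiff(object$features, colnames(X))
  if (length(missing) > 0L) {
    abort(paste0("feature not present in the data: ", missing[1]))
  }
  Xf <- X[, object$features, drop = FALSE]
  switch(object$kind,
    logistic = {
      eta <- object$fit$intercept +
        as.numeric(Xf %*% object$fit$coefficients)
      plogis(eta)
    },
    svm = {
      pr <- predict(object$fit, Xf, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    random_forest = {
      unname(predict(object$fit, Xf, type = "prob")[, "1"])
    })
}

#' @export
print.pds_classifier <- function(x, ...) {
  cat(sprintf("<pds_classifier> %s on %d feature(s)\n",
              x$kind, length(x$features)))
  if (length(x$features) > 0L) {
    cat(" features:", paste(head(x$features, 8), collapse = ", "),
        if (length(x$features) > 8) "...\n" else "\n")
  }
  invisible(x)
}

# ---- metric suite -------------------------------------------------------

#' Area under the ROC curve
#'
#' Midrank (Mann-Whitney) AUC: the probability that a random case scores
#' above a random control, ties counted one half.  Identical to the
#' trapezoidal area under the tie-aware ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param y Class labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  y01 <- as_case01(y)
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Internal: ROC curve points from a threshold sweep over unique scores.
roc_points <- function(scores, y01) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y01[ord]
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie block
  tpr <- cumsum(yy)[last] / n1
  fpr <- cumsum(1 - yy)[last] / n0
  tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion-matrix metric suite
#'
#' Sensitivity, specificity, F1, and Matthews correlation coefficient
#' from raw counts.  MCC is defined as 0 whenever a denominator factor
#' vanishes.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row tibble with the counts and the four metrics.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec, f1 = f1, mcc = mcc)
}

#' Evaluate a classifier on a labelled dataset
#'
#' Computes the full metric suite: midrank AUC plus
#' sensitivity/specificity/MCC/F1 at the given probability threshold.
#'
#' @param model A `pds_classifier` (or `NULL` when `scores` is given).
#' @param X Data containing the model's features.
#' @param y Class labels.
#' @param threshold Probability cutoff for calling a case (default 0.5).
#' @param dataset Name recorded in the report.
#' @param scores Optional pre-computed scores (bypasses `model`/`X`).
#' @return A one-row tibble of class `evaluation_report` (`dataset`,
#'   `n`, `auc`, `sensitivity`, `specificity`, `mcc`, `f1`, counts) with
#'   the tie-aware ROC curve in attribute `"roc"` (monotone, from (0,0)
#'   to (1,1)).
#' @export
evaluate_classifier <- function(model, X, y, threshold = 0.5,
                                dataset = "data", scores = NULL) {
  y01 <- as_case01(y)
  if (is.null(scores)) scores <- predict(model, X)
  stopifnot(length(scores) == length(y01))
  auc <- auc_score(scores, y01)
  pred <- as.integer(scores >= threshold)
  cm <- confusion_metrics(tp = sum(pred == 1L & y01 == 1L),
                          fp = sum(pred == 1L & y01 == 0L),
                          tn = sum(pred == 0L & y01 == 0L),
                          fn = sum(pred == 0L & y01 == 1L))
  out <- dplyr::bind_cols(tibble(dataset = dataset, n = length(y01),
                                 auc = auc), cm)
  attr(out, "roc") <- roc_points(scores, y01)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Single-variate diagnostic models
#'
#' For each feature, fits a one-feature ridge logistic model and runs a
#' two-sided Welch t-test between the classes; features are returned
#' sorted by p-value.  Zero-variance features are flagged and given
#' coefficient 0 and p-value 1.
#'
#' @inheritParams cfs_search
#' @param lambda Ridge penalty for the per-feature logistic fits.
#' @return Tibble (`feature`, `coefficient`, `t_statistic`, `p_value`,
#'   `degenerate`) sorted by increasing p-value.
#' @export
univariate_models <- function(X, y, lambda = 1e-4) {
  X <- selection_matrix(X)
  y01 <- as_case01(y)
  if (length(unique(y01)) < 2L) abort("both classes must be present")
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (sd(x) == 0) {
      return(tibble(feature = colnames(X)[j], coefficient = 0,
                    t_statistic = 0, p_value = 1, degenerate = TRUE))
    }
    fit <- ridge_logistic(X[, j, drop = FALSE], y01, lambda = lambda)
    tt <- t.test(x[y01 == 1L], x[y01 == 0L])
    tibble(feature = colnames(X)[j],
           coefficient = unname(fit$coefficients[1]),
           t_statistic = unname(tt$statistic),
           p_value = tt$p.value, degenerate = FALSE)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
}
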