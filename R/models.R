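# Prediction models: PLSR with RMSEP-based component selection, SVM
# promiscuity classifier, CART compound-class tree.

#' Partial least squares regression with RMSEP component selection
#'
#' Fits PLS regression (through [mixOmics::pls()], predictors standardized
#' to zero mean and unit variance) of a continuous target on a descriptor
#' matrix. The number of components is chosen as the minimizer of the
#' cross-validated root mean squared error of prediction (RMSEP) over
#' `1..max_components`; the reported correlation `r` between measured and
#' predicted values comes from leave-one-out predictions at the selected
#' component count. Rows with missing values are dropped with a message.
#'
#' @param X Numeric descriptor matrix (named columns).
#' @param y Numeric target vector.
#' @param max_components Largest component count tried (default 10,
#'   capped by the predictor rank).
#' @param cv_folds Folds for the RMSEP curve (default 10).
#' @param loo_r Compute the leave-one-out `r` (default `TRUE`; skipping
#'   it leaves `r = NA`, useful when only loadings are needed).
#' @param seed Seed for the fold assignment (default 1).
#' @return Object of class `plsr_fit`: `n_components`, `rmsep`
#'   (per component), `r`, `loadings` (first two components),
#'   `predicted` (LOO), `n`, `seed`.
#' @export
fit_plsr <- function(X, y, max_components = 10, cv_folds = 10,
                     loo_r = TRUE, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- complete.cases(X) & !is.na(y)
  if (any(!keep)) message(sum(!keep), " incomplete row(s) dropped")
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  if (n < 20) stop("need at least 20 complete rows, got ", n)
  constant <- apply(X, 2, sd) == 0
  if (any(constant)) {
    message(sum(constant), " constant predictor(s) dropped")
    X <- X[, !constant, drop = FALSE]
  }
  ncomp_max <- min(max_components, ncol(X), n - ceiling(n / cv_folds) - 1)
  if (ncomp_max < 1) stop("no usable PLS components (rank-deficient input)")
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  sse <- numeric(ncomp_max)
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = ncomp_max,
                         mode = "regression", scale = TRUE)
    pred <- predict(fit, X[!tr, , drop = FALSE])$predict
    for (h in seq_len(ncomp_max))
      sse[h] <- sse[h] + sum((y[!tr] - pred[, 1, h])^2)
  }
  rmsep <- sqrt(sse / n)
  ncomp <- which.min(rmsep)
  full <- mixOmics::pls(X, y, ncomp = max(ncomp, 2), mode = "regression",
                        scale = TRUE)
  loadings <- full$loadings$X[, seq_len(min(2, ncol(full$loadings$X))),
                              drop = FALSE]
  # orient each component so its score correlates positively with y,
  # making loading signs interpretable (PLS signs are otherwise arbitrary)
  for (h in seq_len(ncol(loadings))) {
    flip <- cor(full$variates$X[, h], y)
    if (!is.na(flip) && flip < 0) loadings[, h] <- -loadings[, h]
  }
  pred_loo <- rep(NA_real_, n)
  r <- NA_real_
  if (loo_r) {
    for (i in seq_len(n)) {
      f <- mixOmics::pls(X[-i, , drop = FALSE], y[-i], ncomp = ncomp,
                         mode = "regression", scale = TRUE)
      pred_loo[i] <- predict(f, X[i, , drop = FALSE])$predict[, 1, ncomp]
    }
    r <- cor(y, pred_loo)
  }
  structure(list(n_components = ncomp, rmsep = rmsep, r = r,
                 loadings = loadings, predicted = pred_loo, measured = y,
                 n = n, seed = seed), class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("<plsr_fit> n =", x$n, "| components =", x$n_components,
      "| LOO r =", ifelse(is.na(x$r), "not computed", round(x$r, 3)), "\n")
  invisible(x)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k)
      stop("class '", lv, "' has fewer members (", length(idx),
           ") than folds (", k, ")")
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' SVM promiscuity classifier with stratified cross-validation
#'
#' Trains support vector machines (through [e1071::svm()], variables
#' scaled) to separate promiscuous from selective compounds and reports
#' the stratified 5-fold cross-validation error for each kernel.
#'
#' @param X Numeric descriptor matrix.
#' @param labels Two-level factor or character vector.
#' @param kernels Kernel names (default linear, radial, polynomial).
#' @param folds Number of CV folds (default 5).
#' @param seed Fold-assignment seed (default 1).
#' @return Object of class `svm_fit`: `cv_error` (named per kernel),
#'   `best_kernel`, `best_error`.
#' @export
fit_svm_promiscuity <- function(X, labels,
                                kernels = c("linear", "radial", "polynomial"),
                                folds = 5, seed = 1) {
  X <- as.matrix(X)
  keep <- complete.cases(X) & !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  if (nlevels(labels) < 2) stop("both classes must be present")
  fold_id <- stratified_folds(as.character(labels), folds, seed)
  errs <- setNames(numeric(length(kernels)), kernels)
  for (kn in kernels) {
    wrong <- 0
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      fit <- e1071::svm(X[tr, , drop = FALSE], labels[tr], kernel = kn,
                        scale = TRUE)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      wrong <- wrong + sum(pred != labels[!tr])
    }
    errs[kn] <- wrong / nrow(X)
  }
  structure(list(cv_error = errs, best_kernel = names(which.min(errs)),
                 best_error = min(errs), folds = folds, seed = seed),
            class = "svm_fit")
}

#' @export
print.svm_fit <- function(x, ...) {
  cat("<svm_fit>", x$folds, "fold CV | best kernel:", x$best_kernel,
      "| error:", round(x$best_error, 3), "\n")
  invisible(x)
}

#' Classification tree for compound class
#'
#' Fits a CART model ([rpart::rpart()]) predicting compound class from
#' descriptors and prunes it to the split count within `split_range`
#' that minimizes the cross-validated prediction error.
#'
#' @param X Numeric descriptor matrix or data frame.
#' @param classes Factor/character class labels (>= 2 classes).
#' @param split_range Allowed split counts (default 3:10).
#' @param seed Seed for the internal cross-validation (default 1).
#' @return Object of class `cart_fit`: `tree` (pruned rpart object),
#'   `n_splits`, `cv_error` (absolute cross-validated misclassification
#'   rate), `train_error`.
#' @export
fit_cart_class <- function(X, classes, split_range = 3:10, seed = 1) {
  df <- as.data.frame(X)
  keep <- complete.cases(df) & !is.na(classes)
  df <- df[keep, , drop = FALSE]
  cls <- factor(classes[keep])
  if (nlevels(cls) < 2) stop("need at least 2 classes")
  if (all(vapply(df, function(v) length(unique(v)) == 1, logical(1))))
    stop("all predictors constant")
  df$.class <- cls
  set.seed(seed)
  tree <- rpart::rpart(.class ~ ., data = df, method = "class",
                       control = rpart::rpart.control(cp = 1e-4,
                                                      minsplit = 10,
                                                      xval = 10))
  ct <- tree$cptable
  in_range <- ct[, "nsplit"] >= min(split_range) &
    ct[, "nsplit"] <= max(split_range)
  rows <- if (any(in_range)) which(in_range) else
    order(abs(ct[, "nsplit"] - median(split_range)))[1]
  best <- rows[which.min(ct[rows, "xerror"])]
  pruned <- rpart::prune(tree, cp = ct[best, "CP"])
  root_err <- mean(cls != names(sort(table(cls), decreasing = TRUE))[1])
  pred <- predict(pruned, df, type = "class")
  structure(list(tree = pruned, n_splits = unname(ct[best, "nsplit"]),
                 cv_error = unname(ct[best, "xerror"]) * root_err,
                 train_error = mean(pred != cls), seed = seed),
            class = "cart_fit")
}

#' @export
print.cart_fit <- function(x, ...) {
  cat("<cart_fit>", x$n_splits, "splits | CV misclassification:",
      round(x$cv_error, 3), "\n")
  invisible(x)
}
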