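#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative,
#' counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Ridge-stabilized logistic regression
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' with a weak fixed ridge penalty on the coefficients (intercept
#' unpenalized), so that a finite fit exists even under perfect
#' separation. The fit is deterministic given the data.
#'
#' @param X numeric matrix (subjects x features).
#' @param y 0/1 response.
#' @param lambda ridge penalty; default 1e-3.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return object of class `ridge_logit` with elements `coefficients`
#'   (intercept first), `lambda`, `converged`.
#' @export
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- numeric(p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    new_beta <- solve(XtW %*% Xd + pen, XtW %*% z)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  structure(list(coefficients = drop(beta), lambda = lambda,
                 converged = converged, feature_names = colnames(X)),
            class = "ridge_logit")
}

#' @export
coef.ridge_logit <- function(object, ...) object$coefficients

#' @param object a `ridge_logit` fit.
#' @param newdata matrix with the same columns as the training matrix.
#' @param ... unused.
#' @return linear-predictor scores (monotone in the fitted probability).
#' @rdname ridge_logistic
#' @export
predict.ridge_logit <- function(object, newdata, ...) {
  drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
}

# Stratified train/test split: returns logical vector, TRUE = training row.
stratified_split <- function(y, test_fraction, seed) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  train <- rep(TRUE, length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test_idx <- sample(idx, n_test)
    train[test_idx] <- FALSE
  }
  if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2)
    stop("degenerate split: a class is absent from train or test")
  train
}

#' Step-forward wrapper feature selection scored by holdout AUC
#'
#' Greedy wrapper selection: starting from the empty set, at each step the
#' candidate feature whose addition maximizes the holdout-set ROC AUC of a
#' refit ridge-stabilized logistic classifier is added, until the largest
#' requested size is reached. Selected sets are nested: the size-15 set is
#' a prefix of the size-20 run under the same seed and split. A requested
#' size equal to the number of available features returns the full pool
#' without search.
#'
#' @param X complete 0/1 subjects x features matrix.
#' @param y binary target (0/1 vector, length nrow(X)).
#' @param sizes integer vector of requested set sizes.
#' @param seed integer driving the stratified 70/30 holdout split.
#' @param test_fraction holdout fraction (default 0.3, stratified).
#' @param lambda ridge penalty passed to [ridge_logistic()].
#' @param target_name stored for bookkeeping.
#' @return a list of objects of class `feature_set` (one per size), each
#'   with `ordered_features`, `auc_trajectory` (holdout AUC after each
#'   addition), `train_auc_trajectory`, `size`, `split_seed`.
#' @export
step_forward_select <- function(X, y, sizes, seed = 1L, test_fraction = 0.3,
                                lambda = 1e-3, target_name = "target") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) > ncol(X)) stop("requested size exceeds the feature pool")
  search_sizes <- sizes[sizes < ncol(X)]
  max_search <- if (length(search_sizes)) max(search_sizes) else 0L

  selected <- character(0)
  ho_auc <- numeric(0)
  tr_auc <- numeric(0)
  if (max_search > 0) {
    train <- stratified_split(y, test_fraction, seed)
    pool <- colnames(X)
    for (step in seq_len(max_search)) {
      cands <- sort(setdiff(pool, selected))
      best <- -Inf; best_f <- NA_character_; best_tr <- NA_real_
      for (f in cands) {
        cols <- c(selected, f)
        fit <- ridge_logistic(X[train, cols, drop = FALSE], y[train], lambda)
        a <- roc_auc(predict(fit, X[!train, cols, drop = FALSE]), y[!train])
        if (a > best) {
          best <- a; best_f <- f
          best_tr <- roc_auc(predict(fit, X[train, cols, drop = FALSE]), y[train])
        }
      }
      selected <- c(selected, best_f)
      ho_auc <- c(ho_auc, best)
      tr_auc <- c(tr_auc, best_tr)
    }
  }

  out <- lapply(sizes, function(s) {
    if (s == ncol(X)) {
      fs <- list(target_name = target_name, size = s,
                 ordered_features = colnames(X),
                 auc_trajectory = NULL, train_auc_trajectory = NULL,
                 split_seed = seed, searched = FALSE)
    } else {
      fs <- list(target_name = target_name, size = s,
                 ordered_features = selected[seq_len(s)],
                 auc_trajectory = ho_auc[seq_len(s)],
                 train_auc_trajectory = tr_auc[seq_len(s)],
                 split_seed = seed, searched = TRUE)
    }
    structure(fs, class = "feature_set")
  })
  names(out) <- as.character(sizes)
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set for", x$target_name, "- size", x$size,
      if (!x$searched) "(full pool, no search)" else "", "\n")
  cat("  ", paste(head(x$ordered_features, 10), collapse = ", "),
      if (x$size > 10) "..." else "", "\n")
  if (!is.null(x$auc_trajectory))
    cat("  final holdout AUC:", round(tail(x$auc_trajectory, 1), 4), "\n")
  invisible(x)
}

#' Write a feature set as JSON
#'
#' @param fset a `feature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fset, path) {
  jsonlite::write_json(unclass(fset), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
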