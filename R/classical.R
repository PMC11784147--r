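# Classical-classifier roster selected by stratified five-fold
# cross-validation accuracy. Members wrap established implementations
# (MASS::lda, nnet::multinom, ranger) behind a uniform fit/predict-proba
# interface; the ridge classifier is closed-form one-hot indicator ridge
# regression, and the kNN member votes over a distance matrix so full class
# probabilities are available for log loss.

roster_member <- function(name, fit, predict_proba) {
  list(name = name, fit = fit, predict_proba = predict_proba)
}

# Ridge regression of centered one-hot indicators on standardized features;
# class scores -> softmax probabilities (documented convention).
ridge_member <- function(lambda = 1.0) {
  roster_member(
    "ridge",
    fit = function(X, y, classes, seed) {
      mu <- colMeans(X)
      sdv <- apply(X, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
      Y <- one_hot(y, classes)
      Yc <- sweep(Y, 2L, colMeans(Y))
      B <- solve(crossprod(Xs) + lambda * diag(ncol(Xs)), crossprod(Xs, Yc))
      list(B = B, mu = mu, sdv = sdv, y_mean = colMeans(Y), classes = classes)
    },
    predict_proba = function(fit, X) {
      Xs <- sweep(sweep(as.matrix(X), 2L, fit$mu), 2L, fit$sdv, `/`)
      softmax(sweep(Xs %*% fit$B, 2L, fit$y_mean, `+`))
    })
}

logistic_member <- function(maxit = 100L) {
  roster_member(
    "logistic",
    fit = function(X, y, classes, seed) {
      df <- data.frame(.y = factor(y, levels = classes), X)
      fit <- nnet::multinom(.y ~ ., data = df, maxit = maxit, trace = FALSE,
                            MaxNWts = 50000L)
      list(fit = fit, classes = classes)
    },
    predict_proba = function(fit, X) {
      p <- stats::predict(fit$fit, newdata = data.frame(as.matrix(X)), type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # binomial case returns a vector
      colnames(p) <- fit$classes
      p
    })
}

lda_member <- function() {
  roster_member(
    "lda",
    fit = function(X, y, classes, seed) {
      keep <- apply(X, 2L, stats::sd) > 1e-10
      fit <- suppressWarnings(MASS::lda(X[, keep, drop = FALSE],
                                        grouping = factor(y, levels = classes)))
      list(fit = fit, keep = keep, classes = classes)
    },
    predict_proba = function(fit, X) {
      p <- stats::predict(fit$fit, as.matrix(X)[, fit$keep, drop = FALSE])$posterior
      out <- matrix(0, nrow(p), length(fit$classes), dimnames = list(NULL, fit$classes))
      out[, colnames(p)] <- p
      out
    })
}

# kNN with Laplace-smoothed vote shares as probabilities; squared Euclidean
# distances via the crossprod expansion.
knn_member <- function(k = 5L) {
  roster_member(
    "knn",
    fit = function(X, y, classes, seed) list(X = X, y = y, k = k, classes = classes),
    predict_proba = function(fit, X) {
      X <- as.matrix(X)
      d2 <- outer(rowSums(X^2), rowSums(fit$X^2), `+`) - 2 * X %*% t(fit$X)
      kk <- min(fit$k, nrow(fit$X))
      probs <- matrix(0, nrow(X), length(fit$classes),
                      dimnames = list(NULL, fit$classes))
      for (i in seq_len(nrow(X))) {
        nb <- fit$y[order(d2[i, ])[seq_len(kk)]]
        votes <- table(factor(nb, levels = fit$classes))
        probs[i, ] <- (votes + 1 / length(fit$classes)) / (kk + 1)
      }
      probs
    })
}

rf_member <- function(num_trees = 200L) {
  roster_member(
    "random_forest",
    fit = function(X, y, classes, seed) {
      df <- data.frame(.y = factor(y, levels = classes), X)
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = num_trees,
                            probability = TRUE, seed = seed, num.threads = 1L)
      list(fit = fit, classes = classes)
    },
    predict_proba = function(fit, X) {
      p <- stats::predict(fit$fit, data = data.frame(as.matrix(X)),
                          num.threads = 1L)$predictions
      p[, fit$classes, drop = FALSE]
    })
}

#' Default classical roster
#'
#' Ridge classifier, multinomial logistic regression, linear discriminant
#' analysis, k-nearest neighbors (k = 5), and a random forest.
#'
#' @return Named list of roster members.
#' @export
default_roster <- function() {
  members <- list(ridge_member(), logistic_member(), lda_member(),
                  knn_member(), rf_member())
  stats::setNames(members, vapply(members, `[[`, "", "name"))
}

#' Select the best classical model by stratified five-fold CV accuracy
#'
#' Each roster member is scored by stratified k-fold cross-validation
#' accuracy on the training rows; the best (ties broken by roster order) is
#' refit on the full training set. Members that fail to fit on any fold are
#' excluded with a warning rather than aborting the selection.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param roster Named list from [default_roster()] (or a subset).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed driving fold assignment and stochastic members.
#' @param classes Class level order; defaults to sorted unique labels.
#' @return A `fitted_model` of kind `"classical"` carrying the per-fold
#'   `cv_table` and the winning member's name.
#' @export
train_classical_roster <- function(X, y, roster = default_roster(), folds = 5L,
                                   seed = 1L, classes = NULL) {
  if (length(roster) == 0L) stop_contract("roster must be non-empty")
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- classes %||% sort(unique(y))
  fold <- stratified_folds(y, folds, derive_seed(seed, "cv_folds"))
  cv <- matrix(NA_real_, length(roster), folds,
               dimnames = list(names(roster), paste0("fold", seq_len(folds))))
  for (mi in seq_along(roster)) {
    member <- roster[[mi]]
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold != f
      acc <- tryCatch({
        fit <- member$fit(X[tr, , drop = FALSE], y[tr], classes,
                          derive_seed(seed, "member", member$name, f))
        p <- member$predict_proba(fit, X[!tr, , drop = FALSE])
        mean(classes[max.col(p, ties.method = "first")] == y[!tr])
      }, error = function(e) {
        warning("roster member '", member$name, "' failed on fold ", f, ": ",
                conditionMessage(e))
        ok <<- FALSE
        NA_real_
      })
      if (!ok) break
      cv[mi, f] <- acc
    }
  }
  mean_acc <- rowMeans(cv)
  if (all(is.na(mean_acc))) stop_contract("every roster member failed to fit")
  best_i <- which.max(replace(mean_acc, is.na(mean_acc), -Inf))
  best <- roster[[best_i]]
  fit <- best$fit(X, y, classes, derive_seed(seed, "refit", best$name))
  structure(list(kind = "classical", target = NA_character_, classes = classes,
                 fit = fit, member = best, n_features = ncol(X),
                 hyperparameters = list(selected = best$name, folds = folds),
                 cv_table = data.frame(model = rownames(cv), cv,
                                       mean_accuracy = mean_acc,
                                       row.names = NULL, check.names = FALSE)),
            class = "fitted_model")
}
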