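# Small separable fixture: two Gaussian clouds embedded in 426 features.
clouds_426 <- function(n = 200L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * 426), n)
  y <- rep(c("a", "b"), length.out = n)
  X[y == "b", 1:20] <- X[y == "b", 1:20] + shift
  list(X = X, y = y)
}

nearest_centroid_acc <- function(Xtr, ytr, Xte, yte) {
  cents <- sapply(unique(ytr), function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  d <- sapply(seq_len(ncol(cents)), function(j) rowSums(sweep(Xte, 2, cents[, j])^2))
  mean(unique(ytr)[max.col(-d)] == yte)
}

test_that("PLS-DA separates Gaussian clouds at least as well as nearest centroid", {
  d <- clouds_426(seed = 2)
  te <- clouds_426(n = 100, seed = 3)
  m <- train_plsda(d$X, d$y, ncomp = 2)
  p <- predict(m, te$X)
  acc <- mean(p$labels == te$y)
  expect_gte(acc, 0.95)
  oracle <- nearest_centroid_acc(d$X, d$y, te$X, te$y)
  expect_gte(oracle, 0.95)   # the construction is genuinely separable
  expect_gte(acc, oracle - 0.05)
})

test_that("PLS-DA refuses single-class targets and caps excess components", {
  d <- clouds_426(n = 40, seed = 4)
  expect_error(train_plsda(d$X, rep("a", 40)), class = "hsi_contract_error")
  expect_warning(m <- train_plsda(d$X, d$y, ncomp = 500), "capped")
  expect_lte(m$hyperparameters$ncomp, 39L)
})

test_that("PLS-DA predictions are invariant to a constant feature shift on refit", {
  d <- clouds_426(n = 120, seed = 5)
  te <- clouds_426(n = 60, seed = 6)
  m1 <- train_plsda(d$X, d$y, ncomp = 3)
  m2 <- train_plsda(d$X + 7, d$y, ncomp = 3)
  p1 <- predict(m1, te$X)
  p2 <- predict(m2, te$X + 7)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-8)
})

test_that("SIMPLS scores agree with the mixOmics PLS-DA oracle on binary targets", {
  set.seed(10)
  n <- 80L; p <- 12L
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 1
  ours <- train_plsda(X, y, ncomp = 3)
  score_ours <- sandwichHSI:::plsda_scores(ours, X)[, "b"]
  oracle <- mixOmics::plsda(X, factor(y), ncomp = 3)
  pr <- predict(oracle, X)
  score_oracle <- pr$predict[, "b", 3]
  expect_gt(cor(score_ours, score_oracle), 0.999)
  expect_identical(predict(ours, X)$labels, as.character(pr$class$max.dist[, 3]))
})

test_that("a one-member roster returns that member", {
  d <- clouds_426(n = 60, seed = 7)
  m <- train_classical_roster(d$X, d$y, default_roster()["ridge"], seed = 1)
  expect_identical(m$hyperparameters$selected, "ridge")
  expect_error(train_classical_roster(d$X, d$y, list()), class = "hsi_contract_error")
})

test_that("roster selection is seeded and matches an exhaustive CV recomputation", {
  # a near-collinear informative pair among many noise features: ridge pools
  # the collinear pair, while 5-NN distances drown in the noise dimensions
  set.seed(11)
  n <- 100L
  z <- rnorm(n)
  X <- cbind(z + rnorm(n, sd = 0.05), z + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 300), n))
  y <- ifelse(z > 0, "pos", "neg")
  roster <- default_roster()[c("ridge", "knn")]
  m1 <- train_classical_roster(X, y, roster, seed = 9)
  m2 <- train_classical_roster(X, y, roster, seed = 9)
  expect_identical(m1$hyperparameters$selected, m2$hyperparameters$selected)
  expect_identical(m1$cv_table, m2$cv_table)
  expect_identical(m1$hyperparameters$selected, "ridge")
  # independent recomputation of the fold accuracies
  fold <- sandwichHSI:::stratified_folds(y, 5L, derive_seed(9, "cv_folds"))
  for (nm in names(roster)) {
    for (f in 1:5) {
      tr <- fold != f
      fit <- roster[[nm]]$fit(X[tr, ], y[tr], sort(unique(y)),
                              derive_seed(9, "member", nm, f))
      pr <- roster[[nm]]$predict_proba(fit, X[!tr, ])
      acc <- mean(sort(unique(y))[max.col(pr, ties.method = "first")] == y[!tr])
      expect_equal(m1$cv_table[m1$cv_table$model == nm, paste0("fold", f)], acc)
    }
  }
})

test_that("every roster member emits valid probabilities on a 3-class task", {
  set.seed(12)
  n <- 90L
  X <- matrix(rnorm(n * 10), n)
  y <- rep(c("a", "b", "c"), each = 30)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "c", 2] <- X[y == "c", 2] + 2
  classes <- c("a", "b", "c")
  for (member in default_roster()) {
    fit <- member$fit(X, y, classes, 5L)
    p <- member$predict_proba(fit, X[1:10, ])
    expect_identical(colnames(p), classes)
    expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-9,
                 label = member$name)
    expect_true(all(p >= 0), label = member$name)
  }
})

test_that("the search grid enumerates lr x solver x activation x layouts", {
  configs <- enumerate_grid(mlp_grid())
  expect_length(configs, 88L)
  expect_identical(2L * 2L * 2L * 11L, 88L)
  small <- list(learning_rate = 0.001, solver = "adam", activation = "relu",
                hidden = list(c(8L)))
  expect_length(enumerate_grid(small), 1L)
  expect_error(enumerate_grid(list(learning_rate = numeric(0), solver = "adam",
                                   activation = "relu", hidden = list(8L))),
               class = "hsi_contract_error")
})

test_that("a degenerate grid search runs one config and five fits", {
  d <- clouds_426(n = 100, seed = 13)
  small <- list(learning_rate = 0.01, solver = "adam", activation = "relu",
                hidden = list(c(8L)))
  gs <- grid_search_mlp(d$X, d$y, small, folds = 5, seed = 2, max_epochs = 5)
  expect_identical(gs$n_configs, 1L)
  expect_identical(gs$n_fits, 5L)
  expect_s3_class(gs$model, "fitted_model")
})

test_that("MLP training is reproducible and solver aliases resolve", {
  d <- clouds_426(n = 80, seed = 14)
  cfg <- mlp_config(hidden = c(12L), max_epochs = 15)
  m1 <- train_mlp(d$X, d$y, cfg, seed = 3)
  m2 <- train_mlp(d$X, d$y, cfg, seed = 3)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$fit$par, m2$fit$par)
  cfg_sig <- mlp_config(hidden = c(8L), solver = "sigmoid", max_epochs = 3)
  expect_identical(cfg_sig$solver, "sgd")
  expect_identical(cfg_sig$solver_label, "sigmoid")
  m3 <- train_mlp(d$X, d$y, cfg_sig, seed = 3)
  expect_identical(nrow(m3$history), 3L)
})

test_that("the MLP learns XOR structure that a linear model cannot", {
  set.seed(15)
  n <- 600L
  X <- matrix(runif(n * 2, -1, 1), n)
  y <- ifelse(X[, 1] * X[, 2] > 0, "same", "opposite")
  cfg <- mlp_config(hidden = c(16L, 8L), learning_rate = 0.01, max_epochs = 150,
                    patience = 150)
  m <- train_mlp(X, y, cfg, seed = 4)
  expect_gt(mean(predict(m, X)$labels == y), 0.85)
  # linear oracle: indicator ridge regression is at chance on XOR
  ridge <- default_roster()$ridge
  fit <- ridge$fit(X, y, sort(unique(y)), 1L)
  p <- ridge$predict_proba(fit, X)
  expect_lt(mean(sort(unique(y))[max.col(p)] == y), 0.65)
})

test_that("early stopping halts patience epochs after the best epoch", {
  d <- clouds_426(n = 150, shift = 4, seed = 16)  # easy: accuracy saturates fast
  cfg <- mlp_config(hidden = c(8L), max_epochs = 400, patience = 20)
  m <- train_mlp(d$X, d$y, cfg, seed = 5)
  expect_lt(m$stop_epoch, 400L)
  expect_identical(m$stop_epoch, m$best_epoch + 20L)
  expect_identical(nrow(m$history), m$stop_epoch)
})

test_that("prediction contracts hold: normalization, argmax, width check", {
  d <- clouds_426(n = 100, shift = 3, seed = 17)
  m <- train_plsda(d$X, d$y, ncomp = 2)
  p <- predict(m, d$X)
  expect_equal(unname(rowSums(p$prob)), rep(1, 100), tolerance = 1e-9)
  expect_identical(p$labels, m$classes[max.col(p$prob, ties.method = "first")])
  expect_identical(mean(p$labels == d$y), 1)  # memorizing regime on separable data
  expect_error(predict(m, d$X[, 1:100]), class = "hsi_dimension_error")
})

test_that("divergent training reports the epoch and learning rate", {
  d <- clouds_426(n = 60, seed = 18)
  # an unbounded step makes the first update non-finite; the guard must
  # surface it as a divergence error rather than silent NaN probabilities
  cfg <- mlp_config(hidden = c(8L), solver = "sgd", learning_rate = Inf,
                    max_epochs = 5, batch_size = 20L)
  err <- tryCatch(train_mlp(d$X, d$y, cfg, seed = 6), condition = identity)
  expect_s3_class(err, "hsi_divergence_error")
  expect_match(conditionMessage(err), "epoch")
  expect_match(conditionMessage(err), "learning rate")
})
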