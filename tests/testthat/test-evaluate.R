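test_that("accuracy is the fraction of correct predictions", {
  expect_identical(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_identical(accuracy(c("a", "b", "a", "b"), c("b", "a", "b", "a")), 0)
  expect_error(accuracy(character(0), character(0)), class = "hsi_contract_error")
  expect_error(accuracy(c("a", "b"), "a"), class = "hsi_contract_error")
})

test_that("uniform random 6-class prediction scores 1/6 at large n", {
  set.seed(60)
  n <- 60000L
  truth <- sample(filling_levels, n, replace = TRUE)
  pred <- sample(filling_levels, n, replace = TRUE)
  expect_lt(abs(accuracy(truth, pred) - 1 / 6), 0.006)
})

test_that("the per-class TP/TN macro average relates exactly to accuracy", {
  set.seed(61)
  for (C in c(2L, 3L, 6L)) {
    classes <- letters[seq_len(C)]
    truth <- sample(classes, 400, replace = TRUE)
    pred <- sample(classes, 400, replace = TRUE)
    acc <- accuracy(truth, pred)
    macro <- eq1_macro_average(truth, pred, classes)
    if (C == 2L) {
      # binary: the macro TP/TN form IS the correct/total fraction
      expect_equal(macro, acc, tolerance = 1e-12)
    } else {
      # multi-class: every error counts once as FN and once as FP, so the
      # macro form is an affine transform of the correct/total fraction
      expect_equal(macro, 1 - (2 / C) * (1 - acc), tolerance = 1e-12)
    }
  }
})

test_that("log loss hits its closed forms", {
  classes <- c("x", "y")
  perfect <- one_hot_probs <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                                     dimnames = list(NULL, classes))
  expect_lte(log_loss(c("x", "y"), perfect), 3.1e-14)
  uniform2 <- matrix(0.5, 4, 2, dimnames = list(NULL, classes))
  expect_equal(log_loss(rep(c("x", "y"), 2), uniform2), log(2), tolerance = 1e-12)
  uniform6 <- matrix(1 / 6, 12, 6, dimnames = list(NULL, filling_levels))
  expect_equal(log_loss(rep(filling_levels, 2), uniform6), log(6), tolerance = 1e-12)
})

test_that("log loss penalizes misplaced confidence monotonically", {
  classes <- c("x", "y")
  path <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(path, function(p) {
    probs <- matrix(c(p, 1 - p), 1, dimnames = list(NULL, classes))
    log_loss("x", probs)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))  # more mass on the truth, lower loss
})

test_that("log loss enforces its probability contracts", {
  bad <- matrix(c(0.6, 0.6), 1, dimnames = list(NULL, c("x", "y")))
  expect_error(log_loss("x", bad), class = "hsi_contract_error")
  ok <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("x", "y")))
  expect_error(log_loss("z", ok), class = "hsi_contract_error")
  expect_error(log_loss(c("x", "x"), ok), class = "hsi_contract_error")
})

test_that("confusion matrices count, normalize and flag zero support", {
  truth <- c("no", "no", "yes", "yes", "yes")
  pred <- c("no", "yes", "yes", "yes", "no")
  cm <- confusion(truth, pred, butter_levels)
  expect_identical(cm$counts["no", "no"], 1L)
  expect_identical(cm$counts["yes", "no"], 1L)
  expect_identical(sum(cm$counts), 5L)
  expect_equal(unname(rowSums(cm$row_normalized)), c(1, 1))
  perfect <- confusion(truth, truth, butter_levels)
  expect_equal(unname(perfect$row_normalized), diag(2))
  zs <- confusion(c("no", "no"), c("no", "no"), butter_levels)
  expect_identical(zs$zero_support, "yes")
  expect_equal(unname(zs$row_normalized["yes", ]), c(0, 0))
  expect_error(confusion(c("no", "maybe"), c("no", "no"), butter_levels),
               class = "hsi_contract_error")
})

test_that("row-normalized diagonals equal per-class recall from a counting oracle", {
  set.seed(62)
  truth <- sample(filling_levels, 300, replace = TRUE)
  pred <- sample(filling_levels, 300, replace = TRUE)
  cm <- confusion(truth, pred, filling_levels)
  for (cl in filling_levels) {
    support <- sum(truth == cl)
    recall <- sum(truth == cl & pred == cl) / support
    expect_equal(unname(cm$row_normalized[cl, cl]), recall)
    expect_equal(unname(rowSums(cm$counts)[cl]), support)
  }
  expect_identical(sum(cm$counts), 300L)
})

# Shared four-cube fixture for report-level tests: both breads, both butter
# states and two fillings present.
report_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- ci_scene_params()
      lib <- make_endmember_library(seed = 2)
      codes <- c("A1", "A4", "C2", "C3")
      cubes <- lapply(codes, function(cd)
        simulate_sandwich_cube(cd, params, seed = derive_seed(30, cd), library = lib))
      names(cubes) <- paste0("sandwich_", codes, ".hdr")
      st <- build_dataset(cubes, seed = 31)
      tr <- st$meta$split == "train"
      models <- lapply(c(bread = "bread", butter = "butter", filling = "filling"),
                       function(tg) train_plsda(st$features[tr, ],
                                                st$meta[[tg]][tr],
                                                target_spec(tg)))
      cache <<- list(st = st, models = models)
    }
    cache
  }
})

test_that("the combined report carries accuracy, log loss and confusions per target", {
  fx <- report_fixture()
  rep <- eval_report(fx$models, fx$st, split = "test")
  expect_setequal(names(rep$targets), c("bread", "butter", "filling"))
  for (tg in names(rep$targets)) {
    t <- rep$targets[[tg]]
    expect_gte(t$accuracy, 0)
    expect_lte(t$accuracy, 1)
    expect_gte(t$log_loss, 0)
    expect_s3_class(t$confusion, "confusion_matrix")
  }
  # fillings absent from this four-cube subset appear as zero-support rows
  expect_setequal(rep$targets$filling$confusion$zero_support,
                  setdiff(filling_levels, c("mature cheese", "jelly")))
  expect_error(eval_report(fx$models[c("bread", "butter")], fx$st),
               class = "hsi_contract_error")
})

test_that("training-split evaluation dominates the held-out split", {
  fx <- report_fixture()
  rep_tr <- eval_report(fx$models, fx$st, split = "train")
  rep_te <- eval_report(fx$models, fx$st, split = "test")
  for (tg in names(rep_tr$targets))
    expect_gte(rep_tr$targets[[tg]]$accuracy, rep_te$targets[[tg]]$accuracy - 0.02)
})

test_that("the JSON report round-trips its numbers exactly", {
  fx <- report_fixture()
  rep <- eval_report(fx$models, fx$st, split = "test")
  path <- tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- jsonlite::fromJSON(path)
  for (tg in names(rep$targets)) {
    expect_equal(back$targets[[tg]]$accuracy, rep$targets[[tg]]$accuracy,
                 tolerance = 1e-12)
    expect_equal(back$targets[[tg]]$log_loss, rep$targets[[tg]]$log_loss,
                 tolerance = 1e-12)
    expect_equal(unname(as.matrix(back$targets[[tg]]$row_normalized)),
                 unname(rep$targets[[tg]]$confusion$row_normalized))
  }
})

test_that("the combined confusion table has one row per ground-truth class", {
  fx <- report_fixture()
  rep <- eval_report(fx$models, fx$st, split = "test")
  tab <- combined_confusion_table(rep)
  expect_identical(nrow(tab), 2L + 2L + 6L)
  expect_identical(tab$target, rep(c("bread", "butter", "filling"), c(2L, 2L, 6L)))
})

test_that("training-curve plots build from an MLP history", {
  d <- list(X = matrix(rnorm(60 * 5), 60), y = rep(c("a", "b"), 30))
  m <- train_mlp(d$X, d$y, mlp_config(hidden = c(4L), max_epochs = 5), seed = 1)
  expect_s3_class(plot_history(m), "ggplot")
})
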