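# Evaluation: accuracy (correct/total), multi-class log loss (natural log,
# probabilities clipped at 1e-15), row-normalized confusion matrices in the
# fixed per-target class order, and a combined per-target report with the
# MLP training curves.

#' Classification accuracy
#'
#' The fraction of predictions equal to the ground truth. For single-label
#' problems this is the operational form of the per-class TP/TN ratio
#' average: the two coincide exactly for binary targets, and for C classes
#' the macro TP/TN average equals `1 - (2/C) * (1 - accuracy)`.
#'
#' @param y_true,y_pred Equal-length label vectors (non-empty).
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop_contract("y_true and y_pred must be non-empty and equal length")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Multi-class log loss
#'
#' Average negative log-likelihood of the observed classes under the
#' predicted probabilities, `-(1/N) sum_i sum_j y_ij ln p_ij`, with
#' probabilities clipped to `[1e-15, 1 - 1e-15]`. Confident wrong
#' predictions are penalized most; 0 is a perfect score.
#'
#' @param y_true Label vector.
#' @param probs Probability matrix, one row per sample, columns named by
#'   class (or ordered as `classes`); rows must sum to 1 within 1e-6.
#' @param classes Class order when `probs` lacks column names.
#' @return Non-negative score.
#' @export
log_loss <- function(y_true, probs, classes = colnames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(classes)) stop_contract("probs needs column names or explicit classes")
  if (length(y_true) != nrow(probs))
    stop_contract("y_true length must match probability rows")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_contract("probability rows must sum to 1 within 1e-6")
  j <- match(as.character(y_true), classes)
  if (anyNA(j)) stop_contract("labels outside the class set: ",
                              paste(unique(y_true[is.na(j)]), collapse = ", "))
  p <- pmin(pmax(probs[cbind(seq_along(j), j)], 1e-15), 1 - 1e-15)
  -mean(log(p))
}

#' Confusion matrix with row-normalized proportions
#'
#' Rows are ground truth, columns predictions, in the fixed class order
#' (bread: white, whole wheat; butter: no, yes; filling: mature cheese, low
#' fat mature cheese, jelly, low sugar jelly, peanut butter, chocolate
#' sprinkles). Each supported row of the normalized matrix sums to 1; rows
#' with zero support are all-zero and listed in `zero_support`.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class order; both label vectors must be subsets of it.
#' @return A `confusion_matrix` with `counts`, `row_normalized`, `classes`,
#'   `zero_support`.
#' @export
confusion <- function(y_true, y_pred, classes) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown) > 0L)
    stop_contract("label(s) outside the class set: ", paste(unknown, collapse = ", "))
  counts <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  support <- rowSums(counts)
  norm <- counts / ifelse(support == 0L, 1L, support)
  structure(list(counts = counts, row_normalized = norm, classes = classes,
                 zero_support = classes[support == 0L]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("<confusion_matrix> (rows = ground truth, row-normalized)\n")
  print(round(x$row_normalized, digits))
  invisible(x)
}

#' Combined evaluation report over the three sandwich targets
#'
#' Accuracy, log loss and a row-normalized confusion matrix per target
#' (bread, butter, filling) on the chosen split, plus each MLP model's
#' per-epoch training history when present.
#'
#' @param models Named list with elements `bread`, `butter`, `filling`, each
#'   a `fitted_model`.
#' @param sample_table A `sample_table` from [build_dataset()].
#' @param split `"test"` (default) or `"train"`.
#' @return An `eval_report`.
#' @export
eval_report <- function(models, sample_table, split = "test") {
  stopifnot(inherits(sample_table, "sample_table"))
  targets <- c("bread", "butter", "filling")
  if (!all(targets %in% names(models)))
    stop_contract("models must be named list with bread, butter, filling; missing: ",
                  paste(setdiff(targets, names(models)), collapse = ", "))
  rows <- sample_table$meta$split == split
  X <- sample_table$features[rows, , drop = FALSE]
  out <- list(split = split, n = sum(rows), targets = list())
  for (tg in targets) {
    spec <- target_spec(tg)
    truth <- sample_table$meta[[tg]][rows]
    pred <- predict(models[[tg]], X)
    out$targets[[tg]] <- list(
      accuracy = accuracy(truth, pred$labels),
      log_loss = log_loss(truth, pred$prob),
      confusion = confusion(truth, pred$labels, spec$classes),
      model_kind = models[[tg]]$kind,
      history = models[[tg]]$history)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split=%s n=%d\n", x$split, x$n))
  for (tg in names(x$targets)) {
    t <- x$targets[[tg]]
    cat(sprintf("  %-8s %-9s accuracy %.3f  log loss %.3f\n",
                tg, paste0("(", t$model_kind, ")"), t$accuracy, t$log_loss))
  }
  invisible(x)
}

#' Render the combined confusion table (all three targets) as a data.frame
#'
#' Block-diagonal layout with one row per ground-truth class and one column
#' per predicted class, row-normalized, as in the study's combined results
#' table.
#'
#' @param report An [eval_report()].
#' @return A data.frame with `target` and `truth` columns followed by the
#'   predicted-class proportions.
#' @export
combined_confusion_table <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  blocks <- lapply(names(report$targets), function(tg) {
    cm <- report$targets[[tg]]$confusion
    df <- as.data.frame(as.table(cm$row_normalized))
    names(df) <- c("truth", "predicted", "proportion")
    df$target <- tg
    df
  })
  wide <- do.call(rbind, blocks)
  out <- stats::reshape(wide, idvar = c("target", "truth"),
                        timevar = "predicted", direction = "wide")
  names(out) <- sub("^proportion\\.", "", names(out))
  rownames(out) <- NULL
  out[, c("target", "truth",
          setdiff(names(out), c("target", "truth")))]
}

#' Write an evaluation report to JSON
#'
#' All numbers (accuracy, log loss, counts, normalized confusion, histories)
#' are emitted machine-readably; re-loading reproduces them exactly.
#'
#' @param report An [eval_report()].
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  ser <- list(split = report$split, n = report$n, targets = list())
  for (tg in names(report$targets)) {
    t <- report$targets[[tg]]
    ser$targets[[tg]] <- list(
      accuracy = t$accuracy, log_loss = t$log_loss,
      model_kind = t$model_kind,
      classes = t$confusion$classes,
      counts = t$confusion$counts,
      row_normalized = t$confusion$row_normalized,
      history = t$history)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Plot per-epoch training curves of an MLP model
#'
#' Training loss, validation loss and validation accuracy against epoch, the
#' standard learning-curve diagnostic for the early-stopping behavior.
#'
#' @param model A `fitted_model` of kind `"mlp"` (or an `eval_report` target
#'   entry with a history).
#' @return A ggplot object.
#' @export
plot_history <- function(model) {
  history <- if (inherits(model, "fitted_model")) model$history else model$history
  if (is.null(history)) stop_contract("model has no training history")
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss, series = "training loss"),
    data.frame(epoch = history$epoch, value = history$val_loss, series = "validation loss"),
    data.frame(epoch = history$epoch, value = history$val_accuracy, series = "validation accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
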