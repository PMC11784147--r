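# PLS-DA: partial least squares regression on one-hot class indicators,
# classified by argmax of the predicted indicator scores. The latent
# directions are computed with the SIMPLS algorithm (de Jong 1993,
# Chemometrics Intell. Lab. Syst. 18:251-263), which deflates the p x C
# cross-product matrix instead of the data matrix and so scales to the
# 150/300-component fits used per target.

#' Per-target model specification
#'
#' One classifier is fitted per target -- bread, butter, filling -- never a
#' joint multi-output model, so the confusion-matrix evaluation stays
#' interpretable per sandwich component. PLS-DA component counts default to
#' 150 (bread), 150 (butter) and 300 (filling).
#'
#' @param name One of `"bread"`, `"butter"`, `"filling"`.
#' @return A `target_spec` with `name`, `classes`, `plsda_components`.
#' @export
target_spec <- function(name = c("bread", "butter", "filling")) {
  name <- match.arg(name)
  classes <- switch(name, bread = bread_levels, butter = butter_levels,
                    filling = filling_levels)
  ncomp <- switch(name, bread = 150L, butter = 150L, filling = 300L)
  structure(list(name = name, classes = classes, plsda_components = ncomp),
            class = "target_spec")
}

# SIMPLS core on centered X (n x p) and centered indicator Y (n x C).
simpls <- function(X, Y, ncomp) {
  n <- nrow(X); p <- ncol(X); C <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  X0 <- sweep(X, 2L, x_mean)
  Y0 <- sweep(Y, 2L, y_mean)
  S <- crossprod(X0, Y0)                      # p x C
  d0 <- svd(S, nu = 0L, nv = 0L)$d[1L]
  R <- matrix(0, p, ncomp)
  Q <- matrix(0, C, ncomp)
  V <- matrix(0, p, ncomp)
  a_eff <- 0L
  for (a in seq_len(ncomp)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (sv$d[1L] < 1e-12 * d0) break          # predictive rank exhausted
    r <- sv$u[, 1L]
    t_sc <- X0 %*% r
    normt <- sqrt(sum(t_sc^2))
    if (normt < 1e-12) break
    t_sc <- t_sc / normt
    r <- r / normt
    p_load <- crossprod(X0, t_sc)
    q_load <- crossprod(Y0, t_sc)
    v <- p_load
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, p_load)
    }
    vn <- sqrt(sum(v^2))
    if (vn < 1e-12) break
    v <- v / vn
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- q_load; V[, a] <- v
    a_eff <- a
  }
  if (a_eff == 0L) stop_contract("no predictive PLS component could be extracted")
  R <- R[, seq_len(a_eff), drop = FALSE]
  Q <- Q[, seq_len(a_eff), drop = FALSE]
  B <- R %*% t(Q)                             # p x C coefficients on centered data
  list(coef = B, x_mean = x_mean, y_mean = y_mean, ncomp = a_eff)
}

#' Train a PLS-DA classifier
#'
#' @param X Feature matrix (rows = samples).
#' @param y Class labels (at least 2 classes present).
#' @param spec A [target_spec()], or `NULL` with `ncomp` given directly.
#' @param ncomp Number of latent components; capped at `min(n - 1, p)` with a
#'   warning when the request exceeds what the data can support (as the
#'   300-component filling model does on 426 features).
#' @return A `fitted_model` of kind `"plsda"`.
#' @export
train_plsda <- function(X, y, spec = NULL, ncomp = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- if (!is.null(spec)) spec$classes else sort(unique(y))
  classes <- classes[classes %in% y]
  if (length(classes) < 2L)
    stop_contract("PLS-DA needs at least 2 classes present, got ", length(classes))
  ncomp <- ncomp %||% spec$plsda_components
  cap <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > cap) {
    warning("requested ", ncomp, " components exceeds data capacity; capped at ", cap)
    ncomp <- cap
  }
  fit <- simpls(X, one_hot(y, classes), ncomp)
  structure(list(kind = "plsda", target = spec$name %||% NA_character_,
                 classes = classes, fit = fit, n_features = ncol(X),
                 hyperparameters = list(ncomp = fit$ncomp)),
            class = "fitted_model")
}

# Predicted indicator scores for new data.
plsda_scores <- function(model, X) {
  X0 <- sweep(as.matrix(X), 2L, model$fit$x_mean)
  sc <- sweep(X0 %*% model$fit$coef, 2L, model$fit$y_mean, `+`)
  colnames(sc) <- model$classes
  sc
}
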