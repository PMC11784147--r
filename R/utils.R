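# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages (endmember library, scene noise, split assignment,
#' cross-validation folds, network initialization) draw their own seed from a
#' single master seed plus a string tag, so adding stages or images never
#' perturbs the random stream of earlier ones.
#'
#' @param seed Master seed (integer).
#' @param ... Character or numeric tags identifying the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste0(as.character(x), collapse = "|"),
                       character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tags)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Row-wise softmax with max-subtraction for numerical stability.
softmax <- function(scores) {
  scores <- as.matrix(scores)
  e <- exp(scores - apply(scores, 1L, max))
  e / rowSums(e)
}

# 0/1 indicator matrix, one column per class level (in the given order).
one_hot <- function(y, classes = levels(factor(y))) {
  y <- as.character(y)
  out <- matrix(0, length(y), length(classes),
                dimnames = list(NULL, classes))
  out[cbind(seq_along(y), match(y, classes))] <- 1
  out
}

# Stratified k-fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so fold sizes per class differ by at most one.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(...) stop(errorCondition(paste0(...), class = c("hsi_dimension_error", "hsi_error")))
stop_contract <- function(...) stop(errorCondition(paste0(...), class = c("hsi_contract_error", "hsi_error")))
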