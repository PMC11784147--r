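# Demonstration utilities for the two design safeguards of the sampling
# scheme: partition-level splitting (against spatial interdependency) and
# SNV (against per-pixel scatter).

# 1-nearest-neighbor accuracy on a stratified subsample; the most
# leakage-sensitive classifier, since it can match a test pixel to a
# spatially adjacent training pixel sharing correlated noise.
nn1_accuracy <- function(Xtr, ytr, Xte, yte) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) - 2 * Xte %*% t(Xtr)
  pred <- ytr[apply(d2, 1L, which.min)]
  mean(pred == yte)
}

#' Quantify train/test leakage from pixel-level versus partition-level splits
#'
#' Builds one simulated study twice from the same cubes: once with the
#' design's partition-level train/test assignment, and once with a random
#' pixel-level 70/30 split that ignores partitions. A 1-nearest-neighbor
#' classifier on the filling target is evaluated on both. On spatially
#' correlated scenes the pixel-level split lets test pixels borrow
#' information from adjacent training pixels, inflating its accuracy; the
#' gap measures the interdependency the partition design removes.
#'
#' @param params Scene parameters (default [ci_scene_params()]).
#' @param seed Master seed.
#' @param target Target column to classify (default `"filling"`).
#' @param n_train,n_test Subsample sizes for the 1-NN evaluation.
#' @return List with `partition_accuracy`, `pixel_accuracy`, `gap`.
#' @export
split_leakage_demo <- function(params = ci_scene_params(), seed = 1L,
                               target = "filling", n_train = 3000L,
                               n_test = 1200L) {
  lib <- make_endmember_library(derive_seed(seed, "library"))
  cubes <- simulate_study(params, seed, lib)
  st <- build_dataset(cubes, seed = seed)
  rm(cubes)
  y <- st$meta[[target]]
  n <- nrow(st$features)

  eval_split <- function(is_train, sub_seed) {
    with_seed(sub_seed, {
      tr <- sample(which(is_train), min(n_train, sum(is_train)))
      te <- sample(which(!is_train), min(n_test, sum(!is_train)))
      nn1_accuracy(st$features[tr, , drop = FALSE], y[tr],
                   st$features[te, , drop = FALSE], y[te])
    })
  }
  part_acc <- eval_split(st$meta$split == "train", derive_seed(seed, "sub_part"))
  pixel_train <- with_seed(derive_seed(seed, "pixel_split"),
                           seq_len(n) %in% sample.int(n, round(0.7 * n)))
  pix_acc <- eval_split(pixel_train, derive_seed(seed, "sub_pix"))
  list(partition_accuracy = part_acc, pixel_accuracy = pix_acc,
       gap = pix_acc - part_acc)
}
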