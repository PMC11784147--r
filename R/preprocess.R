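# Per-spectrum preprocessing: Standard Normal Variate scatter correction
# followed by finite-difference derivative features. A 108-band spectrum maps
# to 108 + 107 + 106 + 105 = 426 features; the unpadded-difference scheme is
# the only simple one consistent with that width.

N_BANDS <- 108L
N_FEATURES <- 426L

#' Standard Normal Variate transform of one spectrum
#'
#' Subtracts the spectrum mean and divides by its sample (n-1) standard
#' deviation, removing per-pixel multiplicative and additive scatter: the
#' output is invariant under `a * s + b` for any `a > 0`.
#'
#' @param s Numeric vector, length >= 2, non-constant.
#' @return Transformed spectrum with mean 0 and sample sd 1.
#' @export
snv <- function(s) {
  if (length(s) < 2L) stop_contract("SNV needs at least 2 bands")
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0)
    stop(errorCondition("degenerate (constant) spectrum: SNV undefined",
                        class = c("hsi_degenerate_spectrum", "hsi_error")))
  (s - mean(s)) / sdv
}

#' Derivative feature vector of a 108-band spectrum
#'
#' Appends unpadded first, second and third successive differences to the
#' spectrum: blocks of length 108, 107, 106 and 105, totalling 426 features.
#' Differences are unit-step (not divided by band spacing); the wavelength
#' grid is nearly uniform and downstream classifiers are scale-equivariant.
#'
#' @param s Numeric vector of length 108.
#' @return Named numeric vector of length 426 with a `block_index` attribute
#'   giving the 1-based start offset of each block.
#' @export
derivative_features <- function(s) {
  if (length(s) != N_BANDS)
    stop_dim("derivative features are defined for ", N_BANDS, "-band spectra, got ", length(s))
  d1 <- diff(s)
  d2 <- diff(d1)
  d3 <- diff(d2)
  out <- c(s, d1, d2, d3)
  names(out) <- feature_names()
  attr(out, "block_index") <- c(spectrum = 1L, d1 = 109L, d2 = 216L, d3 = 322L)
  out
}

#' Feature column names for the 426-dimensional vector
#' @return Character vector `b000..b107, d1_000.., d2_000.., d3_000..`.
#' @export
feature_names <- function() {
  c(sprintf("b%03d", 0:107), sprintf("d1_%03d", 0:106),
    sprintf("d2_%03d", 0:105), sprintf("d3_%03d", 0:104))
}

#' Full per-pixel preprocessing: SNV then derivative features
#'
#' @param s Numeric vector of length 108.
#' @return Length-426 feature vector; inherits SNV's invariance to positive
#'   affine transforms of the input.
#' @export
preprocess_pixel <- function(s) derivative_features(snv(s))

#' Vectorized preprocessing of a spectra matrix
#'
#' @param m Numeric matrix, one spectrum per row (108 columns).
#' @param snv Apply the SNV transform first (default `TRUE`); disabling it is
#'   provided for sensitivity checks on the scatter-correction step.
#' @return Matrix with 426 columns named as in [feature_names()].
#' @export
preprocess_matrix <- function(m, snv = TRUE) {
  m <- as.matrix(m)
  if (ncol(m) != N_BANDS)
    stop_dim("expected ", N_BANDS, " bands per row, got ", ncol(m))
  if (snv) {
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    if (any(sdv == 0))
      stop(errorCondition(
        paste0("degenerate (constant) spectrum in row(s) ",
               paste(utils::head(which(sdv == 0), 5L), collapse = ", ")),
        class = c("hsi_degenerate_spectrum", "hsi_error")))
    m <- (m - mu) / sdv
  }
  d1 <- m[, -1L, drop = FALSE] - m[, -N_BANDS, drop = FALSE]
  d2 <- d1[, -1L, drop = FALSE] - d1[, -ncol(d1), drop = FALSE]
  d3 <- d2[, -1L, drop = FALSE] - d2[, -ncol(d2), drop = FALSE]
  out <- cbind(m, d1, d2, d3)
  colnames(out) <- feature_names()
  out
}
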