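# Shared fixtures and independent oracles, built in code at test time.

# Small cube with reproducible values on an arbitrary wavelength axis.
tiny_cube <- function(n = 8L, m = 6L, nb = 5L, seed = 42L, kind = "reflectance",
                      wl = seq(1100, by = 10, length.out = nb)) {
  set.seed(seed)
  hypercube(array(runif(n * m * nb, 0.05, 0.95), c(n, m, nb)), wl, kind)
}

# Cube on the full 108-band study axis.
study_cube <- function(n = 120L, m = 220L, seed = 42L) {
  set.seed(seed)
  hypercube(array(runif(n * m * 108L, 0.05, 0.95), c(n, m, 108L)),
            study_wavelengths(), "reflectance")
}

# Scalar-loop oracle for the two-point reflectance calibration.
calibrate_oracle <- function(raw, white, dark, r_white = 0.95, r_dark = 0.02) {
  out <- raw
  for (i in seq_along(raw)) {
    out[i] <- r_dark + (r_white - r_dark) * (raw[i] - dark[i]) / (white[i] - dark[i])
    out[i] <- min(max(out[i], 1e-6), 1)
  }
  out
}

# Index-loop oracle for the derivative feature blocks.
derivative_oracle <- function(s) {
  L <- length(s)
  d1 <- numeric(L - 1); d2 <- numeric(L - 2); d3 <- numeric(L - 3)
  for (i in seq_len(L - 1)) d1[i] <- s[i + 1] - s[i]
  for (i in seq_len(L - 2)) d2[i] <- d1[i + 1] - d1[i]
  for (i in seq_len(L - 3)) d3[i] <- d2[i + 1] - d2[i]
  c(s, d1, d2, d3)
}

# Per-class TP/TN/FP/FN tally, brute force.
eq1_macro_average <- function(y_true, y_pred, classes) {
  n <- length(y_true)
  vals <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    (tp + tn) / (tp + tn + fp + fn)
  }, numeric(1))
  mean(vals)
}

# Noise-free study scene (all stochastic components off).
noiseless_params <- function(dims = c(12L, 10L, 108L)) {
  ci_scene_params(mult_sd = 0, add_sd = 0, spatial_sd = 0, noise_sd = 0,
                  dims = dims)
}
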