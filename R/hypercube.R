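# Hypercube data model: a (n, m, lambda) array of per-pixel spectra, with the
# wavelength axis carried as metadata. n indexes image width (the axis the
# artifact crop acts on), m image length, lambda the spectral bands.

#' Construct a hypercube
#'
#' @param data 3-D numeric array with dimensions `(n, m, lambda)`: width,
#'   length, spectral bands.
#' @param wavelengths Strictly increasing numeric vector of band centers in
#'   nm; length must equal `dim(data)[3]`.
#' @param value_kind One of `"raw"` (detector counts), `"reflectance"`
#'   (fraction in `(0, 1]`), `"absorbance"` (`log10(1/R)`).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, value_kind = c("raw", "reflectance", "absorbance")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_dim("hypercube data must be a 3-D array, got dimensions (",
             paste(dim(data), collapse = ", "), ")")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop_dim("wavelength vector has length ", length(wavelengths),
             " but data has ", dim(data)[3L], " bands")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop_contract("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, value_kind = value_kind),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hypercube> (%d, %d, %d) %s, %.2f-%.2f nm\n",
              d[1], d[2], d[3], x$value_kind,
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' The study wavelength axis: 108 bands spanning 1116.14 to 1670.62 nm
#' @return Numeric vector of length 108.
#' @export
study_wavelengths <- function() seq(1116.14, 1670.62, length.out = 108L)

#' Pair of white/dark reference cubes for reflectance calibration
#'
#' The white target reflects 95% of incident light and the dark target absorbs
#' 98% (reflects 2%), so calibration maps raw counts onto the `[0.02, 0.95]`
#' reflectance interval rather than an idealized `[0, 1]`.
#'
#' @param white,dark Raw-count hypercubes of the reference targets, same dims.
#' @param r_white,r_dark True reflectance fractions of the targets.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark, r_white = 0.95, r_dark = 0.02) {
  stopifnot(inherits(white, "hypercube"), inherits(dark, "hypercube"))
  if (!identical(dim(white), dim(dark)))
    stop_dim("white and dark reference cubes must share dimensions")
  if (r_white <= r_dark) stop_contract("r_white must exceed r_dark")
  structure(list(white = white, dark = dark, r_white = r_white, r_dark = r_dark),
            class = "reference_pair")
}

#' Two-point reflectance calibration against white/dark references
#'
#' Linear per-pixel, per-band correction mapping the dark reference to its
#' true reflectance (default 0.02) and the white reference to its true
#' reflectance (default 0.95):
#' `R = r_dark + (r_white - r_dark) * (raw - dark) / (white - dark)`,
#' clipped to `[1e-6, 1]`.
#'
#' @param raw Hypercube with `value_kind == "raw"`.
#' @param refs A [reference_pair()].
#' @return Reflectance hypercube.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_pair"))
  if (raw$value_kind != "raw")
    stop_contract("calibrate_reflectance expects raw counts, got ", raw$value_kind)
  if (!identical(dim(raw), dim(refs$white)))
    stop_dim("raw cube and reference cubes must share dimensions")
  denom <- refs$white$data - refs$dark$data
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3L, any))
    stop_contract("degenerate references (white <= dark) in band(s) ",
                  paste(bad, collapse = ", "))
  }
  r <- refs$r_dark + (refs$r_white - refs$r_dark) * (raw$data - refs$dark$data) / denom
  r <- pmin(pmax(r, 1e-6), 1)
  hypercube(r, raw$wavelengths, "reflectance")
}

#' Convert reflectance to absorbance, `A = log10(1/R)`
#'
#' Non-positive reflectance values are clipped at `1e-6` with a warning rather
#' than producing infinities.
#'
#' @param cube Reflectance hypercube with values in `(0, 1]`.
#' @return Absorbance hypercube.
#' @export
to_absorbance <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$value_kind != "reflectance")
    stop_contract("to_absorbance expects reflectance, got ", cube$value_kind)
  r <- cube$data
  if (any(r <= 0)) {
    warning("clipping ", sum(r <= 0), " non-positive reflectance value(s) at 1e-6")
    r <- pmax(r, 1e-6)
  }
  hypercube(log10(1 / r), cube$wavelengths, "absorbance")
}

# Centered window along one axis: 0-based offset floor((size - target)/2).
center_window <- function(size, target) {
  off <- (size - target) %/% 2L
  seq.int(off + 1L, off + target)
}

#' Discard camera artifact margins by center-cropping the width axis
#'
#' Captured cubes carry artifacts on the outer columns of the width (n) axis;
#' the central `width` columns are retained as a pure slice (no resampling).
#'
#' @param cube Hypercube with `n >= width`.
#' @param width Number of columns to keep (default 350).
#' @return Cropped hypercube, `(width, m, lambda)`.
#' @export
crop_artifacts <- function(cube, width = 350L) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube)
  if (d[1L] < width)
    stop_dim("cannot crop width ", d[1L], " to ", width)
  hypercube(cube$data[center_window(d[1L], width), , , drop = FALSE],
            cube$wavelengths, cube$value_kind)
}

#' Select the central region of interest
#'
#' A centered `(rows, cols)` spatial window over all bands, with 0-based
#' offsets `floor((dim - target)/2)` on each axis.
#'
#' @param cube Hypercube with spatial dims at least `(rows, cols)`.
#' @param rows,cols ROI size (default `100 x 200`).
#' @return ROI hypercube, `(rows, cols, lambda)`.
#' @export
select_roi <- function(cube, rows = 100L, cols = 200L) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube)
  if (d[1L] < rows || d[2L] < cols)
    stop_dim("cube (", d[1L], ", ", d[2L], ") smaller than ROI (", rows, ", ", cols, ")")
  hypercube(cube$data[center_window(d[1L], rows), center_window(d[2L], cols), , drop = FALSE],
            cube$wavelengths, cube$value_kind)
}
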