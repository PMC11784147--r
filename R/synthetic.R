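# Synthetic sandwich scenes: depth-weighted linear mixtures of ingredient
# endmembers under per-pixel multiplicative/additive scatter (spatially
# correlated) and iid sensor noise. The generator reproduces the statistical
# structure the analysis pipeline assumes -- scatter that SNV removes,
# spatial correlation that partition-level splitting guards against, and
# confusable "low fat"/"low sugar" variants that make the filling target the
# hardest -- not the radiometry of a real SWIR camera.

#' Scene parameters for the synthetic generator
#'
#' Defaults encode the study conditions: the bread layer dominates the signal
#' (weight 0.65), butter is intermediate (0.20) and the filling, lying under
#' a bread slice, is weakest (0.15). Scatter fields are spatially correlated
#' at 6 px -- just above the 5-px spacing of selected sample pixels, so
#' neighboring samples within a partition remain correlated.
#'
#' @param w_bread,w_butter,w_filling Positive layer weights, sum <= 1, with
#'   bread > butter > filling.
#' @param mult_sd Sd of the multiplicative scatter field (unitless gain).
#' @param add_sd Sd of the additive offset field (reflectance units).
#' @param corr_length Correlation length of all correlated fields, in px
#'   (>= 1).
#' @param spatial_sd Sd of the band-structured spatially correlated noise
#'   (reflectance units). Unlike the two scatter fields, which act uniformly
#'   across bands and are removed by SNV, this component perturbs the
#'   spectral shape itself and is only mitigated by keeping spatial
#'   neighbors out of opposite splits.
#' @param n_spatial Number of independent band patterns in that component.
#' @param noise_sd Sd of iid per-voxel noise (reflectance units).
#' @param dims Cube dimensions `(n, m, lambda)`; default full capture size
#'   `(640, 512, 108)`.
#' @return A `scene_params` list.
#' @export
scene_params <- function(w_bread = 0.65, w_butter = 0.20, w_filling = 0.15,
                         mult_sd = 0.12, add_sd = 0.03, corr_length = 6,
                         spatial_sd = 0.05, n_spatial = 4L,
                         noise_sd = 0.025, dims = c(640L, 512L, 108L)) {
  w <- c(w_bread, w_butter, w_filling)
  if (any(w <= 0) || sum(w) > 1 + 1e-12)
    stop(errorCondition("layer weights must be positive with sum <= 1",
                        class = c("hsi_parameter_error", "hsi_error")))
  if (!(w_bread > w_butter && w_butter > w_filling))
    stop(errorCondition("depth ordering requires w_bread > w_butter > w_filling",
                        class = c("hsi_parameter_error", "hsi_error")))
  if (corr_length < 1) stop(errorCondition("corr_length must be >= 1",
                                           class = c("hsi_parameter_error", "hsi_error")))
  structure(list(w_bread = w_bread, w_butter = w_butter, w_filling = w_filling,
                 mult_sd = mult_sd, add_sd = add_sd, corr_length = corr_length,
                 spatial_sd = spatial_sd, n_spatial = as.integer(n_spatial),
                 noise_sd = noise_sd, dims = as.integer(dims)),
            class = "scene_params")
}

#' Reduced-size scene preset for fast end-to-end runs
#'
#' Same noise structure as the default scene but a `(120, 220, 108)` cube:
#' large enough for the artifact-free ROI path, small enough that a full
#' 24-cube study simulates in seconds.
#'
#' @param ... Overrides passed to [scene_params()].
#' @export
ci_scene_params <- function(...) {
  args <- list(...)
  args$dims <- args$dims %||% c(120L, 220L, 108L)
  do.call(scene_params, args)
}

# One endmember: baseline reflectance minus K Gaussian absorption dips.
gaussian_dips <- function(wl, centers, widths, depths, base) {
  r <- rep(base, length(wl))
  for (k in seq_along(centers))
    r <- r - depths[k] * exp(-((wl - centers[k])^2) / (2 * widths[k]^2))
  pmin(pmax(r, 1e-3), 1)
}

#' Deterministic library of ingredient endmember spectra
#'
#' Nine endmembers on the 108-band study axis: two breads (differing in
#' baseline level and absorption-feature placement), one butter (with a
#' strong fat absorption dip near 1210 nm), and six fillings. The "low fat"
#' and "low sugar" variants share their parent's feature centers and widths
#' and differ only in dip depths (factor `variant_factor`), deliberately
#' making those pairs the confusable, hardest classes.
#'
#' @param seed Library seed; the same seed always yields the same library.
#' @param variant_factor Depth scaling of the low-fat / low-sugar variants.
#' @return Named list of endmembers (`bread: white`, `bread: whole wheat`,
#'   `butter`, and the six filling levels), each with `spectrum`, `centers`,
#'   `widths`, `depths`, `base`.
#' @export
make_endmember_library <- function(seed = 1L, variant_factor = 0.6) {
  wl <- study_wavelengths()
  draw <- function(tag, n, base_rng, depth_rng) {
    with_seed(derive_seed(seed, "endmember", tag), {
      list(centers = runif(n, min(wl) + 30, max(wl) - 30),
           widths = runif(n, 18, 45),
           depths = runif(n, depth_rng[1], depth_rng[2]),
           base = runif(1, base_rng[1], base_rng[2]))
    })
  }
  mk <- function(name, pars) {
    c(list(name = name, spectrum = gaussian_dips(wl, pars$centers, pars$widths,
                                                 pars$depths, pars$base)), pars)
  }
  variant <- function(name, parent) {
    pars <- parent[c("centers", "widths", "depths", "base")]
    pars$depths <- pars$depths * variant_factor
    mk(name, pars)
  }
  lib <- list()
  # breads carry fixed characteristic bands (starch-like for white, bran- and
  # fiber-like for whole wheat) plus one drawn dip, so the top layer is
  # reliably the most distinguishable pair regardless of the library seed
  bw <- draw("bread_white", 1L, c(0.58, 0.66), c(0.10, 0.18))
  bw$centers <- c(1190, 1440, bw$centers)
  bw$widths <- c(30, 40, bw$widths)
  bw$depths <- c(0.12, 0.16, bw$depths)
  lib[["bread: white"]] <- mk("bread: white", bw)
  ww <- draw("bread_wheat", 1L, c(0.42, 0.50), c(0.10, 0.18))
  ww$centers <- c(1310, 1580, ww$centers)
  ww$widths <- c(35, 35, ww$widths)
  ww$depths <- c(0.14, 0.14, ww$depths)
  lib[["bread: whole wheat"]] <- mk("bread: whole wheat", ww)
  # butter: fixed strong fat band near 1210 nm plus one drawn secondary dip
  bu <- draw("butter", 1L, c(0.50, 0.58), c(0.10, 0.16))
  bu$centers <- c(1210, bu$centers)
  bu$widths <- c(25, bu$widths)
  bu$depths <- c(0.30, bu$depths)
  lib[["butter"]] <- mk("butter", bu)
  parents <- list("mature cheese" = "cheese", "jelly" = "jelly",
                  "peanut butter" = "peanut", "chocolate sprinkles" = "choco")
  for (nm in names(parents))
    lib[[nm]] <- mk(nm, draw(parents[[nm]], 3L, c(0.45, 0.58), c(0.08, 0.16)))
  lib[["low fat mature cheese"]] <- variant("low fat mature cheese", lib[["mature cheese"]])
  lib[["low sugar jelly"]] <- variant("low sugar jelly", lib[["jelly"]])
  lib[order(match(names(lib), c("bread: white", "bread: whole wheat", "butter", filling_levels)))]
}

# Spatially correlated zero-mean Gaussian field: white noise smoothed with a
# separable Gaussian kernel (truncated at 3 correlation lengths), rescaled so
# the realized field sd matches `sd`.
smooth_field <- function(n, m, corr_length, sd) {
  w <- matrix(stats::rnorm(n * m), n, m)
  if (corr_length > 1) {
    half <- max(1L, ceiling(3 * corr_length))
    kern1 <- function(size) {
      k <- matrix(0, size, size)
      for (i in seq_len(size)) {
        g <- exp(-((seq_len(size) - i)^2) / (2 * corr_length^2))
        g[abs(seq_len(size) - i) > half] <- 0
        k[i, ] <- g / sum(g)
      }
      k
    }
    w <- kern1(n) %*% w %*% t(kern1(m))
  }
  s <- stats::sd(as.vector(w))
  if (s > 0) w * (sd / s) else w
}

# Noise-free mixture spectrum for one grid label.
mixture_spectrum <- function(label, params, library) {
  bread_key <- paste0("bread: ", label$bread)
  m <- params$w_bread * library[[bread_key]]$spectrum +
    params$w_filling * library[[label$filling]]$spectrum
  if (label$butter == "yes") m <- m + params$w_butter * library[["butter"]]$spectrum
  m
}

#' Simulate one sandwich hypercube
#'
#' Every pixel carries the same depth-weighted ingredient mixture
#' `w_b * E_bread + w_u * E_butter * [butter] + w_f * E_filling`, perturbed by
#' `(1 + mult field)` gain, an additive offset field, a band-structured
#' spatially correlated noise term (`n_spatial` smooth band patterns, each
#' modulated by its own correlated field), and iid voxel noise. All fields
#' are spatially correlated at `corr_length`; every noise term has zero
#' mean, so the expected pixel spectrum is exactly the noiseless mixture.
#'
#' @param label A one-row grid data.frame (see [parse_label()]) or a grid
#'   code such as `"A1"`.
#' @param params A [scene_params()].
#' @param seed Cube seed (reproducible).
#' @param library Endmember library; default [make_endmember_library()] with
#'   seed 1.
#' @return Reflectance [hypercube()] of dimensions `params$dims`.
#' @export
simulate_sandwich_cube <- function(label, params = scene_params(), seed = 1L,
                                   library = make_endmember_library()) {
  if (is.character(label)) {
    grid <- sandwich_grid()
    label <- grid[grid$code == label, , drop = FALSE]
    if (nrow(label) != 1L) stop_contract("unknown grid code")
  }
  stopifnot(inherits(params, "scene_params"))
  n <- params$dims[1L]; m <- params$dims[2L]; nb <- params$dims[3L]
  mix <- mixture_spectrum(label, params, library)
  stopifnot(length(mix) == nb)
  data <- with_seed(seed, {
    gain <- 1 + smooth_field(n, m, params$corr_length, params$mult_sd)
    offset <- smooth_field(n, m, params$corr_length, params$add_sd)
    # (n*m) x nb outer product: rows are pixels, columns bands
    mat <- as.vector(gain) %o% mix + as.vector(offset)
    if (params$spatial_sd > 0 && params$n_spatial > 0L) {
      for (k in seq_len(params$n_spatial)) {
        # smooth unit-sd band pattern: shape noise SNV cannot remove
        u <- stats::filter(stats::rnorm(nb + 20L), rep(1 / 7, 7), sides = 2L)
        u <- u[11:(nb + 10L)]
        u <- (u - mean(u)) / stats::sd(u)
        f <- smooth_field(n, m, params$corr_length, params$spatial_sd)
        mat <- mat + as.vector(f) %o% u
      }
    }
    if (params$noise_sd > 0)
      mat <- mat + stats::rnorm(length(mat), sd = params$noise_sd)
    mat
  })
  data <- pmin(pmax(data, 1e-6), 1)
  hypercube(array(data, dim = c(n, m, nb)), study_wavelengths(), "reflectance")
}

#' Simulate the full 24-sandwich study
#'
#' One cube per grid cell A1..F4, each independently seeded from the master
#' seed, with filenames `sandwich_<code>.hdr` carrying the grid code.
#'
#' @param params A [scene_params()]; use [ci_scene_params()] for fast runs.
#' @param seed Master seed.
#' @param library Endmember library shared by all cubes.
#' @param handler Optional `function(filename, cube)` called per cube (for
#'   streaming full-size studies without holding 24 cubes in memory); when
#'   given, cubes are not retained.
#' @return Named list of 24 hypercubes (or, with `handler`, the character
#'   vector of filenames, invisibly).
#' @export
simulate_study <- function(params = ci_scene_params(), seed = 1L,
                           library = make_endmember_library(), handler = NULL) {
  grid <- sandwich_grid()
  filenames <- paste0("sandwich_", grid$code, ".hdr")
  if (is.null(handler)) {
    cubes <- vector("list", nrow(grid))
    names(cubes) <- filenames
    for (i in seq_len(nrow(grid)))
      cubes[[i]] <- simulate_sandwich_cube(grid[i, ], params,
                                           derive_seed(seed, "cube", grid$code[i]),
                                           library)
    cubes
  } else {
    for (i in seq_len(nrow(grid)))
      handler(filenames[i],
              simulate_sandwich_cube(grid[i, ], params,
                                     derive_seed(seed, "cube", grid$code[i]),
                                     library))
    invisible(filenames)
  }
}
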