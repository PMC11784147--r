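# Spatial subsampling against pixel interdependency: each 100 x 200 ROI is
# tiled into ten 50 x 40 partitions, partitions (never pixels) are assigned
# wholly to train or test at a 7/3 ratio, and one pixel per 5 x 5 sub-grid
# (its center) is kept, giving 80 samples per partition and 800 per image.

#' Class level orders used throughout (confusion-table convention)
#' @name class_levels
#' @export
bread_levels <- c("white", "whole wheat")

#' @rdname class_levels
#' @export
butter_levels <- c("no", "yes")

#' @rdname class_levels
#' @export
filling_levels <- c("mature cheese", "low fat mature cheese", "jelly",
                    "low sugar jelly", "peanut butter", "chocolate sprinkles")

#' The 24-cell sandwich assembly grid
#'
#' Codes A1..F4: the letter selects the filling (A mature cheese, B low fat
#' mature cheese, C jelly, D low sugar jelly, E peanut butter, F chocolate
#' sprinkles) and the digit the bread/butter combination (1 white/no butter,
#' 2 white/butter, 3 whole wheat/no butter, 4 whole wheat/butter).
#'
#' @return A data.frame with columns `code`, `filling`, `bread`, `butter`.
#' @export
sandwich_grid <- function() {
  letters6 <- LETTERS[1:6]
  grid <- expand.grid(digit = 1:4, letter = letters6,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    code = paste0(grid$letter, grid$digit),
    filling = filling_levels[match(grid$letter, letters6)],
    bread = bread_levels[ifelse(grid$digit <= 2L, 1L, 2L)],
    butter = butter_levels[ifelse(grid$digit %% 2L == 1L, 1L, 2L)],
    stringsAsFactors = FALSE)
}

#' Parse a sandwich label from a hypercube filename
#'
#' The filename must contain exactly one grid code (`A`-`F` followed by
#' `1`-`4`); the matching grid row supplies the bread, butter and filling
#' ground truth.
#'
#' @param filename Character scalar.
#' @return One-row data.frame (`code`, `filling`, `bread`, `butter`).
#' @export
parse_label <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L)
  hits <- regmatches(filename, gregexpr("[A-F][1-4]", filename))[[1]]
  if (length(hits) != 1L)
    stop(errorCondition(
      paste0("expected exactly one grid code in '", filename, "', found ",
             length(hits)),
      class = c("hsi_label_error", "hsi_error")))
  grid <- sandwich_grid()
  grid[grid$code == hits, , drop = FALSE]
}

#' Tile a 100 x 200 ROI into ten 50 x 40 partitions
#'
#' Row-major 2 x 5 tiling: partition 1 covers rows 1-50, cols 1-40; partition
#' 10 covers rows 51-100, cols 161-200. The tiling is exact (no gaps, no
#' overlap).
#'
#' @param roi Hypercube with spatial dims exactly `(100, 200)`.
#' @return List of 10 partitions, each `list(index, rows, cols)`.
#' @export
partition_roi <- function(roi) {
  stopifnot(inherits(roi, "hypercube"))
  d <- dim(roi)
  if (d[1L] != 100L || d[2L] != 200L)
    stop_dim("partitioning expects a (100, 200) ROI, got (", d[1L], ", ", d[2L], ")")
  parts <- vector("list", 10L)
  k <- 0L
  for (rb in 0:1) {
    for (cb in 0:4) {
      k <- k + 1L
      parts[[k]] <- list(index = k,
                         rows = (rb * 50L + 1L):(rb * 50L + 50L),
                         cols = (cb * 40L + 1L):(cb * 40L + 40L))
    }
  }
  parts
}

#' Assign the 10 partitions of one image to train/test at a 7/3 split
#'
#' Exactly 7 train and 3 test partitions are drawn uniformly at random,
#' deterministic in the seed. Exact 7/3 (rather than independent 70%
#' Bernoulli draws) is what makes the study totals 13,440 / 5,760 exact.
#'
#' @param partitions Output of [partition_roi()] (length 10).
#' @param seed Integer seed for this image's assignment.
#' @return Same list with a `split` element (`"train"` or `"test"`) added.
#' @export
assign_split <- function(partitions, seed) {
  if (length(partitions) != 10L)
    stop_contract("expected 10 partitions per image, got ", length(partitions))
  train_idx <- with_seed(seed, sample.int(10L, 7L))
  for (k in seq_along(partitions))
    partitions[[k]]$split <- if (k %in% train_idx) "train" else "test"
  partitions
}

#' Extract the 5 x 5 sub-grid center pixels of one partition
#'
#' The 50 x 40 partition tiles into 10 x 8 = 80 sub-grids of 5 x 5 pixels;
#' the central pixel of each (offset +2, +2, 0-based) is kept, so selected
#' pixels are 5 px apart and carry one spectrum each.
#'
#' @param partition One element of [partition_roi()] output.
#' @param cube The ROI hypercube the partition indexes into.
#' @return List with `coords` (80 x 2 matrix of ROI row/col) and `spectra`
#'   (80 x lambda matrix).
#' @export
extract_grid_centers <- function(partition, cube) {
  stopifnot(inherits(cube, "hypercube"))
  nr <- length(partition$rows)
  nc <- length(partition$cols)
  if (nr %% 5L != 0L || nc %% 5L != 0L)
    stop_dim("partition dims (", nr, ", ", nc, ") not divisible by 5")
  centers_r <- partition$rows[seq(3L, nr, by = 5L)]
  centers_c <- partition$cols[seq(3L, nc, by = 5L)]
  coords <- as.matrix(expand.grid(row = centers_r, col = centers_c,
                                  KEEP.OUT.ATTRS = FALSE))
  nb <- dim(cube)[3L]
  spectra <- matrix(NA_real_, nrow(coords), nb)
  for (i in seq_len(nrow(coords)))
    spectra[i, ] <- cube$data[coords[i, 1L], coords[i, 2L], ]
  list(coords = coords, spectra = spectra)
}

#' Build the sample table from a set of labelled hypercubes
#'
#' Composes the full extraction pipeline per cube: (optional) absorbance
#' conversion, artifact crop (when the cube is wider than 350 px), central
#' ROI selection, partition tiling, seeded 7/3 train/test assignment,
#' sub-grid center extraction, and per-pixel preprocessing (SNV +
#' derivatives). For the 24-cube study this yields 19,200 rows x 426
#' features with 13,440 train and 5,760 test rows.
#'
#' @param cubes Named list of reflectance/absorbance hypercubes (names are
#'   the filenames carrying grid codes), or a function `function(filename)`
#'   returning the cube lazily (used to stream full-size studies).
#' @param filenames Character vector of filenames; defaults to `names(cubes)`.
#' @param seed Master seed; each image's split assignment uses a sub-seed
#'   derived from it and the filename, so the assignment of one image never
#'   depends on which other images are present.
#' @param absorbance Convert reflectance cubes to absorbance first (default
#'   `TRUE`).
#' @param snv Apply SNV before derivative features (default `TRUE`).
#' @return A `sample_table`: `list(features, meta)` where `features` is an
#'   `N x 426` matrix and `meta` a data.frame with label, split and
#'   provenance columns.
#' @export
build_dataset <- function(cubes, filenames = NULL, seed = 1L,
                          absorbance = TRUE, snv = TRUE) {
  if (is.function(cubes)) {
    if (is.null(filenames)) stop_contract("filenames required when cubes is a function")
    get_cube <- cubes
  } else {
    filenames <- filenames %||% names(cubes)
    if (is.null(filenames)) stop_contract("cubes must be named or filenames given")
    get_cube <- function(fn) cubes[[fn]]
  }
  labels <- do.call(rbind, lapply(filenames, parse_label))
  if (anyDuplicated(labels$code))
    stop(errorCondition(
      paste0("duplicate grid code(s) across files: ",
             paste(unique(labels$code[duplicated(labels$code)]), collapse = ", ")),
      class = c("hsi_label_error", "hsi_error")))

  feat_list <- vector("list", length(filenames))
  meta_list <- vector("list", length(filenames))
  for (i in seq_along(filenames)) {
    fn <- filenames[i]
    cube <- get_cube(fn)
    stopifnot(inherits(cube, "hypercube"))
    if (cube$value_kind == "raw")
      stop_contract("cube '", fn, "' is uncalibrated raw counts; calibrate first")
    if (dim(cube)[1L] > 350L) cube <- crop_artifacts(cube)
    roi <- select_roi(cube)
    # absorbance is elementwise, so converting after the spatial slices is
    # equivalent and avoids transforming pixels that are never sampled
    if (absorbance && roi$value_kind == "reflectance")
      roi <- to_absorbance(roi)
    parts <- assign_split(partition_roi(roi), derive_seed(seed, "split", fn))

    spectra <- matrix(NA_real_, 800L, dim(roi)[3L])
    meta <- data.frame(image_id = fn, code = labels$code[i],
                       bread = labels$bread[i], butter = labels$butter[i],
                       filling = labels$filling[i],
                       split = NA_character_, partition = NA_integer_,
                       row = NA_integer_, col = NA_integer_,
                       stringsAsFactors = FALSE)[rep(1L, 800L), ]
    pos <- 0L
    for (p in parts) {
      ext <- extract_grid_centers(p, roi)
      idx <- pos + seq_len(nrow(ext$coords))
      spectra[idx, ] <- ext$spectra
      meta$split[idx] <- p$split
      meta$partition[idx] <- p$index
      meta$row[idx] <- ext$coords[, 1L]
      meta$col[idx] <- ext$coords[, 2L]
      pos <- pos + nrow(ext$coords)
    }
    feat_list[[i]] <- preprocess_matrix(spectra, snv = snv)
    meta_list[[i]] <- meta
  }
  st <- structure(list(features = do.call(rbind, feat_list),
                       meta = do.call(rbind, c(meta_list, make.row.names = FALSE))),
                  class = "sample_table")
  stopifnot(!anyDuplicated(st$meta[, c("image_id", "row", "col")]))
  st
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d features; %d train / %d test; %d image(s)\n",
              nrow(x$features), ncol(x$features),
              sum(x$meta$split == "train"), sum(x$meta$split == "test"),
              length(unique(x$meta$image_id))))
  invisible(x)
}

#' Write a sample table as CSV (features + labels + provenance)
#' @param x A `sample_table`.
#' @param path Output CSV path.
#' @export
write_sample_table <- function(x, path) {
  stopifnot(inherits(x, "sample_table"))
  utils::write.csv(cbind(x$meta, as.data.frame(x$features)), path, row.names = FALSE)
  invisible(path)
}
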