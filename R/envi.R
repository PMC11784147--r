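# Minimal ENVI-style I/O: a text header (.hdr) beside a raw binary payload.
# Convention here: samples = width (n, first array axis), lines = length (m,
# second axis). Cubes are written BSQ float32 little-endian; BSQ/BIL/BIP and
# float64 are accepted on read.

ENVI_DTYPES <- list(`4` = list(what = "numeric", size = 4L),
                    `5` = list(what = "numeric", size = 8L))

envi_paths <- function(path) {
  # `path` may be the header, the payload, or the common stem.
  stem <- sub("\\.(hdr|raw|img|dat)$", "", path)
  hdr <- paste0(stem, ".hdr")
  for (ext in c(".raw", ".img", ".dat")) {
    p <- paste0(stem, ext)
    if (file.exists(p)) return(list(hdr = hdr, bin = p, stem = stem))
  }
  list(hdr = hdr, bin = paste0(stem, ".raw"), stem = stem)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # Fold brace-delimited multi-line values onto one line, then split fields.
  fields <- list()
  pat <- "([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- m
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop_contract("ENVI header missing field '", key, "'")
  as.numeric(v)
}

#' Read an ENVI-style hypercube
#'
#' Expects a `.hdr` text header and a raw binary payload sharing a file stem.
#' Interleaves BSQ, BIL and BIP and data types 4 (float32) / 5 (float64) are
#' supported; the wavelength vector is taken from the header `wavelength`
#' field.
#'
#' @param path Path to the header, the payload, or their common stem.
#' @param value_kind Interpretation of the stored values (`"reflectance"` by
#'   default; the format itself does not record this).
#' @return A [hypercube()].
#' @export
read_envi <- function(path, value_kind = "reflectance") {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop("ENVI header not found: ", p$hdr)
  if (!file.exists(p$bin)) stop("ENVI payload not found: ", p$bin)
  f <- parse_envi_header(p$hdr)
  ns <- as.integer(envi_num(f, "samples"))
  nl <- as.integer(envi_num(f, "lines"))
  nb <- as.integer(envi_num(f, "bands"))
  dtype <- as.character(as.integer(envi_num(f, "data type")))
  if (is.null(ENVI_DTYPES[[dtype]]))
    stop_contract("unsupported ENVI data type ", dtype)
  interleave <- tolower(f[["interleave"]] %||% "bsq")
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop_contract("unsupported interleave '", interleave, "'")
  byte_order <- as.integer(f[["byte order"]] %||% "0")
  endian <- if (byte_order == 0L) "little" else "big"

  size <- ENVI_DTYPES[[dtype]]$size
  n_expect <- as.numeric(ns) * nl * nb
  n_file <- file.info(p$bin)$size / size
  if (n_file != n_expect)
    stop_contract("ENVI payload holds ", n_file, " values but header declares ",
                  ns, " x ", nl, " x ", nb, " = ", n_expect)

  wl <- f[["wavelength"]]
  if (is.null(wl)) stop_contract("ENVI header missing field 'wavelength'")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
  if (length(wl) != nb)
    stop_contract("header lists ", length(wl), " wavelengths for ", nb, " bands")

  con <- file(p$bin, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n_expect, size = size, endian = endian)
  data <- switch(interleave,
    bsq = array(v, dim = c(ns, nl, nb)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(1L, 3L, 2L)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(2L, 3L, 1L)))
  hypercube(data, wl, value_kind)
}

#' Write a hypercube as ENVI BSQ float32
#'
#' Writes `<stem>.hdr` and `<stem>.raw` (band-sequential float32,
#' little-endian) with the wavelength vector in the header. Round-trips with
#' [read_envi()] bit-exactly for float32-representable payloads.
#'
#' @param cube A [hypercube()].
#' @param path Output stem (or a `.hdr`/`.raw` path; the extension is
#'   replaced).
#' @return The header path, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  p <- envi_paths(path)
  d <- dim(cube)
  hdr <- c(
    "ENVI",
    "description = {sandwichHSI hypercube}",
    paste0("samples = ", d[1L]),
    paste0("lines = ", d[2L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE), collapse = ", "), "}"))
  writeLines(hdr, p$hdr)
  con <- file(paste0(p$stem, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$data), con, size = 4L, endian = "little")
  invisible(p$hdr)
}
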