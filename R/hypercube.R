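#' Construct a spectral cube
#'
#' A hypercube is a `lines x samples x bands` array with one wavelength per
#' band. `kind` records whether the values are raw sensor counts or calibrated
#' reflectance %.
#'
#' @param data 3-D numeric array (lines, samples, bands).
#' @param wavelengths Strictly increasing wavelengths (nm), length = bands.
#' @param kind `"raw"` or `"reflectance"`.
#' @return A `spectral_cube` object.
#' @export
spectral_cube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("cube data must be a 3-D array (lines x samples x bands)",
         call. = FALSE)
  if (dim(data)[3] != length(wavelengths))
    stop("band dimension (", dim(data)[3], ") does not match wavelength ",
         "vector length (", length(wavelengths), ")", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<spectral_cube> ", d[1], " lines x ", d[2], " samples x ", d[3],
      " bands (", x$kind, "), ", min(x$wavelengths), "-", max(x$wavelengths),
      " nm\n", sep = "")
  invisible(x)
}

#' Dark/white reference reflectance calibration
#'
#' Converts raw counts to reflectance % via
#' `R = 100 * (raw - dark) / (white - dark)`. The white reference maps to
#' 100%, the dark reference to 0%. Elements where `white == dark` are
#' undefined and set to `NA`; the affected bands are recorded in the
#' `flagged_bands` attribute. Values outside \[0, 120\] (slight real-world
#' overshoot is expected; 120 preserves specular flags) are clipped, with the
#' clip count in the `clipped` attribute.
#'
#' @param raw,dark,white `spectral_cube`s of identical shape and wavelengths.
#' @return A reflectance `spectral_cube`.
#' @export
calibrate_reflectance <- function(raw, dark, white) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(dark, "spectral_cube"),
            inherits(white, "spectral_cube"))
  if (!identical(dim(raw$data), dim(dark$data)) ||
      !identical(dim(raw$data), dim(white$data)))
    stop("raw, dark and white cubes must have identical shapes",
         call. = FALSE)
  if (!isTRUE(all.equal(raw$wavelengths, dark$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, white$wavelengths)))
    stop("raw, dark and white cubes must share one wavelength vector",
         call. = FALSE)
  denom <- white$data - dark$data
  bad <- denom == 0
  denom[bad] <- NA_real_
  refl <- 100 * (raw$data - dark$data) / denom
  n_low <- sum(refl < 0, na.rm = TRUE)
  n_high <- sum(refl > 120, na.rm = TRUE)
  refl[refl < 0] <- 0
  refl[refl > 120] <- 120
  out <- spectral_cube(refl, raw$wavelengths, kind = "reflectance")
  flagged <- which(apply(bad, 3, any))
  attr(out, "flagged_bands") <- flagged
  attr(out, "clipped") <- n_low + n_high
  if (length(flagged))
    message(length(flagged), " band(s) flagged: white == dark reference")
  out
}

# ---- ENVI container -------------------------------------------------------

.envi_dtype <- c("int16" = 2, "int32" = 3, "float32" = 4, "float64" = 5)

#' Write a cube in ENVI format
#'
#' Writes the flat binary file at `path` and an ASCII header at
#' `<path>.hdr` declaring samples, lines, bands, data type, interleave and the
#' wavelength list. Little-endian byte order.
#'
#' @param cube A `spectral_cube`.
#' @param path Data-file path (header written alongside).
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @param dtype `"float32"`, `"float64"`, `"int16"` or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       dtype = "float64") {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  if (!dtype %in% names(.envi_dtype))
    stop("unsupported dtype '", dtype, "'", call. = FALSE)
  d <- dim(cube$data)  # lines, samples, bands
  # R arrays are column-major; permute so the fastest-varying axis comes first
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),  # sample, line, band
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),  # sample, band, line
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))  # band, sample, line
  size <- c(int16 = 2L, int32 = 4L, float32 = 4L, float64 = 8L)[[dtype]]
  what <- if (grepl("^int", dtype)) "integer" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  if (what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = size, endian = "little",
           useBytes = TRUE)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", .envi_dtype[[dtype]]),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, digits = 17, trim = TRUE,
                               scientific = FALSE), collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse an ENVI ASCII header into a named list (values as strings; braced
# lists collapsed onto one entry).
.parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  txt <- sub("^ENVI[ \t]*\n", "", txt)
  fields <- list()
  # split on newlines but re-merge lines inside braces
  lines <- strsplit(txt, "\n")[[1]]
  buf <- character(0); open <- FALSE
  merged <- character(0)
  for (ln in lines) {
    if (!open) {
      if (grepl("\\{", ln) && !grepl("\\}", ln)) { buf <- ln; open <- TRUE }
      else merged <- c(merged, ln)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { merged <- c(merged, buf); open <- FALSE }
    }
  }
  for (ln in merged) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI cube
#'
#' @param header_path Path to the `.hdr` header (the data file is the same
#'   path without the `.hdr` suffix).
#' @return A `spectral_cube` (kind `"reflectance"` if the header carries a
#'   `reflectance` flag, else `"raw"`; reading back cubes written by
#'   [write_envi()] restores values bit-exactly for float64).
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path))
    stop("header not found: ", header_path, call. = FALSE)
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("ENVI header declares no wavelength list; a wavelength entry is ",
         "required", call. = FALSE)
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  interleave <- tolower(h[["interleave"]])
  if (!interleave %in% c("bil", "bsq", "bip"))
    stop("unsupported interleave '", interleave, "'", call. = FALSE)
  dt <- as.integer(h[["data type"]])
  if (!dt %in% .envi_dtype)
    stop("unsupported ENVI data type ", dt, call. = FALSE)
  dtype <- names(.envi_dtype)[match(dt, .envi_dtype)]
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  if (length(wl) != bands)
    stop("header declares ", bands, " bands but ", length(wl),
         " wavelengths", call. = FALSE)
  data_path <- sub("\\.hdr$", "", header_path)
  n <- samples * lines * bands
  con <- file(data_path, "rb")
  on.exit(close(con))
  size <- c(int16 = 2L, int32 = 4L, float32 = 4L, float64 = 8L)[[dtype]]
  what <- if (grepl("^int", dtype)) "integer" else "double"
  v <- readBin(con, what, n = n, size = size, endian = "little")
  a <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3, 2, 1)))
  spectral_cube(a, wl, kind = "raw")
}

# ---- rendering ------------------------------------------------------------

# nearest band index for a wavelength (0.5 nm native sampling makes
# interpolation needless)
.nearest_band <- function(cube, nm) {
  vapply(nm, function(x) which.min(abs(cube$wavelengths - x)), 0L)
}

#' Pseudo-RGB rendering of a cube
#'
#' Picks the nearest bands to three requested wavelengths and normalises each
#' channel to \[0, 1\].
#'
#' @param cube A `spectral_cube`.
#' @param bands_for_rgb Three wavelengths (nm), red/green/blue.
#' @return A `lines x samples x 3` array in \[0, 1\].
#' @export
pseudo_rgb <- function(cube, bands_for_rgb = c(650, 550, 450)) {
  stopifnot(inherits(cube, "spectral_cube"), length(bands_for_rgb) == 3)
  if (any(bands_for_rgb < min(cube$wavelengths) - 1e-9) ||
      any(bands_for_rgb > max(cube$wavelengths) + 1e-9))
    stop("requested wavelengths outside cube coverage", call. = FALSE)
  idx <- .nearest_band(cube, bands_for_rgb)
  out <- cube$data[, , idx, drop = FALSE]
  for (k in 1:3) {
    ch <- out[, , k]
    rng <- range(ch, na.rm = TRUE)
    out[, , k] <- if (diff(rng) == 0) 0 else (ch - rng[1]) / diff(rng)
  }
  out
}

#' Maximum-variance band image
#'
#' Projects the cube onto the single band with maximal pixel variance — the
#' channel exhibiting maximum spectral variation across the scene.
#'
#' @param cube A `spectral_cube`.
#' @return A `lines x samples` matrix with attributes `band` (index) and
#'   `wavelength` (nm). A single-band cube returns that band with a warning.
#' @export
max_variance_image <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  nb <- dim(cube$data)[3]
  if (nb == 1) {
    warning("single-band cube: returning the only band", call. = FALSE)
    b <- 1L
  } else {
    v <- apply(cube$data, 3, function(m) stats::var(as.vector(m)))
    b <- which.max(v)
  }
  img <- cube$data[, , b]
  attr(img, "band") <- b
  attr(img, "wavelength") <- cube$wavelengths[b]
  img
}

#' Serialise a cohort's ROIs through cube containers
#'
#' Writes each ROI's pixel spectra as a 1-line ENVI cube and reads it back;
#' mainly used to verify lossless round-tripping of generated datasets.
#'
#' @param roi A `weed_roi`.
#' @param path Data-file path.
#' @return The re-read pixel matrix.
#' @keywords internal
#' @export
roi_roundtrip_envi <- function(roi, path) {
  cube <- spectral_cube(array(roi$spectra,
                              c(1, nrow(roi$spectra), ncol(roi$spectra))),
                        roi$wavelengths)
  write_envi(cube, path, interleave = "bil", dtype = "float64")
  back <- read_envi(paste0(path, ".hdr"))
  matrix(back$data[1, , ], nrow(roi$spectra), ncol(roi$spectra))
}
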