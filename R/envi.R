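# ENVI raster I/O: a text .hdr alongside a flat binary file. Supported data
# types: 1 (uint8), 12 (uint16), 4 (float32), 5 (float64); interleaves bsq,
# bil, bip. Everything is normalized to (row, col, band) order on read.

.envi_dtypes <- list(
  `1`  = list(size = 1L, what = "integer", signed = FALSE),
  `12` = list(size = 2L, what = "integer", signed = FALSE),
  `4`  = list(size = 4L, what = "double",  signed = TRUE),
  `5`  = list(size = 8L, what = "double",  signed = TRUE)
)

envi_header_path <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) return(path)
  paste0(path, ".hdr")
}

envi_data_path <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE))
    return(sub("\\.hdr$", "", path, ignore.case = TRUE))
  path
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[1]))
    stop("not an ENVI header: ", hdr_path, call. = FALSE)
  # join multi-line brace values
  txt <- paste(lines[-1], collapse = "\n")
  fields <- list()
  pos <- 1L
  pat <- "(?s)([a-zA-Z ][a-zA-Z0-9 _.]*?)\\s*=\\s*(\\{.*?\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      eq <- regexpr("=", piece, fixed = TRUE)
      key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
      val <- trimws(substr(piece, eq + 1L, nchar(piece)))
      fields[[key]] <- val
    }
  }
  fields
}

envi_field_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header missing required field '", key, "'",
                       call. = FALSE)
  suppressWarnings(n <- as.numeric(v))
  if (is.na(n)) stop("ENVI header field '", key, "' is not numeric",
                     call. = FALSE)
  n
}

envi_brace_values <- function(v) {
  v <- gsub("[{}]", "", v)
  out <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
  out[!is.na(out)]
}

#' Read an ENVI raster into a hyperspectral cube
#'
#' Parses the text header, reads the binary payload, and converts whatever
#' interleave the file uses (BSQ, BIL, or BIP) into the package's fixed
#' `(row, col, band)` array order. The header's `samples` count maps to
#' columns and `lines` to rows, the ENVI convention.
#'
#' @param path path to the binary data file, or to its `.hdr`; the companion
#'   file is located by appending/stripping the `.hdr` extension.
#' @return An [hsi_cube]. Wavelengths come from the header's `wavelength`
#'   block when present; remaining header fields are kept in `meta`.
#' @seealso [write_envi()]
#' @export
read_envi <- function(path) {
  hdr <- envi_header_path(path)
  dat <- envi_data_path(path)
  if (!file.exists(hdr)) stop("ENVI header not found: ", hdr, call. = FALSE)
  if (!file.exists(dat)) stop("ENVI data file not found: ", dat, call. = FALSE)
  f <- parse_envi_header(hdr)
  samples <- as.integer(envi_field_num(f, "samples"))
  lines_n <- as.integer(envi_field_num(f, "lines"))
  bands <- as.integer(envi_field_num(f, "bands"))
  dtype <- as.character(as.integer(envi_field_num(f, "data type")))
  interleave <- tolower(trimws(f[["interleave"]] %||% ""))
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("ENVI header missing or unsupported interleave: '", interleave, "'",
         call. = FALSE)
  spec <- .envi_dtypes[[dtype]]
  if (is.null(spec))
    stop("unsupported ENVI data type ", dtype,
         " (supported: 1, 4, 5, 12)", call. = FALSE)
  offset <- if (!is.null(f[["header offset"]]))
    as.integer(envi_field_num(f, "header offset")) else 0L
  n <- samples * lines_n * bands
  expected <- offset + n * spec$size
  actual <- file.info(dat)$size
  if (actual != expected)
    stop(sprintf(
      "ENVI file size mismatch: header implies %d bytes, file has %d (corrupt or truncated)",
      expected, actual), call. = FALSE)
  con <- file(dat, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = "little")
  v <- as.numeric(v)
  arr <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, samples, lines_n)), c(3, 2, 1)))
  wl <- if (!is.null(f[["wavelength"]])) envi_brace_values(f[["wavelength"]])
  if (!is.null(wl) && length(wl) != bands) wl <- NULL
  meta <- f[setdiff(names(f), c("samples", "lines", "bands", "data type",
                                "interleave", "header offset", "wavelength",
                                "byte order"))]
  hsi_cube(arr, wavelengths = wl, meta = meta)
}

#' Write a hyperspectral cube as an ENVI raster
#'
#' Writes `path` (binary payload) and `path.hdr` (text header) in the chosen
#' interleave. Round-trips through [read_envi()] are bit-exact for the
#' float64 default, and exact for integer types whenever the data are
#' representable integers in range.
#'
#' @param cube an [hsi_cube].
#' @param path output path for the binary data file.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 1 (uint8), 12 (uint16),
#'   4 (float32), 5 (float64, default).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  dtype <- as.character(as.integer(data_type))
  spec <- .envi_dtypes[[dtype]]
  if (is.null(spec))
    stop("unsupported ENVI data type ", dtype, call. = FALSE)
  d <- dim(cube$data)
  if (any(d < 1L)) stop("cannot write an empty cube", call. = FALSE)
  x <- cube$data
  if (spec$what == "integer") {
    if (any(x != round(x)) || any(x < 0) ||
        any(x > (2^(8 * spec$size) - 1)))
      stop("cube values not representable in integer data type ", dtype,
           call. = FALSE)
  }
  v <- switch(interleave,
    bsq = as.vector(aperm(x, c(2, 1, 3))),
    bil = as.vector(aperm(x, c(2, 3, 1))),
    bip = as.vector(aperm(x, c(3, 2, 1))))
  con <- file(path, "wb")
  ok <- FALSE
  on.exit(if (!ok) unlink(path) else NULL, add = TRUE)
  on.exit(close(con), add = TRUE, after = FALSE)
  if (spec$what == "integer") {
    writeBin(as.integer(v), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = spec$size, endian = "little")
  }
  ok <- TRUE
  hdr <- c(
    "ENVI",
    "description = {cottonhsi export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dtype),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}"))
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
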