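#' Hyperspectral image cube
#'
#' Constructs the central raster object of the package: a three-dimensional
#' reflectance (or raw-count) array in fixed `(row, col, band)` axis order,
#' together with the wavelength grid and free-form header metadata. Every
#' function in the package uses this axis convention; ENVI interleaves are
#' converted on read so no other ordering ever circulates.
#'
#' @param data numeric 3-d array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band. Defaults to an even grid over
#'   400--1000 nm, the visible/near-infrared range of the target camera.
#' @param meta named list of free-form header key/value pairs.
#' @return An object of class `hsi_cube` with elements `data`,
#'   `wavelengths`, `meta`.
#' @examples
#' cube <- hsi_cube(array(runif(4 * 5 * 3), c(4, 5, 3)))
#' dim(cube)
#' @export
hsi_cube <- function(data, wavelengths = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (rows x cols x bands)", call. = FALSE)
  if (!is.numeric(data))
    stop("`data` must be numeric", call. = FALSE)
  d <- dim(data)
  if (d[3] < 1L) stop("cube must have at least one band", call. = FALSE)
  if (is.null(wavelengths)) {
    wavelengths <- if (d[3] == 1L) 700 else seq(400, 1000, length.out = d[3])
  }
  if (length(wavelengths) != d[3])
    stop("`wavelengths` must have one entry per band", call. = FALSE)
  if (d[3] > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "hsi_cube")
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  rng <- range(x$data)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

n_bands <- function(cube) dim(cube$data)[3]

#' Per-pixel class label map
#'
#' An integer raster aligned to a cube's spatial grid. Class indices run
#' `1..C`; `0` is reserved for pixels excluded from training (unlabeled).
#' The background of a scene is an ordinary class, not `0`.
#'
#' @param labels integer matrix, `rows x cols`, values in `0..C`.
#' @param class_names character vector of length `C` naming classes `1..C`.
#'   Defaults to `"class_1" .. "class_C"` with `C = max(labels)`.
#' @return An object of class `label_map` with elements `labels`,
#'   `class_names`.
#' @export
label_map <- function(labels, class_names = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  C <- max(labels, 0L)
  if (is.null(class_names)) {
    class_names <- if (C > 0L) paste0("class_", seq_len(C)) else character()
  }
  if (length(class_names) < C)
    stop("`class_names` must cover every class index used", call. = FALSE)
  structure(list(labels = labels, class_names = as.character(class_names)),
            class = "label_map")
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = 0:length(x$class_names)))
  cat(sprintf("<label_map> %d x %d pixels, %d classes\n",
              d[1], d[2], length(x$class_names)))
  nm <- c("(unlabeled)", x$class_names)
  for (i in seq_along(tab))
    if (tab[i] > 0) cat(sprintf("  %-20s %d\n", nm[i], tab[i]))
  invisible(x)
}

check_aligned <- function(cube, labels) {
  if (!identical(dim(cube$data)[1:2], dim(labels$labels)))
    stop("label map and cube have different spatial shapes", call. = FALSE)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every seeded operation so seed-determinism holds exactly.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
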