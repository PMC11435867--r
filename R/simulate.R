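# Synthetic acquisition model. A scene is a background material carrying
# elliptical impurity blobs; each material has a smooth reflectance curve
# over the 400-1000 nm grid. The sensor sees
#   raw = dark_level + gain * (a_px * signature + c_px) + noise
# where a_px ~ N(1, scatter_mult_sd) and c_px ~ N(0, scatter_add_sd) are a
# per-pixel affine scatter distortion (what MSC exists to remove),
# dark_level is the dark-current offset, and noise is additive sensor
# noise. Dark and white reference frames are captured through the same
# noise model, so black-and-white correction has realistic inputs.

#' Specify a synthetic hyperspectral scene
#'
#' Bundles the geometry, optics, and noise parameters of a simulated
#' acquisition. With all standard deviations zero, the composition of
#' [simulate_scene()] and [black_white_correct()] returns each pixel's
#' class signature exactly, which anchors the preprocessing tests.
#'
#' @param rows,cols scene size in pixels.
#' @param bands number of spectral bands over 400--1000 nm.
#' @param n_classes number of material classes; class `n_classes` is the
#'   background, classes `1..n_classes-1` are impurity blobs.
#' @param class_signatures optional `n_classes x bands` matrix of
#'   reflectance curves in `[0, 1]`; defaults to smooth sums of 2--3
#'   Gaussian bumps with class-specific centers.
#' @param blob_count number of impurity blobs laid on the background.
#' @param blob_size_range blob diameter range in pixels, `c(min, max)`.
#' @param scatter_mult_sd sd of the per-pixel multiplicative scatter factor
#'   (around 1).
#' @param scatter_add_sd sd of the per-pixel additive scatter baseline.
#' @param noise_sd sd of additive sensor noise, in raw-count units.
#' @param dark_level dark-current offset, raw-count units.
#' @param gain sensor gain mapping reflectance 1.0 to raw counts above dark.
#' @param seed RNG seed; fixes the scene exactly.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 64, cols = 64, bands = 32, n_classes = 9,
                       class_signatures = NULL,
                       blob_count = 20, blob_size_range = c(5, 15),
                       scatter_mult_sd = 0.10, scatter_add_sd = 0.02,
                       noise_sd = 0.01, dark_level = 0.05, gain = 0.9,
                       seed = 1) {
  stopifnot(rows >= 1, cols >= 1, bands >= 1, n_classes >= 2,
            blob_count >= 0, length(blob_size_range) == 2,
            blob_size_range[1] <= blob_size_range[2],
            scatter_mult_sd >= 0, scatter_add_sd >= 0, noise_sd >= 0)
  wl <- if (bands == 1L) 700 else seq(400, 1000, length.out = bands)
  if (is.null(class_signatures))
    class_signatures <- default_signatures(n_classes, wl)
  if (!is.matrix(class_signatures) ||
      nrow(class_signatures) != n_classes ||
      ncol(class_signatures) != bands)
    stop("`class_signatures` must be an n_classes x bands matrix",
         call. = FALSE)
  if (any(class_signatures < 0) || any(class_signatures > 1))
    stop("class signatures must lie in [0, 1]", call. = FALSE)
  structure(list(rows = rows, cols = cols, bands = bands,
                 n_classes = n_classes, wavelengths = wl,
                 class_signatures = class_signatures,
                 blob_count = blob_count, blob_size_range = blob_size_range,
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd, noise_sd = noise_sd,
                 dark_level = dark_level, gain = gain, seed = seed),
            class = "scene_spec")
}

#' Default class reflectance signatures
#'
#' Deterministic smooth curves: each class is a sum of 2--3 Gaussian bumps
#' with class-specific centers and widths, rescaled into `[0.1, 0.9]`.
#' Curves are fixed (no RNG), mutually well separated, and smooth, standing
#' in for the distinct reflectance spectra of cotton, films, ropes, paper,
#' and foam.
#'
#' @param n_classes number of classes.
#' @param wavelengths band-center wavelengths in nm.
#' @return An `n_classes x length(wavelengths)` matrix in `[0.1, 0.9]`.
#' @export
default_signatures <- function(n_classes, wavelengths) {
  sig <- matrix(0, n_classes, length(wavelengths))
  for (k in seq_len(n_classes)) {
    nb <- 2L + (k %% 2L)
    # low-discrepancy bump placement: distinct centers per class
    cent <- 400 + 600 * ((k * 0.6180340 + seq_len(nb) * 0.3819660) %% 1)
    wid <- 60 + 25 * ((k + seq_len(nb)) %% 3L)
    amp <- 0.5 + 0.5 * ((k * seq_len(nb)) %% 4L) / 3
    raw <- rep(0.15 * k / n_classes, length(wavelengths))
    for (b in seq_len(nb))
      raw <- raw + amp[b] * exp(-(wavelengths - cent[b])^2 / (2 * wid[b]^2))
    rng <- range(raw)
    sig[k, ] <- 0.1 + 0.8 * (raw - rng[1]) / max(rng[2] - rng[1], 1e-12)
  }
  sig
}

#' Simulate a hyperspectral acquisition with reference frames
#'
#' Generates the raw scene cube plus the dark and white reference cubes an
#' operator would capture (shutter closed; standard white board), and the
#' ground-truth label map. The simulation is a pure function of its spec:
#' identical seeds give bit-identical outputs.
#'
#' @param spec a [scene_spec].
#' @return A list with elements `raw`, `dark`, `white` ([hsi_cube]s) and
#'   `truth` (a [label_map] covering every pixel; background is a class).
#' @examples
#' sc <- simulate_scene(scene_spec(rows = 16, cols = 16, bands = 8, seed = 3))
#' table(sc$truth$labels)
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$blob_count > 0 &&
      spec$blob_size_range[1] > min(spec$rows, spec$cols))
    stop("blob size exceeds scene dimensions", call. = FALSE)
  with_seed(spec$seed, {
    R <- spec$rows; C <- spec$cols; B <- spec$bands
    labels <- matrix(spec$n_classes, R, C)  # background class
    n_imp <- spec$n_classes - 1L
    rr <- row(labels); cc <- col(labels)
    for (b in seq_len(spec$blob_count)) {
      cls <- 1L + ((b - 1L) %% n_imp)
      r1 <- runif(1, spec$blob_size_range[1], spec$blob_size_range[2]) / 2
      r2 <- runif(1, spec$blob_size_range[1], spec$blob_size_range[2]) / 2
      th <- runif(1, 0, pi)
      cy <- runif(1, min(1 + r1, (R + 1) / 2), max(R - r1, (R + 1) / 2))
      cx <- runif(1, min(1 + r2, (C + 1) / 2), max(C - r2, (C + 1) / 2))
      dy <- rr - cy; dx <- cc - cx
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      labels[(u / r1)^2 + (v / r2)^2 <= 1] <- cls
    }
    npx <- R * C
    a <- 1 + rnorm(npx, sd = spec$scatter_mult_sd)
    cadd <- rnorm(npx, sd = spec$scatter_add_sd)
    refl <- spec$class_signatures[as.vector(labels), , drop = FALSE]
    refl <- refl * a + cadd                     # per-pixel affine scatter
    raw <- spec$dark_level + spec$gain * refl
    if (spec$noise_sd > 0)
      raw <- raw + rnorm(npx * B, sd = spec$noise_sd)
    dark <- matrix(spec$dark_level, npx, B)
    white <- matrix(spec$dark_level + spec$gain, npx, B)
    if (spec$noise_sd > 0) {
      dark <- dark + rnorm(npx * B, sd = spec$noise_sd)
      white <- white + rnorm(npx * B, sd = spec$noise_sd)
    }
    as_cube <- function(m) hsi_cube(array(m, c(R, C, B)),
                                    wavelengths = spec$wavelengths)
    list(raw = as_cube(raw), dark = as_cube(dark), white = as_cube(white),
         truth = label_map(labels,
                           class_names = c(paste0("impurity_", seq_len(n_imp)),
                                           "background")))
  })
}
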