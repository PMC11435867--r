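# The five-stage spectral preprocessing chain: reflectance correction with
# dark/white references, spatial cropping, per-band standardization,
# multiplicative scatter correction (MSC), and PCA band reduction; plus the
# band-discrimination score used for label making and the absorbance view.
# All divide guards use a common epsilon.

.EPS <- 1e-8

cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, d[1] * d[2], d[3])
}

matrix_cube <- function(m, template, wavelengths = NULL) {
  d <- dim(template$data)
  hsi_cube(array(m, c(d[1], d[2], ncol(m))),
           wavelengths = wavelengths %||% template$wavelengths,
           meta = template$meta)
}

#' Black-and-white reflectance correction
#'
#' Converts raw sensor counts to relative reflectance using the dark-frame
#' and white-board reference captures:
#' \deqn{R = (L - B) / (W - B)}
#' applied elementwise per pixel and band. Where the dynamic range
#' `|W - B|` vanishes the output is set to 0 with a warning. The result is
#' invariant to any common positive gain applied to all three cubes.
#'
#' @param raw,dark,white [hsi_cube]s of identical shape: the scene, the
#'   shutter-closed capture, and the white reference capture.
#' @return An [hsi_cube] of relative reflectance (typically in `[0, 1]`,
#'   mildly outside under noise; no clipping is applied).
#' @export
black_white_correct <- function(raw, dark, white) {
  stopifnot(inherits(raw, "hsi_cube"), inherits(dark, "hsi_cube"),
            inherits(white, "hsi_cube"))
  if (!identical(dim(raw$data), dim(dark$data)) ||
      !identical(dim(raw$data), dim(white$data)))
    stop("raw, dark, and white cubes must have identical shapes",
         call. = FALSE)
  den <- white$data - dark$data
  bad <- abs(den) < .EPS
  if (any(bad)) {
    warning(sum(bad), " cells with vanishing white-dark range set to 0")
    den[bad] <- 1
  }
  out <- (raw$data - dark$data) / den
  out[bad] <- 0
  hsi_cube(out, wavelengths = raw$wavelengths, meta = raw$meta)
}

#' Crop a cube (and its label map) spatially
#'
#' Removes redundant background by taking a half-open spatial window
#' `[row_range[1], row_range[2]) x [col_range[1], col_range[2])` in 0-based
#' coordinates, keeping all bands. The label map, when given, is cropped
#' identically so alignment is preserved.
#'
#' @param cube an [hsi_cube].
#' @param labels an optional [label_map] aligned to `cube`.
#' @param row_range,col_range integer pairs `c(start, stop)`, half-open,
#'   0-based; defaults keep the full extent.
#' @return If `labels` is `NULL`, the cropped cube; otherwise
#'   `list(cube, labels)`.
#' @export
crop_cube <- function(cube, labels = NULL,
                      row_range = c(0L, dim(cube$data)[1]),
                      col_range = c(0L, dim(cube$data)[2])) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  chk <- function(r, n, nm) {
    if (length(r) != 2 || r[1] < 0 || r[2] > n || r[1] >= r[2])
      stop("invalid ", nm, " [", r[1], ", ", r[2], ") for extent ", n,
           call. = FALSE)
  }
  chk(row_range, d[1], "row range")
  chk(col_range, d[2], "col range")
  ri <- (row_range[1] + 1L):row_range[2]
  ci <- (col_range[1] + 1L):col_range[2]
  out <- hsi_cube(cube$data[ri, ci, , drop = FALSE],
                  wavelengths = cube$wavelengths, meta = cube$meta)
  if (is.null(labels)) return(out)
  check_aligned(cube, labels)
  list(cube = out,
       labels = label_map(labels$labels[ri, ci, drop = FALSE],
                          labels$class_names))
}

#' Per-band class separation score
#'
#' For label making one wants the band where the materials differ most in
#' reflectance. For every band the score is the *minimum* over class pairs
#' of the absolute difference in class-mean reflectance (computed over
#' labeled pixels only), so a high score means every pair of classes is
#' separated in that band. Returns the scores and the first band attaining
#' the maximum.
#'
#' @param cube an [hsi_cube].
#' @param labels a [label_map] with at least two represented classes.
#' @return A list with `scores` (numeric, one per band), `best_band`
#'   (1-based index of the first maximal band), and `class_means`
#'   (`classes x bands`).
#' @export
band_discrimination <- function(cube, labels) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(labels, "label_map"))
  check_aligned(cube, labels)
  lab <- as.vector(labels$labels)
  keep <- lab > 0L
  cls <- sort(unique(lab[keep]))
  if (length(cls) < 2L)
    stop("band discrimination needs at least two labeled classes",
         call. = FALSE)
  X <- cube_matrix(cube)[keep, , drop = FALSE]
  g <- factor(lab[keep], levels = cls)
  means <- rowsum(X, g) / as.vector(table(g))
  pairs <- utils::combn(length(cls), 2)
  diffs <- abs(means[pairs[1, ], , drop = FALSE] -
               means[pairs[2, ], , drop = FALSE])
  scores <- apply(diffs, 2, min)
  list(scores = scores, best_band = which.max(scores), class_means = means)
}

#' Standardize a cube to mean 0, standard deviation 1
#'
#' Centers and scales the spectral data to mean 0 and population standard
#' deviation 1, stabilizing the value distribution before scatter
#' correction and PCA. With `scope = "band"` (the default) each band is
#' standardized separately over all pixels; with `scope = "global"` a
#' single mean and sd over the whole cube are used, which preserves the
#' relative band structure (and in particular keeps the cube's mean
#' spectrum non-degenerate, a prerequisite for the MSC stage that follows
#' it in the chain). Constant bands (sd below epsilon) are mapped to 0
#' with a warning. The returned centers and scales can be reused on
#' held-out cubes via [standardize_apply()].
#'
#' @param cube an [hsi_cube] with at least 2 pixels.
#' @param scope `"band"` for per-band standardization, `"global"` for one
#'   scalar mean/sd over the whole cube.
#' @return A list with `cube` (standardized), `center` and `scale`
#'   (per-band, or scalar for `"global"`), and `model` for reuse.
#' @export
standardize_cube <- function(cube, scope = c("band", "global")) {
  stopifnot(inherits(cube, "hsi_cube"))
  scope <- match.arg(scope)
  X <- cube_matrix(cube)
  if (nrow(X) < 2L) stop("standardization needs at least 2 pixels",
                         call. = FALSE)
  if (scope == "band") {
    mu <- colMeans(X)
    sdv <- sqrt(colMeans(X^2) - mu^2)  # population sd
  } else {
    mu <- rep(mean(X), ncol(X))
    sdv <- rep(sqrt(mean(X^2) - mean(X)^2), ncol(X))
  }
  flat <- sdv < .EPS
  if (any(flat))
    warning(sum(flat), " constant band(s) mapped to 0")
  model <- list(center = mu, scale = ifelse(flat, 1, sdv), flat = flat)
  list(cube = standardize_apply(cube, model), center = mu, scale = sdv,
       model = model)
}

#' Apply a previously fitted standardization
#'
#' @param cube an [hsi_cube] with the same band count the model was fit on.
#' @param model the `model` element returned by [standardize_cube()].
#' @return The standardized [hsi_cube].
#' @export
standardize_apply <- function(cube, model) {
  X <- cube_matrix(cube)
  if (ncol(X) != length(model$center))
    stop("band count does not match standardization model", call. = FALSE)
  Z <- (X - rep(model$center, each = nrow(X))) /
    rep(model$scale, each = nrow(X))
  Z[, model$flat] <- 0
  matrix_cube(Z, cube)
}

#' Multiplicative scatter correction
#'
#' Removes per-pixel baseline shift and scale caused by light scattering.
#' Each pixel spectrum \eqn{Z_i} is regressed by ordinary least squares on
#' a reference spectrum \eqn{\bar Z} (by default the cube's own mean
#' spectrum), \eqn{Z_i = m_i \bar Z + b_i}, and the corrected spectrum is
#' \eqn{(Z_i - b_i) / m_i}. This exactly inverts a noiseless affine
#' distortion \eqn{a_i \bar Z + c_i}. Pixels whose slope magnitude is
#' negligible — below epsilon, or below `slope_tol` times the median
#' absolute slope of the cube — are passed through unchanged with a
#' warning: dividing by a near-zero slope would amplify such pixels by
#' orders of magnitude, and on multi-material scenes a few mixed or noisy
#' pixels otherwise come to dominate the band covariance of every
#' downstream stage.
#'
#' @param cube an [hsi_cube] with at least 2 bands.
#' @param reference optional reference spectrum of length `bands`; defaults
#'   to the mean spectrum over all pixels.
#' @param slope_tol relative near-zero-slope guard: pixels with
#'   `|m| < slope_tol * median(|m|)` are passed through (default 0.05).
#' @return A list with `cube` (corrected) and `model` (class `msc_model`:
#'   `mean_spectrum`, per-pixel `slope` and `intercept`).
#' @export
msc <- function(cube, reference = NULL, slope_tol = 0.05) {
  stopifnot(inherits(cube, "hsi_cube"))
  X <- cube_matrix(cube)
  n <- ncol(X)
  if (n < 2L) stop("MSC needs at least 2 bands", call. = FALSE)
  ref <- reference %||% colMeans(X)
  if (length(ref) != n)
    stop("reference spectrum length does not match band count",
         call. = FALSE)
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  if (denom < .EPS)
    stop("reference spectrum is constant; MSC slope is undefined",
         call. = FALSE)
  m <- as.vector(X %*% rc) / denom
  b <- rowMeans(X) - m * mean(ref)
  low <- abs(m) < pmax(.EPS, slope_tol * stats::median(abs(m)))
  if (any(low))
    warning(sum(low), " pixel(s) with near-zero MSC slope passed through")
  ms <- ifelse(low, 1, m)
  bs <- ifelse(low, 0, b)
  Z <- (X - bs) / ms
  list(cube = matrix_cube(Z, cube),
       model = structure(list(mean_spectrum = ref, slope = m, intercept = b),
                         class = "msc_model"))
}

#' Apply MSC with a stored reference spectrum
#'
#' @param cube an [hsi_cube].
#' @param model an `msc_model` from [msc()] (only its reference spectrum is
#'   reused; slopes and intercepts are refit per pixel of the new cube).
#' @return The corrected [hsi_cube].
#' @export
msc_apply <- function(cube, model) {
  msc(cube, reference = model$mean_spectrum)$cube
}

#' Fit a PCA band-reduction model
#'
#' Centers the pixels per band, forms the band covariance matrix, and
#' eigendecomposes it. The retained dimension `p` is either given directly
#' (`n_comp`) or chosen as the smallest `p` whose cumulative explained
#' variance ratio reaches `threshold`.
#'
#' @param cube an [hsi_cube]; more pixels than bands is recommended.
#' @param threshold cumulative explained-variance threshold `b` in
#'   `(0, 1]`. Exactly one of `threshold` and `n_comp` must be given.
#' @param n_comp fixed number of components to retain.
#' @return An object of class `pca_model`: `component_matrix` (orthonormal
#'   `bands x p`), `eigenvalues` (all, descending), `center`, `retained`,
#'   `threshold`.
#' @export
pca_fit <- function(cube, threshold = NULL, n_comp = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(threshold) == is.null(n_comp))
    stop("give exactly one of `threshold` or `n_comp`", call. = FALSE)
  X <- cube_matrix(cube)
  m <- nrow(X); n <- ncol(X)
  center <- colMeans(X)
  Xc <- X - rep(center, each = m)
  covm <- crossprod(Xc) / m
  ed <- eigen(covm, symmetric = TRUE)
  lambda <- pmax(ed$values, 0)
  if (!is.null(n_comp)) {
    if (n_comp < 1 || n_comp > n)
      stop("`n_comp` must be in 1..bands", call. = FALSE)
    p <- as.integer(n_comp)
  } else {
    if (threshold <= 0 || threshold > 1)
      stop("`threshold` must be in (0, 1]", call. = FALSE)
    ratio <- cumsum(lambda) / sum(lambda)
    p <- which(ratio >= threshold - 1e-12)[1]
    if (is.na(p)) p <- n
  }
  structure(list(component_matrix = ed$vectors[, seq_len(p), drop = FALSE],
                 eigenvalues = lambda, center = center, retained = p,
                 threshold = threshold),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  kept <- sum(x$eigenvalues[seq_len(x$retained)])
  cat(sprintf("<pca_model> %d of %d bands retained (%.2f%% variance)\n",
              x$retained, length(x$eigenvalues), 100 * kept / max(tot, .EPS)))
  invisible(x)
}

#' Project a cube onto fitted principal components
#'
#' @param cube an [hsi_cube] with the band count the model was fit on.
#' @param model a [pca_fit()] model.
#' @return An [hsi_cube] with `p` bands of component scores (wavelength
#'   metadata is replaced by component indices).
#' @export
pca_apply <- function(cube, model) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(model, "pca_model"))
  X <- cube_matrix(cube)
  if (ncol(X) != length(model$center))
    stop("band count does not match PCA model", call. = FALSE)
  Xc <- X - rep(model$center, each = nrow(X))
  S <- Xc %*% model$component_matrix
  matrix_cube(S, cube, wavelengths = seq_len(ncol(S)))
}

#' Absorbance view of a reflectance cube
#'
#' Converts measured intensity to absorbance against a reference intensity:
#' \eqn{A = -\log_{10}(I / I_0)}. Non-positive intensities are clipped to
#' epsilon with a warning.
#'
#' @param cube an [hsi_cube] of intensities `I`.
#' @param reference per-band reference intensity `I0` (unabsorbed light).
#' @return The absorbance [hsi_cube].
#' @export
absorbance <- function(cube, reference) {
  stopifnot(inherits(cube, "hsi_cube"))
  X <- cube_matrix(cube)
  if (length(reference) != ncol(X))
    stop("reference length does not match band count", call. = FALSE)
  if (any(X <= 0) || any(reference <= 0)) {
    warning("non-positive intensities clipped to epsilon")
    X[X <= 0] <- .EPS
    reference[reference <= 0] <- .EPS
  }
  A <- -log10(X / rep(reference, each = nrow(X)))
  matrix_cube(A, cube)
}

#' Configuration for the preprocessing chain
#'
#' @param crop_rows,crop_cols optional half-open 0-based ranges passed to
#'   [crop_cube()]; `NULL` keeps the full extent.
#' @param correct,standardize,msc,pca logical switches enabling each stage.
#' @param standardize_scope `"global"` (default) or `"band"`; see
#'   [standardize_cube()]. The chain defaults to global scaling because
#'   per-band scaling would zero the mean spectrum that the MSC stage
#'   regresses against.
#' @param pca_n fixed number of retained components (default 16); set to
#'   `NULL` to use `pca_threshold` instead.
#' @param pca_threshold cumulative-variance threshold alternative to
#'   `pca_n`.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(crop_rows = NULL, crop_cols = NULL,
                         correct = TRUE, standardize = TRUE, msc = TRUE,
                         pca = TRUE, standardize_scope = "global",
                         pca_n = 16, pca_threshold = NULL) {
  stopifnot(standardize_scope %in% c("band", "global"))
  structure(list(crop_rows = crop_rows, crop_cols = crop_cols,
                 correct = correct, standardize = standardize, msc = msc,
                 pca = pca, standardize_scope = standardize_scope,
                 pca_n = pca_n, pca_threshold = pca_threshold),
            class = "chain_config")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: black-and-white correction, cropping,
#' standardization, MSC, and PCA band reduction. Each stage can be
#' switched off in the [chain_config()]. Standardization is global
#' (scalar) by default so that the standardized cube keeps a non-trivial
#' mean spectrum for the MSC regression; MSC then uses its default
#' reference, the cube's own mean spectrum. Fitted models are returned
#' and can be reused on held-out cubes by passing them back via `models`.
#'
#' @param raw,dark,white [hsi_cube]s from one acquisition; `dark`/`white`
#'   may be `NULL` when `correct` is disabled.
#' @param config a [chain_config()].
#' @param labels optional [label_map] cropped alongside the cube.
#' @param models optional list of previously fitted models (as returned by
#'   this function) reused instead of refitting, for inference cubes.
#' @return A list with `cube` (preprocessed), `labels` (cropped map or
#'   `NULL`), and `models` (list: `standardize`, `msc_reference`, `pca`).
#' @export
preprocess_chain <- function(raw, dark = NULL, white = NULL,
                             config = chain_config(), labels = NULL,
                             models = NULL) {
  stopifnot(inherits(config, "chain_config"))
  cube <- if (isTRUE(config$correct)) {
    if (is.null(dark) || is.null(white))
      stop("correction enabled but dark/white references missing",
           call. = FALSE)
    black_white_correct(raw, dark, white)
  } else raw
  if (!is.null(config$crop_rows) || !is.null(config$crop_cols)) {
    d <- dim(cube$data)
    cr <- config$crop_rows %||% c(0L, d[1])
    cc <- config$crop_cols %||% c(0L, d[2])
    res <- crop_cube(cube, labels, cr, cc)
    if (is.null(labels)) cube <- res else { cube <- res$cube; labels <- res$labels }
  }
  out_models <- list(standardize = NULL, msc_reference = NULL, pca = NULL)
  if (isTRUE(config$standardize)) {
    if (!is.null(models$standardize)) {
      cube <- standardize_apply(cube, models$standardize)
      out_models$standardize <- models$standardize
    } else {
      st <- standardize_cube(cube, scope = config$standardize_scope)
      cube <- st$cube
      out_models$standardize <- st$model
    }
  }
  if (isTRUE(config$msc)) {
    msc_ref <- models$msc_reference %||% colMeans(cube_matrix(cube))
    cube <- msc(cube, reference = msc_ref)$cube
    out_models$msc_reference <- msc_ref
  }
  if (isTRUE(config$pca)) {
    if (!is.null(models$pca)) {
      out_models$pca <- models$pca
    } else {
      out_models$pca <- pca_fit(cube, threshold = config$pca_threshold,
                                n_comp = if (is.null(config$pca_threshold))
                                  config$pca_n else NULL)
    }
    cube <- pca_apply(cube, out_models$pca)
  }
  list(cube = cube, labels = labels, models = out_models)
}
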