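# Confusion-matrix evaluation: per-class recall and precision, average
# accuracy (AA, the mean of per-class recalls) and overall accuracy (OA,
# the fraction of all samples classified correctly).
#
# Note on conventions: recall_i = TP_i / (TP_i + FN_i) (diagonal over row
# sum) and precision_i = TP_i / (TP_i + FP_i) (diagonal over column sum),
# the standard definitions. These are the definitions under which the AA
# column of a per-class recall table equals the mean of its recall entries;
# presentations that swap the two formulas are transposition typos and are
# not followed.

#' Confusion matrix
#'
#' @param truth,pred integer class labels in `1..C`, equal length.
#' @param n_classes number of classes `C`; defaults to the largest label
#'   seen.
#' @param class_names optional class names for the dimnames.
#' @return A `C x C` integer matrix; entry `(i, j)` counts samples of true
#'   class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL,
                             class_names = NULL) {
  if (length(truth) != length(pred))
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (any(truth < 1) || any(pred < 1))
    stop("labels must be in 1..C", call. = FALSE)
  C <- n_classes %||% max(truth, pred)
  if (any(truth > C) || any(pred > C))
    stop("labels exceed `n_classes`", call. = FALSE)
  lev <- seq_len(C)
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  cm <- matrix(as.integer(cm), C, C)
  nm <- class_names %||% paste0("class_", lev)
  dimnames(cm) <- list(truth = nm, pred = nm)
  cm
}

#' Per-class recall and precision
#'
#' Classes absent from the truth (empty row) have undefined recall;
#' classes never predicted (empty column) have undefined precision. Both
#' are reported as `NA` with a warning.
#'
#' @param confusion a square count matrix from [confusion_matrix()].
#' @return A list with numeric vectors `recall` and `precision`
#'   (proportions in `[0, 1]`, `NA` where undefined).
#' @export
per_class_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  recall <- unname(ifelse(rs > 0, tp / rs, NA_real_))
  precision <- unname(ifelse(cs > 0, tp / cs, NA_real_))
  if (any(rs == 0) || any(cs == 0))
    warning("empty class row/column: undefined metrics reported as NA")
  list(recall = recall, precision = precision)
}

#' Average and overall accuracy
#'
#' AA is the mean of per-class recalls (undefined classes excluded with a
#' warning from [per_class_metrics()]); OA is the trace over the total.
#' Both are returned in percent. Alternatively a vector of per-class
#' recalls may be supplied directly (on whatever scale it is given; the
#' mean is returned on the same scale), which is how published per-class
#' tables are checked for internal consistency.
#'
#' @param confusion a square count matrix, or `NULL` when `recalls` is
#'   given.
#' @param recalls optional vector of per-class recalls.
#' @return For a confusion matrix, `list(AA, OA)` in percent; for a recall
#'   vector, `list(AA, OA = NA)`.
#' @export
aggregate_accuracy <- function(confusion = NULL, recalls = NULL) {
  if (is.null(confusion) == is.null(recalls))
    stop("give exactly one of `confusion` or `recalls`", call. = FALSE)
  if (!is.null(recalls))
    return(list(AA = mean(recalls, na.rm = TRUE), OA = NA_real_))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  pm <- suppressWarnings(per_class_metrics(confusion))
  if (anyNA(pm$recall))
    warning("classes with no samples excluded from AA")
  list(AA = 100 * mean(pm$recall, na.rm = TRUE),
       OA = 100 * sum(diag(confusion)) / total)
}

#' Evaluate a model on a split of a patch dataset
#'
#' @param model an [mjhresnet] model.
#' @param dataset a [patch_dataset].
#' @param split which split to score (`"test"`, `"train"`, or `"all"`).
#' @return An object of class `eval_report`: `confusion`, `recall` and
#'   `precision` (percent), `AA`, `OA`, `class_names`.
#' @export
evaluate_model <- function(model, dataset, split = c("test", "train",
                                                     "all")) {
  split <- match.arg(split)
  idx <- if (split == "all") seq_along(dataset$labels)
         else which(dataset$split == split)
  if (length(idx) == 0L) stop("no samples in split '", split, "'",
                              call. = FALSE)
  pred <- predict(model, dataset$patches[idx, , , , drop = FALSE])
  cm <- confusion_matrix(dataset$labels[idx], pred,
                         n_classes = model$config$n_classes,
                         class_names = dataset$class_names)
  pm <- suppressWarnings(per_class_metrics(cm))
  agg <- suppressWarnings(aggregate_accuracy(cm))
  structure(list(confusion = cm, recall = 100 * pm$recall,
                 precision = 100 * pm$precision,
                 AA = agg$AA, OA = agg$OA,
                 class_names = dataset$class_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  nm <- if (length(x$class_names) == length(x$recall)) x$class_names
        else paste0("class_", seq_along(x$recall))
  df <- data.frame(class = nm,
                   recall = sprintf("%.4f", x$recall),
                   precision = sprintf("%.4f", x$precision))
  print(df, row.names = FALSE)
  cat(sprintf("AA %.4f%%  OA %.4f%%  (n = %d)\n", x$AA, x$OA,
              sum(x$confusion)))
  invisible(x)
}

# Fixed palette for up to 12 classes (class index -> RGB in [0, 1]).
.class_palette <- matrix(c(
  0.894, 0.102, 0.110,
  0.216, 0.494, 0.722,
  0.302, 0.686, 0.290,
  0.596, 0.306, 0.639,
  1.000, 0.498, 0.000,
  1.000, 1.000, 0.200,
  0.651, 0.337, 0.157,
  0.969, 0.506, 0.749,
  0.600, 0.600, 0.600,
  0.121, 0.471, 0.706,
  0.682, 0.780, 0.910,
  0.090, 0.745, 0.812), ncol = 3, byrow = TRUE)

#' Classify every pixel of a cube
#'
#' Slides the model over all pixels: each pixel is classified from the
#' mirror-padded patch centered on it, producing a full-scene class map.
#' Optionally renders the map to a PNG with a fixed per-class palette.
#'
#' @param model an [mjhresnet] model.
#' @param cube a preprocessed [hsi_cube] whose band count matches the
#'   model's input depth.
#' @param patch_size patch side; defaults to the model's configured size.
#' @param png_path optional path; when given the map is rendered as a PNG.
#' @param class_names optional class names for the returned map.
#' @param batch_size inference batch size.
#' @return A [label_map] of predicted classes (invisibly also written as
#'   PNG when requested).
#' @export
classify_map <- function(model, cube, patch_size = NULL, png_path = NULL,
                         class_names = NULL, batch_size = 1024L) {
  stopifnot(inherits(model, "mjhresnet"), inherits(cube, "hsi_cube"))
  s <- as.integer(patch_size %||% model$config$patch_size)
  d <- dim(cube$data)
  if (d[3] != model$config$in_bands)
    stop(sprintf("cube has %d bands but model expects %d", d[3],
                 model$config$in_bands), call. = FALSE)
  all_lab <- label_map(matrix(1L, d[1], d[2]),
                       class_names = "all")
  ds <- extract_patches(cube, all_lab, s)
  pred <- predict(model, ds$patches, batch_size = batch_size)
  out <- matrix(0L, d[1], d[2])
  out[ds$coords] <- pred
  map <- label_map(out, class_names = class_names %||%
                     paste0("class_", seq_len(model$config$n_classes)))
  if (!is.null(png_path)) {
    img <- array(0, c(d[1], d[2], 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(.class_palette[(out - 1L) %%
                                             nrow(.class_palette) + 1L, ch],
                            d[1], d[2])
    png::writePNG(img, png_path)
  }
  map
}
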