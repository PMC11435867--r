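# Center-labeled patch extraction and the stratified train/test split.
# Every labeled (nonzero) pixel yields exactly one s x s x d patch centered
# on it; scene borders are mirror-padded (reflection about the edge pixel,
# which never duplicates the edge and never injects unlabeled values).

mirror_index <- function(n, pad) {
  idx <- (1L - pad):(n + pad)
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  ifelse(idx > n, 2L * n - idx, idx)
}

#' Extract center-labeled patches from a cube
#'
#' @param cube a preprocessed [hsi_cube] of `d` bands.
#' @param labels a [label_map] aligned to the cube; every pixel with a
#'   nonzero label becomes a patch center.
#' @param patch_size odd patch side `s`, at most `min(rows, cols)`.
#' @return An object of class `patch_dataset`: `patches`
#'   (`N x s x s x d` array), `labels` (center-pixel class per patch),
#'   `coords` (`N x 2` matrix of center row/col), `split` (factor,
#'   initially all `"train"` until [split_patches()] is applied),
#'   `patch_size`, `class_names`.
#' @export
extract_patches <- function(cube, labels, patch_size = 9L) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(labels, "label_map"))
  check_aligned(cube, labels)
  s <- as.integer(patch_size)
  if (s %% 2L == 0L) stop("`patch_size` must be odd", call. = FALSE)
  d <- dim(cube$data)
  if (s > min(d[1], d[2]))
    stop("`patch_size` exceeds the scene extent", call. = FALSE)
  lab <- labels$labels
  centers <- which(lab > 0L, arr.ind = TRUE)
  if (nrow(centers) == 0L)
    stop("no labeled pixels: empty dataset", call. = FALSE)
  pad <- (s - 1L) %/% 2L
  ri <- mirror_index(d[1], pad)
  ci <- mirror_index(d[2], pad)
  padded <- cube$data[ri, ci, , drop = FALSE]
  N <- nrow(centers)
  patches <- array(0, c(N, s, s, d[3]))
  off <- 0:(s - 1L)
  for (i in seq_len(N)) {
    # center (r, c) sits at padded index (r + pad, c + pad)
    patches[i, , , ] <- padded[centers[i, 1] + off, centers[i, 2] + off, ,
                               drop = FALSE]
  }
  structure(list(patches = patches,
                 labels = as.integer(lab[centers]),
                 coords = unname(centers),
                 split = factor(rep("train", N),
                                levels = c("train", "test")),
                 patch_size = s,
                 class_names = labels$class_names),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches of %d x %d x %d\n",
              length(x$labels), x$patch_size, x$patch_size,
              dim(x$patches)[4]))
  tab <- table(class = x$labels, split = x$split)
  print(tab)
  invisible(x)
}

#' @export
length.patch_dataset <- function(x) length(x$labels)

#' Stratified train/test split
#'
#' Assigns each patch to the training or test set, stratified per class:
#' every class contributes `round(train_fraction * class_count)` training
#' patches (at least 1), drawn uniformly at random under the given seed.
#' The split is a partition (train and test are disjoint and exhaustive)
#' and deterministic for a fixed seed.
#'
#' @param dataset a [extract_patches()] dataset.
#' @param train_fraction fraction of each class used for training, in
#'   `(0, 1)` (default 0.08, i.e. 8%).
#' @param seed RNG seed.
#' @return The dataset with its `split` factor assigned.
#' @export
split_patches <- function(dataset, train_fraction = 0.08, seed = 1) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  y <- dataset$labels
  split <- rep("test", length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_train <- max(1L, round(train_fraction * length(idx)))
      n_train <- min(n_train, length(idx))
      split[sample(idx, n_train)] <- "train"
    }
  })
  dataset$split <- factor(split, levels = c("train", "test"))
  dataset
}

subset_patches <- function(dataset, idx) {
  dataset$patches <- dataset$patches[idx, , , , drop = FALSE]
  dataset$labels <- dataset$labels[idx]
  dataset$coords <- dataset$coords[idx, , drop = FALSE]
  dataset$split <- dataset$split[idx]
  dataset
}
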