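# Training protocol: Adadelta on mean cross-entropy with a two-phase
# learning-rate schedule (lr_a for the first epochs_a epochs, lr_b for the
# remaining epochs_b), per-epoch reshuffling, last incomplete batch kept.
# Adadelta keeps running averages of squared gradients and squared updates
# (decay rho, epsilon eps) per parameter; the learning rate scales the
# resulting step, so the canonical parameter-free update corresponds to
# lr = 1.

#' Training configuration
#'
#' @param epochs_a,epochs_b lengths of the two schedule phases
#'   (defaults 70 and 30).
#' @param lr_a,lr_b learning rates of the two phases (defaults 1.0, 0.1).
#' @param batch_size minibatch size (default 1024).
#' @param rho Adadelta decay (default 0.9).
#' @param eps Adadelta epsilon (default 1e-6).
#' @param seed RNG seed controlling shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_a = 70L, epochs_b = 30L, lr_a = 1.0,
                         lr_b = 0.1, batch_size = 1024L, rho = 0.9,
                         eps = 1e-6, seed = 1L) {
  stopifnot(epochs_a >= 1, epochs_b >= 0, lr_a > 0, lr_b > 0,
            batch_size >= 1, rho > 0, rho < 1, eps > 0)
  structure(list(epochs_a = as.integer(epochs_a),
                 epochs_b = as.integer(epochs_b),
                 lr_a = lr_a, lr_b = lr_b,
                 batch_size = as.integer(batch_size),
                 rho = rho, eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network on a patch dataset
#'
#' Optimizes the model's parameters by Adadelta on the training split of
#' `dataset`. Deterministic for a fixed seed under single-threaded BLAS.
#' The per-epoch history records the learning rate, mean minibatch loss,
#' training accuracy (over the epoch's own forward passes), evaluation
#' accuracy (only when `eval_data` is supplied; `NA` otherwise), and wall
#' time.
#'
#' @param model an [mjhresnet] model.
#' @param dataset a [patch_dataset] with a train split (see
#'   [split_patches()]).
#' @param config a [train_config()].
#' @param eval_data optional `(N, s, s, d)` array or [patch_dataset] scored
#'   after every epoch.
#' @param eval_labels integer labels for `eval_data` (taken from the
#'   dataset when omitted).
#' @param verbose print one line per epoch.
#' @return The trained model; its `history` element is the per-epoch data
#'   frame.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        eval_data = NULL, eval_labels = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "mjhresnet"),
            inherits(dataset, "patch_dataset"),
            inherits(config, "train_config"))
  tr <- which(dataset$split == "train")
  if (length(tr) == 0L) stop("dataset has no training split", call. = FALSE)
  y <- dataset$labels[tr]
  if (max(y) > model$config$n_classes)
    stop("dataset labels exceed the model's class count", call. = FALSE)
  if (!is.null(eval_data) && inherits(eval_data, "patch_dataset")) {
    eval_labels <- eval_labels %||% eval_data$labels
    eval_data <- eval_data$patches
  }
  Eg <- tree_map(model$params, function(x) array(0, dim(x) %||% length(x)))
  Ed <- tree_map(model$params, function(x) array(0, dim(x) %||% length(x)))
  total_epochs <- config$epochs_a + config$epochs_b
  hist <- data.frame(epoch = seq_len(total_epochs), lr = NA_real_,
                     loss = NA_real_, train_acc = NA_real_,
                     eval_acc = NA_real_, seconds = NA_real_)
  n_tr <- length(tr)
  with_seed(config$seed, {
    for (ep in seq_len(total_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- if (ep <= config$epochs_a) config$lr_a else config$lr_b
      ord <- sample(n_tr)
      losses <- c(); n_correct <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- tr[ord[start:min(start + config$batch_size - 1L, n_tr)]]
        nb <- length(idx)
        Xb <- patches_matrix(dataset$patches[idx, , , , drop = FALSE])
        yb <- dataset$labels[idx]
        fw <- nn_forward(model, Xb, nb, training = TRUE, keep = TRUE)
        model$stats <- fw$stats
        sm <- softmax_xent(fw$logits, yb)
        if (!is.finite(sm$loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        losses <- c(losses, sm$loss)
        n_correct <- n_correct +
          sum(max.col(fw$logits, ties.method = "first") == yb)
        grads <- nn_backward(model, fw, sm$dlogits)
        upd <- adadelta_step(model$params, grads, Eg, Ed, lr,
                             config$rho, config$eps)
        model$params <- upd$params
        Eg <- upd$Eg
        Ed <- upd$Ed
      }
      hist$lr[ep] <- lr
      hist$loss[ep] <- mean(losses)
      hist$train_acc[ep] <- n_correct / n_tr
      if (!is.null(eval_data)) {
        pred <- predict(model, eval_data, type = "class")
        hist$eval_acc[ep] <- mean(pred == eval_labels)
      }
      hist$seconds[ep] <- proc.time()[["elapsed"]] - t0
      if (verbose)
        message(sprintf(
          "epoch %3d lr %.3g loss %.4f train_acc %.4f%s (%.1fs)",
          ep, lr, hist$loss[ep], hist$train_acc[ep],
          if (is.na(hist$eval_acc[ep])) ""
          else sprintf(" eval_acc %.4f", hist$eval_acc[ep]),
          hist$seconds[ep]))
    }
  })
  model$history <- hist
  model
}

# One Adadelta update over the parameter tree; returns the new parameters
# and accumulator trees.
adadelta_step <- function(params, grads, Eg, Ed, lr, rho, eps) {
  walk <- function(p, g, eg, ed) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], eg[[i]], ed[[i]])
        p[[i]] <- r$p; eg[[i]] <- r$eg; ed[[i]] <- r$ed
      }
      return(list(p = p, eg = eg, ed = ed))
    }
    eg <- rho * eg + (1 - rho) * g * g
    delta <- -sqrt(ed + eps) / sqrt(eg + eps) * g
    ed <- rho * ed + (1 - rho) * delta * delta
    list(p = p + lr * delta, eg = eg, ed = ed)
  }
  r <- walk(params, grads, Eg, Ed)
  list(params = r$p, Eg = r$eg, Ed = r$ed)
}

#' Hyperparameter sweep over kernel/patch sizes or learning-rate pairs
#'
#' Runs one full train-and-evaluate cycle per grid row on patches drawn
#' from a single preprocessed scene, mirroring the protocol's grid search.
#' Grid columns may be any of `kernel`, `patch_size`, `lr_a`, `lr_b`,
#' `epochs_a`, `epochs_b`; omitted columns take the base configuration's
#' values. Patch datasets are re-extracted per distinct patch size, every
#' cell is seeded reproducibly from the base seed, and per-cell failures
#' are recorded rather than fatal.
#'
#' @param cube preprocessed [hsi_cube].
#' @param labels [label_map] for the cube.
#' @param grid data frame, one row per experiment.
#' @param base_model a [model_config()] supplying defaults.
#' @param base_train a [train_config()] supplying defaults.
#' @param train_fraction stratified training fraction.
#' @return A data frame with the grid settings plus `AA`, `OA`,
#'   `predict_seconds`, and a logical `best` flag on the top-AA row; sorted
#'   by AA descending.
#' @export
run_sweep <- function(cube, labels, grid, base_model = model_config(),
                      base_train = train_config(),
                      train_fraction = 0.08) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  res <- grid
  res$AA <- NA_real_; res$OA <- NA_real_
  res$predict_seconds <- NA_real_; res$error <- NA_character_
  ds_cache <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    out <- tryCatch({
      ps <- as.integer(cell$patch_size %||% base_model$patch_size)
      key <- as.character(ps)
      if (is.null(ds_cache[[key]])) {
        ds <- extract_patches(cube, labels, ps)
        ds_cache[[key]] <- split_patches(ds, train_fraction,
                                         seed = base_train$seed)
      }
      ds <- ds_cache[[key]]
      mc <- model_config(
        in_bands = dim(cube$data)[3], patch_size = ps,
        channels = base_model$channels,
        kernel = as.integer(cell$kernel %||% base_model$kernel),
        blocks_per_branch = base_model$blocks_per_branch,
        se_reduction = base_model$se_reduction,
        n_classes = base_model$n_classes, variant = base_model$variant)
      tc <- train_config(
        epochs_a = cell$epochs_a %||% base_train$epochs_a,
        epochs_b = cell$epochs_b %||% base_train$epochs_b,
        lr_a = cell$lr_a %||% base_train$lr_a,
        lr_b = cell$lr_b %||% base_train$lr_b,
        batch_size = base_train$batch_size, rho = base_train$rho,
        eps = base_train$eps, seed = base_train$seed + i)
      m <- mjhresnet(mc, seed = base_train$seed + i)
      m <- train_model(m, ds, tc)
      te <- which(ds$split == "test")
      t0 <- proc.time()[["elapsed"]]
      pred <- predict(m, ds$patches[te, , , , drop = FALSE])
      pt <- proc.time()[["elapsed"]] - t0
      cm <- confusion_matrix(ds$labels[te], pred,
                             n_classes = mc$n_classes)
      agg <- aggregate_accuracy(cm)
      list(AA = agg$AA, OA = agg$OA, pt = pt)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$error[i] <- conditionMessage(out)
    } else {
      res$AA[i] <- out$AA; res$OA[i] <- out$OA
      res$predict_seconds[i] <- out$pt
    }
  }
  res <- res[order(-res$AA, na.last = TRUE), , drop = FALSE]
  res$best <- FALSE
  if (any(!is.na(res$AA))) res$best[1] <- TRUE
  rownames(res) <- NULL
  res
}
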