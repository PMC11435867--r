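# The network: an initial valid convolution (Conv0), a double-hierarchical
# residual (DHR) structure, squeeze-and-excitation (SE) channel attention,
# global average pooling, and a linear classifier head.
#
# A hierarchical block with branches C_1..C_B maps its input x to
#   y_0 = x,  y_1 = C_1(x),  y_b = C_b(x + y_{b-1})  for b >= 2,
#   output = sum_b y_b ,
# so each successive branch sees the input enriched by the previous
# branch, widening the receptive field while the identity path prevents
# gradient vanishing. Each conv branch is `blocks_per_branch` pre-activation
# units (BN -> ReLU -> Conv), channel- and spatial-size-preserving; with
# all convolution weights zero every branch output is zero and the block
# is the identity. The DHR chains a 4-conv-branch block (output xp) with a
# 2-conv-branch block (output Y, whose second branch uses 1x1 kernels);
# the SE block then acts on the channel concatenation [xp || Y].

#' Architecture configuration
#'
#' @param in_bands spectral depth `d` of input patches (default 16, the
#'   retained PCA dimension).
#' @param patch_size spatial patch side `s` (odd; default 9).
#' @param channels feature channels `C0` after Conv0 (default 64).
#' @param kernel convolution kernel side for Conv0 and the 2-d branches
#'   (odd; 3, 5, or 7; default 3).
#' @param blocks_per_branch BN-ReLU-Conv units per convolutional branch
#'   (default 6).
#' @param se_reduction SE bottleneck reduction ratio `r` (default 16); must
#'   divide the SE input channel count.
#' @param n_classes number of output classes (default 9).
#' @param variant architecture variant: `"full"` (DHR + SE), `"dhr_only"`
#'   (DHR without SE), `"first_block_only"` (single 4-branch hierarchical
#'   block + SE on `C0` channels), `"single_multibranch"` (one hierarchical
#'   block with 6 conv branches + SE on `C0` channels). The variants mirror
#'   the ablation study.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_bands = 16, patch_size = 9, channels = 64,
                         kernel = 3, blocks_per_branch = 6,
                         se_reduction = 16, n_classes = 9,
                         variant = c("full", "dhr_only", "first_block_only",
                                     "single_multibranch")) {
  variant <- match.arg(variant)
  if (kernel %% 2 == 0) stop("`kernel` must be odd", call. = FALSE)
  if (patch_size %% 2 == 0) stop("`patch_size` must be odd", call. = FALSE)
  if (patch_size < kernel)
    stop("`patch_size` must be at least `kernel`", call. = FALSE)
  stopifnot(in_bands >= 1, channels >= 1, blocks_per_branch >= 1,
            se_reduction >= 1, n_classes >= 2)
  cfg <- structure(list(in_bands = as.integer(in_bands),
                        patch_size = as.integer(patch_size),
                        channels = as.integer(channels),
                        kernel = as.integer(kernel),
                        blocks_per_branch = as.integer(blocks_per_branch),
                        se_reduction = as.integer(se_reduction),
                        n_classes = as.integer(n_classes),
                        variant = variant),
                   class = "model_config")
  plan <- arch_plan(cfg)
  if (plan$has_se && plan$concat_channels %% cfg$se_reduction != 0)
    stop("`se_reduction` must divide the SE input channel count (",
         plan$concat_channels, ")", call. = FALSE)
  cfg
}

# Internal layout: kernel sizes of each conv branch per hierarchical block.
arch_plan <- function(cfg) {
  k <- cfg$kernel
  switch(cfg$variant,
    full = list(blocks = list(c(k, k, k, k), c(k, 1L)),
                concat = TRUE, has_se = TRUE,
                concat_channels = 2L * cfg$channels),
    dhr_only = list(blocks = list(c(k, k, k, k), c(k, 1L)),
                    concat = TRUE, has_se = FALSE,
                    concat_channels = 2L * cfg$channels),
    first_block_only = list(blocks = list(c(k, k, k, k)),
                            concat = FALSE, has_se = TRUE,
                            concat_channels = cfg$channels),
    single_multibranch = list(blocks = list(c(k, k, k, k, k, 1L)),
                              concat = FALSE, has_se = TRUE,
                              concat_channels = cfg$channels))
}

kaiming <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build a network
#'
#' Instantiates the architecture described by a [model_config()].
#' Convolutions use Kaiming fan-in initialization and carry no bias (each
#' is followed by batch-norm, initialized at unit scale / zero shift); the
#' final linear head has a bias. Two components start at zero so the
#' network is the identity-plus-calibrated-head at initialization: the
#' *last* convolution of every residual branch (each hierarchical block
#' therefore begins as an identity map and the branches activate as their
#' output layers move off zero) and the classifier head (the initial loss
#' is exactly `log(n_classes)`). This identity-at-init scheme is standard
#' for residual networks and matters here because the training protocol
#' runs few optimizer steps.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `mjhresnet`: `config`, `params` (nested list
#'   of weight arrays), `stats` (batch-norm running statistics), `history`
#'   (`NULL` until trained).
#' @examples
#' m <- mjhresnet(model_config(in_bands = 4, channels = 8, se_reduction = 4,
#'                             blocks_per_branch = 1))
#' count_parameters(m)
#' @export
mjhresnet <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  plan <- arch_plan(config)
  C0 <- config$channels
  with_seed(seed, {
    params <- list()
    stats <- list()
    params$conv0 <- kaiming(config$kernel^2 * config$in_bands, C0,
                            config$kernel^2 * config$in_bands)
    for (bi in seq_along(plan$blocks)) {
      kernels <- plan$blocks[[bi]]
      blk <- list(); blk_stats <- list()
      for (br in seq_along(kernels)) {
        kk <- kernels[br]
        units <- list(); u_stats <- list()
        for (u in seq_len(config$blocks_per_branch)) {
          units[[u]] <- list(gamma = rep(1, C0), beta = rep(0, C0),
                             W = kaiming(kk^2 * C0, C0, kk^2 * C0))
          u_stats[[u]] <- list(mean = rep(0, C0), var = rep(1, C0))
        }
        # identity-at-init: the branch contributes nothing until trained
        units[[config$blocks_per_branch]]$W[] <- 0
        blk[[br]] <- units
        blk_stats[[br]] <- u_stats
      }
      params[[paste0("block", bi)]] <- blk
      stats[[paste0("block", bi)]] <- blk_stats
    }
    Cse <- plan$concat_channels
    if (plan$has_se) {
      mid <- Cse %/% config$se_reduction
      params$se <- list(W1 = kaiming(Cse, mid, Cse), b1 = rep(0, mid),
                        W2 = kaiming(mid, Cse, mid), b2 = rep(0, Cse))
    }
    # zero head: uniform class scores at init, loss starts at log(C)
    params$fc <- list(W = matrix(0, Cse, config$n_classes),
                      b = rep(0, config$n_classes))
    structure(list(config = config, params = params, stats = stats,
                   history = NULL),
              class = "mjhresnet")
  })
}

branch_kernel_pad <- function(kk) if (kk == 1L) 0L else (kk - 1L) %/% 2L

# One convolutional branch: blocks_per_branch x (BN -> ReLU -> Conv).
branch_fwd <- function(X, units, u_stats, kk, N, H, W, training, keep) {
  pad <- branch_kernel_pad(kk)
  caches <- if (keep) vector("list", length(units)) else NULL
  cur <- X
  for (u in seq_along(units)) {
    p <- units[[u]]
    bn <- bn_fwd(cur, p$gamma, p$beta, u_stats[[u]], training)
    u_stats[[u]] <- bn$stats
    act <- relu(bn$out)
    cur <- conv_fwd(act, p$W, N, H, W, kk, pad)
    if (keep) caches[[u]] <- list(bn = bn$cache, act = act)
  }
  list(out = cur, caches = caches, stats = u_stats)
}

branch_bwd <- function(dout, units, caches, kk, N, H, W) {
  pad <- branch_kernel_pad(kk)
  g <- vector("list", length(units))
  cur <- dout
  for (u in rev(seq_along(units))) {
    p <- units[[u]]
    cc <- caches[[u]]
    cv <- conv_bwd(cur, cc$act, p$W, N, H, W, kk, pad)
    dact <- cv$dX * (cc$act > 0)
    bb <- bn_bwd(dact, cc$bn, p$gamma)
    g[[u]] <- list(gamma = bb$dgamma, beta = bb$dbeta, W = cv$dW)
    cur <- bb$dX
  }
  list(dX = cur, grads = g)
}

# Hierarchical block: y0 = x, y1 = C1(x), y_b = C_b(x + y_{b-1}), sum.
block_fwd <- function(X, branches, b_stats, kernels, N, H, W, training, keep) {
  B <- length(branches)
  S <- X
  prev <- NULL
  caches <- if (keep) vector("list", B) else NULL
  for (b in seq_len(B)) {
    inp <- if (b == 1L) X else X + prev
    r <- branch_fwd(inp, branches[[b]], b_stats[[b]], kernels[b],
                    N, H, W, training, keep)
    b_stats[[b]] <- r$stats
    if (keep) caches[[b]] <- r$caches
    prev <- r$out
    S <- S + prev
  }
  list(out = S, caches = caches, stats = b_stats)
}

block_bwd <- function(dout, branches, caches, kernels, N, H, W) {
  B <- length(branches)
  g <- vector("list", B)
  dX <- dout            # identity path y0
  carry <- NULL         # gradient into y_b coming from branch b+1's input
  for (b in rev(seq_len(B))) {
    gy <- if (is.null(carry)) dout else dout + carry
    r <- branch_bwd(gy, branches[[b]], caches[[b]], kernels[b], N, H, W)
    g[[b]] <- r$grads
    dX <- dX + r$dX
    carry <- r$dX
  }
  list(dX = dX, grads = g)
}

# Full forward pass. X: (N, s, s, d) array already converted to the
# (N*s*s, d) matrix via patches_matrix(). Returns logits and, if keep,
# every cache needed for the backward pass; if training, updated BN stats.
nn_forward <- function(model, X, N, training = FALSE, keep = FALSE) {
  cfg <- model$config
  plan <- arch_plan(cfg)
  p <- model$params
  s <- cfg$patch_size
  H <- s - cfg$kernel + 1L
  HW <- H * H
  cache <- list()
  xn <- conv_fwd(X, p$conv0, N, s, s, cfg$kernel, 0L)
  if (keep) cache$X0 <- X
  stats <- model$stats
  outs <- vector("list", length(plan$blocks))
  cur <- xn
  for (bi in seq_along(plan$blocks)) {
    nm <- paste0("block", bi)
    r <- block_fwd(cur, p[[nm]], stats[[nm]], plan$blocks[[bi]],
                   N, H, H, training, keep)
    stats[[nm]] <- r$stats
    if (keep) cache[[paste0("caches", bi)]] <- r$caches
    outs[[bi]] <- r$out
    cur <- r$out
  }
  Z <- if (plan$concat) cbind(outs[[1]], outs[[2]]) else outs[[1]]
  if (keep) cache$outs <- outs
  if (plan$has_se) {
    se <- se_fwd(Z, p$se, N, HW)
    if (keep) { cache$Z <- Z; cache$se <- se$cache }
    Zs <- se$out
  } else Zs <- Z
  grp <- rep(seq_len(N), each = HW)
  pool <- unname(rowsum(Zs, grp)) / HW
  if (keep) cache$pool <- pool
  logits <- pool %*% p$fc$W + rep(p$fc$b, each = N)
  list(logits = logits, cache = cache, stats = stats,
       dims = list(N = N, H = H, HW = HW))
}

nn_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  plan <- arch_plan(cfg)
  p <- model$params
  cache <- fw$cache
  N <- fw$dims$N; H <- fw$dims$H; HW <- fw$dims$HW
  grads <- list()
  grads$fc <- list(W = crossprod(cache$pool, dlogits),
                   b = colSums(dlogits))
  dpool <- tcrossprod(dlogits, p$fc$W)
  grp <- rep(seq_len(N), each = HW)
  dZs <- dpool[grp, , drop = FALSE] / HW
  if (plan$has_se) {
    sb <- se_bwd(dZs, cache$Z, p$se, cache$se, HW)
    grads$se <- list(W1 = sb$dW1, b1 = sb$db1, W2 = sb$dW2, b2 = sb$db2)
    dZ <- sb$dX
  } else dZ <- dZs
  C0 <- cfg$channels
  if (plan$concat) {
    dxp_direct <- dZ[, seq_len(C0), drop = FALSE]
    dY <- dZ[, C0 + seq_len(C0), drop = FALSE]
    b2 <- block_bwd(dY, p$block2, cache$caches2, plan$blocks[[2]], N, H, H)
    grads$block2 <- b2$grads
    dxp <- dxp_direct + b2$dX
  } else dxp <- dZ
  b1 <- block_bwd(dxp, p$block1, cache$caches1, plan$blocks[[1]], N, H, H)
  grads$block1 <- b1$grads
  dxn <- b1$dX
  cv <- conv_bwd(dxn, cache$X0, p$conv0, N, cfg$patch_size, cfg$patch_size,
                 cfg$kernel, 0L, need_dx = FALSE)
  grads$conv0 <- cv$dW
  # order grads like params for tree operations
  grads[names(model$params)]
}

# (N, s, s, d) array -> (N*s*s, d) matrix in the engine's row order.
patches_matrix <- function(arr) {
  d <- dim(arr)
  m <- aperm(arr, c(3, 2, 1, 4))
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

#' Count trainable parameters
#'
#' Counts every independently trainable scalar in the model: convolution
#' and linear weights, linear and SE biases, and batch-norm scale/shift
#' pairs. Batch-norm running statistics are not trainable and are not
#' counted.
#'
#' @param model an [mjhresnet] model.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mjhresnet"))
  tree_sum(model$params, length)
}

#' Per-layer summary and parameter accounting
#'
#' Prints a per-layer table (layer, output shape, kernel, parameter count)
#' mirroring the architecture plan, with the total in raw and in millions.
#' When `reference_total_m` is given the residual against that published
#' total is reported, making the reconciliation (or the remaining
#' discrepancy) explicit.
#'
#' @param model an [mjhresnet] model.
#' @param reference_total_m optional published parameter total in millions
#'   to compare against.
#' @return The summary data frame, invisibly.
#' @export
model_summary <- function(model, reference_total_m = NULL) {
  stopifnot(inherits(model, "mjhresnet"))
  cfg <- model$config
  plan <- arch_plan(cfg)
  s <- cfg$patch_size
  H <- s - cfg$kernel + 1L
  C0 <- cfg$channels
  rows <- list()
  add <- function(layer, shape, kernel, n)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, output = shape,
                                             kernel = kernel, params = n)
  add("input", sprintf("%d x %d x %d", s, s, cfg$in_bands), "", 0L)
  add("conv0", sprintf("%d x %d x %d", H, H, C0),
      sprintf("%d x %d x %d", cfg$kernel, cfg$kernel, cfg$in_bands),
      length(model$params$conv0))
  br_id <- 0L
  for (bi in seq_along(plan$blocks)) {
    kernels <- plan$blocks[[bi]]
    for (br in seq_along(kernels)) {
      br_id <- br_id + 1L
      n <- tree_sum(model$params[[paste0("block", bi)]][[br]], length)
      add(sprintf("block%d.branch%d (%d units)", bi, br,
                  cfg$blocks_per_branch),
          sprintf("%d x %d x %d", H, H, C0),
          sprintf("%d x %d x %d", kernels[br], kernels[br], C0), n)
    }
  }
  Cse <- plan$concat_channels
  if (plan$has_se)
    add(sprintf("se (r = %d)", cfg$se_reduction),
        sprintf("%d x %d x %d", H, H, Cse), "",
        tree_sum(model$params$se, length))
  add("avg_pool", sprintf("1 x 1 x %d", Cse),
      sprintf("%d x %d", H, H), 0L)
  add("fc", sprintf("%d", cfg$n_classes), "",
      tree_sum(model$params$fc, length))
  df <- do.call(rbind, rows)
  total <- sum(df$params)
  cat(sprintf("mjhresnet variant '%s'\n", cfg$variant))
  print(df, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d (%.2f M)\n",
              total, total / 1e6))
  if (!is.null(reference_total_m)) {
    resid <- total / 1e6 - reference_total_m
    cat(sprintf("reference total: %.2f M; residual: %+.3f M (%+.1f%%)\n",
                reference_total_m, resid, 100 * resid / reference_total_m))
  }
  attr(df, "total") <- total
  invisible(df)
}

#' Layer-by-layer shape trace of a forward pass
#'
#' @param model an [mjhresnet] model.
#' @return A data frame of layer names and output shapes
#'   `c(height, width, channels)` for one input patch.
#' @export
shape_trace <- function(model) {
  cfg <- model$config
  plan <- arch_plan(cfg)
  s <- cfg$patch_size
  H <- s - cfg$kernel + 1L
  C0 <- cfg$channels
  Cse <- plan$concat_channels
  out <- list(
    input = c(s, s, cfg$in_bands),
    conv0 = c(H, H, C0))
  for (bi in seq_along(plan$blocks))
    for (br in seq_along(plan$blocks[[bi]]))
      out[[sprintf("block%d.branch%d", bi, br)]] <- c(H, H, C0)
  if (plan$has_se) out$se_input <- c(H, H, Cse)
  out$avg_pool <- c(1L, 1L, Cse)
  out$output <- c(1L, 1L, cfg$n_classes)
  data.frame(layer = names(out),
             height = vapply(out, `[`, numeric(1), 1),
             width = vapply(out, `[`, numeric(1), 2),
             channels = vapply(out, `[`, numeric(1), 3))
}

#' @export
print.mjhresnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mjhresnet> variant '%s': %dx%dx%d patches -> %d classes, %d params\n",
    cfg$variant, cfg$patch_size, cfg$patch_size, cfg$in_bands,
    cfg$n_classes, count_parameters(x)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.mjhresnet <- function(object, ...) {
  model_summary(object, ...)
}

#' Predict classes for patches
#'
#' Runs the deterministic inference forward pass (batch-norm in running-
#' statistics mode) over patches in batches.
#'
#' @param object an [mjhresnet] model.
#' @param newdata a [extract_patches()] dataset, an `(N, s, s, d)` array,
#'   or a single `(s, s, d)` patch.
#' @param type `"class"` for integer labels, `"prob"` for softmax
#'   probabilities, `"score"` for raw logits.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return Integer vector, or an `N x n_classes` matrix for
#'   `"prob"`/`"score"`.
#' @export
predict.mjhresnet <- function(object, newdata, type = c("class", "prob",
                                                        "score"),
                              batch_size = 512L, ...) {
  type <- match.arg(type)
  arr <- if (inherits(newdata, "patch_dataset")) newdata$patches else newdata
  if (length(dim(arr)) == 3L) arr <- array(arr, c(1L, dim(arr)))
  stopifnot(length(dim(arr)) == 4L)
  cfg <- object$config
  if (dim(arr)[2] != cfg$patch_size || dim(arr)[4] != cfg$in_bands)
    stop(sprintf("patches are %dx%dx%d but model expects %dx%dx%d",
                 dim(arr)[2], dim(arr)[3], dim(arr)[4],
                 cfg$patch_size, cfg$patch_size, cfg$in_bands),
         call. = FALSE)
  N <- dim(arr)[1]
  scores <- matrix(0, N, cfg$n_classes)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    Xb <- patches_matrix(arr[idx, , , , drop = FALSE])
    scores[idx, ] <- nn_forward(object, Xb, length(idx))$logits
  }
  switch(type,
         score = scores,
         prob = {
           ex <- exp(scores - apply(scores, 1, max))
           ex / rowSums(ex)
         },
         class = max.col(scores, ties.method = "first"))
}
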