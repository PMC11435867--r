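# Shared fixtures: tiny cubes, a tiny network configuration, and naive
# reference implementations used as independent oracles. The naive code
# paths (nested-loop convolution, per-sample metric tallies) deliberately
# share nothing with the package's vectorized implementations.

tiny_cube <- function(rows = 4, cols = 5, bands = 3, seed = 1) {
  set.seed(seed)
  hsi_cube(array(runif(rows * cols * bands), c(rows, cols, bands)))
}

tiny_model_config <- function(...) {
  args <- list(in_bands = 3, patch_size = 5, channels = 4, kernel = 3,
               blocks_per_branch = 2, se_reduction = 4, n_classes = 3)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

# Naive valid/padded 2-d convolution of a single sample.
# x: (H, W, Cin) array; W_mat: (k*k*Cin, Cout) in the engine's column
# order (kernel offset major, input channel minor).
naive_conv <- function(x, W_mat, k, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- ncol(W_mat)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  xp <- array(0, c(Hp, Wp, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- Hp - k + 1; Wo <- Wp - k + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    patch <- numeric(k * k * Cin)
    m <- 0
    for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
      patch[m * Cin + seq_len(Cin)] <- xp[i + dy, j + dx, ]
      m <- m + 1
    }
    out[i, j, ] <- as.vector(patch %*% W_mat)
  }
  out
}

# Naive batch norm with batch statistics over a list of (H, W, C) arrays.
naive_bn <- function(xs, gamma, beta, eps = 1e-5) {
  C <- dim(xs[[1]])[3]
  vals <- lapply(seq_len(C), function(c)
    unlist(lapply(xs, function(x) x[, , c])))
  mu <- vapply(vals, mean, numeric(1))
  v <- vapply(seq_len(C), function(c) mean((vals[[c]] - mu[c])^2),
              numeric(1))
  lapply(xs, function(x) {
    out <- x
    for (c in seq_len(C))
      out[, , c] <- gamma[c] * (x[, , c] - mu[c]) / sqrt(v[c] + eps) +
        beta[c]
    out
  })
}

naive_relu <- function(xs) lapply(xs, function(x) pmax(x, 0))

# Naive branch: blocks_per_branch x (BN -> ReLU -> Conv) over a batch.
naive_branch <- function(xs, units, k, pad) {
  for (u in units) {
    xs <- naive_bn(xs, u$gamma, u$beta)
    xs <- naive_relu(xs)
    xs <- lapply(xs, naive_conv, W_mat = u$W, k = k, pad = pad)
  }
  xs
}

# Hand-unrolled hierarchical block: y0 = x, y1 = C1(x),
# y_b = C_b(x + y_{b-1}); output = sum of all y.
naive_block <- function(xs, branches, kernels) {
  B <- length(branches)
  S <- xs
  prev <- NULL
  for (b in seq_len(B)) {
    pad <- if (kernels[b] == 1) 0 else (kernels[b] - 1) / 2
    inp <- if (b == 1) xs else mapply(`+`, xs, prev, SIMPLIFY = FALSE)
    prev <- naive_branch(inp, branches[[b]], kernels[b], pad)
    S <- mapply(`+`, S, prev, SIMPLIFY = FALSE)
  }
  S
}

# Engine-layout matrix -> per-sample (H, W, C) arrays and back.
mat_to_arrays <- function(M, N, H, W) {
  lapply(seq_len(N), function(n) {
    rows <- (n - 1) * H * W + seq_len(H * W)
    x <- array(0, c(H, W, ncol(M)))
    for (i in seq_len(H)) for (j in seq_len(W))
      x[i, j, ] <- M[rows[(i - 1) * W + j], ]
    x
  })
}

arrays_to_mat <- function(xs, H, W) {
  N <- length(xs)
  M <- matrix(0, N * H * W, dim(xs[[1]])[3])
  for (n in seq_len(N)) for (i in seq_len(H)) for (j in seq_len(W))
    M[(n - 1) * H * W + (i - 1) * W + j, ] <- xs[[n]][i, j, ]
  M
}

# Per-sample tally oracle for classification metrics.
naive_metrics <- function(truth, pred, C) {
  recall <- precision <- numeric(C)
  for (c in seq_len(C)) {
    tp <- sum(truth == c & pred == c)
    fn <- sum(truth == c & pred != c)
    fp <- sum(truth != c & pred == c)
    recall[c] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision[c] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  list(recall = recall, precision = precision,
       AA = 100 * mean(recall, na.rm = TRUE),
       OA = 100 * mean(truth == pred))
}

# Linearly separable two-class patch dataset for training sanity checks.
separable_dataset <- function(n_per_class = 30, s = 5, d = 3, seed = 5) {
  set.seed(seed)
  N <- 2 * n_per_class
  arr <- array(rnorm(N * s * s * d, sd = 0.1), c(N, s, s, d))
  y <- rep(1:2, each = n_per_class)
  arr[y == 1, , , 1] <- arr[y == 1, , , 1] + 1
  arr[y == 2, , , 1] <- arr[y == 2, , , 1] - 1
  structure(list(patches = arr, labels = as.integer(y),
                 coords = cbind(seq_len(N), seq_len(N)),
                 split = factor(rep("train", N),
                                levels = c("train", "test")),
                 patch_size = s, class_names = c("a", "b")),
            class = "patch_dataset")
}

# Fill every parameter leaf with nontrivial random values (the package's
# own init zeroes branch-final convolutions and the head, which would make
# oracle comparisons vacuous).
randomize_params <- function(model, seed = 1, sd = 0.3) {
  set.seed(seed)
  model$params <- cottonhsi:::tree_map(model$params, function(x) {
    x[] <- rnorm(length(x), sd = sd)
    x
  })
  model
}

get_leaf <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

set_leaf <- function(x, path, i, v) {
  if (length(path) == 1) {
    x[[path[[1]]]][i] <- v
    return(x)
  }
  x[[path[[1]]]] <- set_leaf(x[[path[[1]]]], path[-1], i, v)
  x
}
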