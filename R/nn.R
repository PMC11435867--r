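# Neural-network primitives. Activations are dense matrices of shape
# (N*H*W, channels) with row index (n-1)*H*W + (i-1)*W + j, so every
# convolution is one BLAS matrix product over an im2col gather. The hot
# kernels (im2col/col2im convolution, batch norm) are compiled
# (src/nn_ops.cpp); the surrounding structure, the SE block, the loss, and
# the optimizer live here. All arithmetic is double precision; forward
# passes are deterministic and backward passes are exact analytic
# gradients (verified against finite differences in the tests).

# X: (N*H*W, Cin); Wt: (k*k*Cin, Cout). Returns (N*Ho*Wo, Cout).
conv_fwd <- function(X, Wt, N, H, W, k, pad) {
  cpp_conv_fwd(X, Wt, N, H, W, k, pad)
}

# Gradients of conv_fwd; X is the saved layer input.
conv_bwd <- function(dout, X, Wt, N, H, W, k, pad, need_dx = TRUE) {
  cpp_conv_bwd(dout, X, Wt, N, H, W, k, pad, need_dx)
}

.BN_EPS <- 1e-5

# Batch normalization over channels (columns). In training mode the batch
# mean and population variance are used and running statistics updated; in
# inference mode the running statistics are used.
bn_fwd <- function(X, gamma, beta, stats, training, momentum = 0.1) {
  if (training) {
    r <- cpp_bn_fwd_train(X, gamma, beta, .BN_EPS)
    stats$mean <- (1 - momentum) * stats$mean + momentum * as.vector(r$mean)
    stats$var <- (1 - momentum) * stats$var + momentum * as.vector(r$var)
    list(out = r$out, cache = list(xhat = r$xhat, inv = r$inv),
         stats = stats)
  } else {
    list(out = cpp_bn_fwd_eval(X, gamma, beta, stats$mean, stats$var,
                               .BN_EPS),
         cache = NULL, stats = stats)
  }
}

bn_bwd <- function(dout, cache, gamma) {
  r <- cpp_bn_bwd(dout, cache$xhat, cache$inv, gamma)
  list(dX = r$dX, dgamma = as.vector(r$dgamma),
       dbeta = as.vector(r$dbeta))
}

relu <- function(X) cpp_relu(X)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Squeeze-and-excitation channel attention on a (N*HW, C) map.
se_fwd <- function(X, p, N, HW) {
  grp <- rep(seq_len(N), each = HW)
  z <- unname(rowsum(X, grp)) / HW         # (N, C) squeeze
  h <- z %*% p$W1 + rep(p$b1, each = N)
  hr <- relu(h)
  u <- hr %*% p$W2 + rep(p$b2, each = N)
  s <- sigmoid(u)                          # gates in (0, 1)
  out <- X * s[grp, , drop = FALSE]
  list(out = out, cache = list(z = z, h = h, hr = hr, s = s, grp = grp))
}

se_bwd <- function(dout, X, p, cache, HW) {
  grp <- cache$grp
  s <- cache$s
  dX <- dout * s[grp, , drop = FALSE]
  ds <- rowsum(dout * X, grp)
  du <- ds * s * (1 - s)
  dW2 <- crossprod(cache$hr, du)
  db2 <- colSums(du)
  dhr <- tcrossprod(du, p$W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$z, dh)
  db1 <- colSums(dh)
  dz <- tcrossprod(dh, p$W1)
  dX <- dX + dz[grp, , drop = FALSE] / HW
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# Mean cross-entropy of logits (N, C) against integer labels 1..C.
softmax_xent <- function(logits, y) {
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  prob <- ex / rowSums(ex)
  n <- nrow(logits)
  picked <- prob[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- prob
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, prob = prob, dlogits = dlogits / n)
}

# Apply f over one or two parallel nested list trees.
tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else f(a)
}

tree_sum <- function(a, f) {
  if (is.list(a)) sum(vapply(a, tree_sum, numeric(1), f = f)) else f(a)
}
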