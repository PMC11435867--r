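test_that("conv0 performs a valid convolution with the configured kernel", {
  m <- mjhresnet(tiny_model_config(), seed = 1)
  N <- 2
  set.seed(3)
  arr <- array(rnorm(N * 5 * 5 * 3), c(N, 5, 5, 3))
  X <- cottonhsi:::patches_matrix(arr)
  out <- cottonhsi:::conv_fwd(X, m$params$conv0, N, 5, 5, 3, 0L)
  expect_equal(dim(out), c(N * 3 * 3, 4))
  # against the naive per-pixel convolution
  for (n in 1:N) {
    ref <- naive_conv(arr[n, , , ], m$params$conv0, 3, 0)
    got <- mat_to_arrays(out, N, 3, 3)[[n]]
    expect_equal(got, ref, tolerance = 1e-12)
  }
  # zero weights give a zero map; 13x13 patch with k=7 gives 7x7
  expect_true(all(cottonhsi:::conv_fwd(X, m$params$conv0 * 0, N, 5, 5, 3,
                                       0L) == 0))
  cfg13 <- model_config(in_bands = 2, patch_size = 13, channels = 4,
                        kernel = 7, blocks_per_branch = 1,
                        se_reduction = 4, n_classes = 3)
  m13 <- mjhresnet(cfg13, seed = 2)
  tr <- shape_trace(m13)
  expect_equal(unlist(tr[tr$layer == "conv0", c("height", "width")]),
               c(height = 7, width = 7))
})

test_that("zero convolution weights make the DHR an identity map", {
  for (variant in c("full", "dhr_only", "first_block_only",
                    "single_multibranch")) {
    m <- mjhresnet(tiny_model_config(variant = variant), seed = 4)
    for (bn in grep("^block", names(m$params), value = TRUE))
      for (br in seq_along(m$params[[bn]]))
        for (u in seq_along(m$params[[bn]][[br]]))
          m$params[[bn]][[br]][[u]]$W[] <- 0
    N <- 3
    set.seed(5)
    arr <- array(rnorm(N * 5 * 5 * 3), c(N, 5, 5, 3))
    X <- cottonhsi:::patches_matrix(arr)
    xn <- cottonhsi:::conv_fwd(X, m$params$conv0, N, 5, 5, 3, 0L)
    plan <- cottonhsi:::arch_plan(m$config)
    st <- m$stats$block1
    b1 <- cottonhsi:::block_fwd(xn, m$params$block1, st, plan$blocks[[1]],
                                N, 3, 3, FALSE, FALSE)
    expect_equal(b1$out, xn, tolerance = 1e-12)
    if (length(plan$blocks) > 1) {
      b2 <- cottonhsi:::block_fwd(b1$out, m$params$block2, m$stats$block2,
                                  plan$blocks[[2]], N, 3, 3, FALSE, FALSE)
      expect_equal(b2$out, xn, tolerance = 1e-12)
    }
  }
})

test_that("DHR forward matches a hand-unrolled branch-by-branch oracle", {
  cfg <- tiny_model_config()
  # nontrivial weights everywhere so the oracle exercises every unit
  m <- randomize_params(mjhresnet(cfg, seed = 6), seed = 7)
  set.seed(7)
  N <- 3
  arr <- array(rnorm(N * 5 * 5 * 3), c(N, 5, 5, 3))
  X <- cottonhsi:::patches_matrix(arr)
  xn <- cottonhsi:::conv_fwd(X, m$params$conv0, N, 5, 5, 3, 0L)
  plan <- cottonhsi:::arch_plan(cfg)
  # package path (training mode: batch statistics)
  b1 <- cottonhsi:::block_fwd(xn, m$params$block1, m$stats$block1,
                              plan$blocks[[1]], N, 3, 3, TRUE, FALSE)
  b2 <- cottonhsi:::block_fwd(b1$out, m$params$block2, m$stats$block2,
                              plan$blocks[[2]], N, 3, 3, TRUE, FALSE)
  # naive path
  xs <- mat_to_arrays(xn, N, 3, 3)
  n1 <- naive_block(xs, m$params$block1, plan$blocks[[1]])
  n2 <- naive_block(n1, m$params$block2, plan$blocks[[2]])
  expect_equal(b1$out, arrays_to_mat(n1, 3, 3), tolerance = 1e-5)
  expect_equal(b2$out, arrays_to_mat(n2, 3, 3), tolerance = 1e-5)
})

test_that("SE attention squeezes, gates in (0,1), and scales channelwise", {
  m <- mjhresnet(tiny_model_config(), seed = 8)
  N <- 2; HW <- 9; C <- 8
  # constant channels: squeeze returns the constant
  vals <- matrix(rep(seq_len(C), each = N * HW), N * HW, C)
  se <- cottonhsi:::se_fwd(vals, m$params$se, N, HW)
  expect_equal(se$cache$z, matrix(rep(seq_len(C), each = N), N, C),
               tolerance = 1e-12)
  expect_true(all(se$cache$s > 0 & se$cache$s < 1))
  # zero excitation weights: every gate is sigmoid(0) = 1/2
  p0 <- m$params$se
  p0$W1[] <- 0; p0$W2[] <- 0; p0$b1[] <- 0; p0$b2[] <- 0
  se0 <- cottonhsi:::se_fwd(vals, p0, N, HW)
  expect_equal(se0$out, vals / 2, tolerance = 1e-12)
  # random input: output/input ratio constant across spatial positions
  set.seed(9)
  Xr <- matrix(rnorm(N * HW * C), N * HW, C) + 5
  ser <- cottonhsi:::se_fwd(Xr, m$params$se, N, HW)
  ratio <- ser$out / Xr
  for (n in 1:N) {
    rows <- (n - 1) * HW + seq_len(HW)
    expect_lt(max(apply(ratio[rows, ], 2, function(v) diff(range(v)))),
              1e-12)
  }
})

test_that("forcing SE gates to one reproduces the dhr_only forward", {
  cfg_full <- tiny_model_config(variant = "full")
  cfg_dhr <- tiny_model_config(variant = "dhr_only")
  m_full <- randomize_params(mjhresnet(cfg_full, seed = 10), seed = 20)
  m_dhr <- mjhresnet(cfg_dhr, seed = 10)
  # identical trunks; neutralize the SE gating
  m_dhr$params$conv0 <- m_full$params$conv0
  m_dhr$params$block1 <- m_full$params$block1
  m_dhr$params$block2 <- m_full$params$block2
  m_dhr$params$fc <- m_full$params$fc
  m_full$params$se$W1[] <- 0
  m_full$params$se$W2[] <- 0
  m_full$params$se$b1[] <- 0
  m_full$params$se$b2[] <- 1e4   # sigmoid(1e4) == 1
  N <- 2
  set.seed(11)
  arr <- array(rnorm(N * 5 * 5 * 3), c(N, 5, 5, 3))
  s_full <- predict(m_full, arr, type = "score")
  s_dhr <- predict(m_dhr, arr, type = "score")
  expect_equal(s_full, s_dhr, tolerance = 1e-10)
})

test_that("the forward pass is deterministic and variant shapes hold", {
  m <- mjhresnet(tiny_model_config(), seed = 12)
  set.seed(13)
  patch <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  s1 <- predict(m, patch, type = "score")
  s2 <- predict(m, patch, type = "score")
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(1L, 3L))
  expect_true(all(is.finite(s1)))
  # duplicated patch gives identical rows
  two <- array(0, c(2, 5, 5, 3))
  two[1, , , ] <- patch; two[2, , , ] <- patch
  sb <- predict(m, two, type = "score")
  expect_equal(sb[1, ], sb[2, ])
  # variant head widths
  mf <- mjhresnet(tiny_model_config(variant = "first_block_only"), seed = 1)
  tr <- shape_trace(mf)
  expect_equal(tr$channels[tr$layer == "se_input"], 4)
  expect_equal(nrow(mf$params$fc$W), 4L)
  ms <- mjhresnet(tiny_model_config(variant = "single_multibranch"),
                  seed = 1)
  expect_equal(length(ms$params$block1), 6L)
  expect_error(model_config(kernel = 4), "odd")
  expect_error(tiny_model_config(se_reduction = 3), "divide")
})

test_that("parameter counts match closed-form layer sums", {
  # single conv and BN unit counts
  m1 <- mjhresnet(model_config(in_bands = 16, patch_size = 5, channels = 64,
                               blocks_per_branch = 1, se_reduction = 16,
                               n_classes = 9), seed = 1)
  expect_equal(length(m1$params$conv0), 3 * 3 * 16 * 64)
  u <- m1$params$block1[[1]][[1]]
  expect_equal(length(u$gamma) + length(u$beta), 128)
  # closed-form total for the default architecture, computed independently
  cfg <- model_config()
  conv0 <- cfg$kernel^2 * cfg$in_bands * cfg$channels
  unit3 <- 2 * cfg$channels + cfg$kernel^2 * cfg$channels^2
  unit1 <- 2 * cfg$channels + cfg$channels^2
  branches3 <- 5 * cfg$blocks_per_branch * unit3   # C1..C4, C6
  branch1 <- cfg$blocks_per_branch * unit1          # C7 (1x1)
  cse <- 2 * cfg$channels
  se <- cse * (cse / cfg$se_reduction) * 2 + cse / cfg$se_reduction + cse
  fc <- cse * cfg$n_classes + cfg$n_classes
  closed <- conv0 + branches3 + branch1 + se + fc
  m <- mjhresnet(cfg, seed = 1)
  expect_equal(count_parameters(m), closed)
  expect_equal(closed, 1147665)
  # invariant to input spatial size
  m_big <- mjhresnet(model_config(patch_size = 13), seed = 1)
  expect_equal(count_parameters(m_big), closed)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_model_config()
  m <- randomize_params(mjhresnet(cfg, seed = 42), seed = 43)
  set.seed(9)
  N <- 4
  arr <- array(rnorm(N * 5 * 5 * 3), c(N, 5, 5, 3))
  X <- cottonhsi:::patches_matrix(arr)
  y <- c(1L, 2L, 3L, 1L)
  fw <- cottonhsi:::nn_forward(m, X, N, training = TRUE, keep = TRUE)
  sm <- cottonhsi:::softmax_xent(fw$logits, y)
  gr <- cottonhsi:::nn_backward(m, fw, sm$dlogits)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    f2 <- cottonhsi:::nn_forward(m2, X, N, training = TRUE)
    cottonhsi:::softmax_xent(f2$logits, y)$loss
  }
  h <- 1e-5
  paths <- list(list("conv0"), list("block1", 1, 1, "W"),
                list("block1", 3, 2, "gamma"), list("block1", 4, 2, "beta"),
                list("block2", 2, 1, "W"), list("se", "W1"),
                list("se", "b2"), list("fc", "W"), list("fc", "b"))
  for (pth in paths) {
    pv <- get_leaf(m$params, pth)
    gv <- get_leaf(gr, pth)
    set.seed(17)
    for (i in sample(length(pv), min(3, length(pv)))) {
      lp <- lossfun(set_leaf(m$params, pth, i, pv[i] + h))
      lm <- lossfun(set_leaf(m$params, pth, i, pv[i] - h))
      num <- (lp - lm) / (2 * h)
      expect_equal(gv[i], num, tolerance = 1e-4)
    }
  }
})
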