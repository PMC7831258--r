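# structural and numerical checks on the layer library and architectures

test_that("rcin components normalize as documented", {
  set.seed(51)
  L <- 6; C <- 5
  x <- matrix(rnorm(L * L * C, mean = 3, sd = 2), L * L, C)
  # row normalization: each (row, channel) slice has mean 0, unit variance
  rn <- nn_forward(nn_rownorm(), x, L)$y
  for (ch in 1:C) {
    M <- matrix(rn[, ch], L, L)
    expect_equal(rowMeans(M), rep(0, L), tolerance = 1e-5)
    expect_equal(apply(M, 1, function(r) mean(r^2)), rep(1, L),
                 tolerance = 1e-3)
  }
  cn <- nn_forward(nn_colnorm(), x, L)$y
  M <- matrix(cn[, 1], L, L)
  expect_equal(colMeans(M), rep(0, L), tolerance = 1e-5)
  # constant input: instance-normalized component is zero
  instn <- nn_instnorm(C)
  y <- nn_forward(instn, matrix(7, L * L, C), L)$y
  expect_equal(max(abs(y)), 0)
  # full RCIN output is nonnegative (ReLU)
  rcin <- nn_rcin(C)
  expect_true(all(nn_forward(rcin, x, L)$y >= 0))
})

test_that("maxout reduces channels by grouped maxima", {
  set.seed(52)
  L <- 4
  mo <- nn_maxout(6, 3, groups = 2)
  x <- matrix(rnorm(L * L * 6), L * L, 6)
  y <- nn_forward(mo, x, L)$y
  expect_equal(ncol(y), 3L)
  # manual check: z = conv(x), max over channel-pair groups
  z <- sweep(x %*% mo$params$W, 2, mo$params$b, `+`)
  expect_equal(y[, 1], pmax(z[, 1], z[, 2]))
  expect_equal(y[, 3], pmax(z[, 5], z[, 6]))
})

test_that("se block gates channels multiplicatively in (0,1)", {
  set.seed(53)
  L <- 8; C <- 8
  se <- nn_se(C, reduction = 4)
  x <- matrix(rnorm(L * L * C) + 2, L * L, C)
  r <- nn_forward(se, x, L)
  ratio <- r$y / x
  for (ch in 1:C) {
    expect_equal(stats::sd(ratio[, ch]), 0, tolerance = 1e-9)
    expect_gt(ratio[1, ch], 0)
    expect_lt(ratio[1, ch], 1)
  }
  # zeroed bottleneck: sigmoid(0) = 0.5 exactly
  se0 <- se
  se0$params$W1[] <- 0; se0$params$b1[] <- 0
  se0$params$W2[] <- 0; se0$params$b2[] <- 0
  expect_equal(nn_forward(se0, x, L)$y, x / 2, tolerance = 1e-12)
})

test_that("built networks have the contracted structure", {
  specs <- list(network_spec("COV"), network_spec("PLM"),
                network_spec("PRE"), network_spec("OTHER"))
  blocks <- c(16L, 20L, 16L, 22L)
  chans <- c(483L, 482L, 484L, 53L)
  for (k in seq_along(specs)) {
    expect_equal(specs[[k]]$residual_blocks, blocks[k])
    expect_equal(specs[[k]]$input_channels, chans[k])
    expect_equal(specs[[k]]$trunk_width, 64L)
    expect_equal(specs[[k]]$bins, 25L)
  }
  # build desk-scale variants and introspect
  set.seed(54)
  for (k in seq_along(specs)) {
    s <- network_spec(specs[[k]]$branch, input_channels = 12,
                      trunk_width = 8, se_reduction = 4)
    m <- build_network(s)
    expect_equal(count_residual_blocks(m), blocks[k])
  }
})

test_that("forward pass emits valid dual predictions at any length", {
  set.seed(55)
  spec <- network_spec("COV", input_channels = 10, trunk_width = 8,
                       residual_blocks = 2, se_reduction = 4)
  model <- build_network(spec)
  for (L in c(8, 17)) {
    x <- array(rnorm(L * L * 10), dim = c(L, L, 10))
    pr <- predict_dual(model, x)
    expect_equal(dim(pr$real_distance), c(L, L))
    expect_equal(dim(pr$distogram), c(L, L, 25L))
    expect_true(all(pr$real_distance >= 0))
    sums <- apply(pr$distogram, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, L * L), tolerance = 1e-5)
    expect_equal(pr$real_distance, t(pr$real_distance))
  }
  # channel mismatch rejected
  bad <- array(0, dim = c(5, 5, 9))
  expect_error(predict_dual(model, bad), "channels")
})

test_that("zeroed residual bodies make the trunk a skip-path identity", {
  set.seed(56)
  spec <- network_spec("COV", input_channels = 6, trunk_width = 6,
                       residual_blocks = 3, se_reduction = 2)
  model <- build_network(spec)
  # zero every parameter inside the residual blocks (leave the stem alone)
  blocks <- model$net$layers[[1]]$layers[[2]]
  zero_layer <- function(l) {
    l$params <- lapply(l$params, function(p) { p[] <- 0; p })
    if (!is.null(l$layers)) l$layers <- lapply(l$layers, zero_layer)
    l
  }
  model$net$layers[[1]]$layers[[2]] <- zero_layer(blocks)
  L <- 5
  x <- array(abs(rnorm(L * L * 6)), dim = c(L, L, 6))
  stem_out <- nn_forward(model$net$layers[[1]]$layers[[1]],
                         matrix(x, L * L, 6), L)$y
  trunk_out <- nn_forward(model$net$layers[[1]], matrix(x, L * L, 6), L)$y
  # with zero bodies each residual block is x -> relu(x); stem output passes
  # through up to the ReLU clamps
  expect_equal(trunk_out, pmax(stem_out, 0), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for all branches", {
  set.seed(57)
  L <- 6
  truth <- generate_structure(L + 4, seed = 57)$distmap[1:L, 1:L]
  tg <- training_target(truth)
  for (b in c("COV", "PLM", "PRE", "OTHER")) {
    spec <- network_spec(b, input_channels = 7, trunk_width = 6,
                         residual_blocks = 1, se_reduction = 2,
                         dropout_rate = 0)
    model <- build_network(spec)
    x <- array(rnorm(L * L * 7), dim = c(L, L, 7))
    lg <- coevdist:::.loss_and_grad(model, x, tg, train = FALSE)
    th <- nn_flatten_params(model$net)
    idxs <- sample(length(th), 12)
    for (k in idxs) {
      e <- 1e-5
      up <- model; up$net <- nn_set_params(up$net, replace(th, k, th[k] + e))
      dn <- model; dn$net <- nn_set_params(dn$net, replace(th, k, th[k] - e))
      gnum <- (coevdist:::.loss_and_grad(up, x, tg, train = FALSE)$loss -
                 coevdist:::.loss_and_grad(dn, x, tg, train = FALSE)$loss) / (2 * e)
      expect_equal(lg$grad[k], gnum, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip predictions", {
  set.seed(58)
  spec <- network_spec("PRE", input_channels = 8, trunk_width = 8,
                       residual_blocks = 1, se_reduction = 4)
  model <- build_network(spec)
  p <- tempfile(fileext = ".json")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  L <- 7
  x <- array(rnorm(L * L * 8), dim = c(L, L, 8))
  a <- predict_dual(model, x)
  b <- predict_dual(back, x)
  expect_equal(a$real_distance, b$real_distance, tolerance = 1e-12)
  expect_equal(a$distogram, b$distogram, tolerance = 1e-12)
  expect_error(load_checkpoint(write_temp_fasta("ACD")), "checkpoint")
})
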