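test_that("masked_mse follows the 16 A masking rule", {
  truth <- matrix(c(0, 5, 20, 5, 0, 10, 20, 10, 0), 3, 3)
  tg <- training_target(truth)
  expect_false(any(tg$regression_mask[truth >= 16]))
  expect_equal(masked_mse(truth, tg), 0)
  # all true distances >= 16 -> empty mask -> 0
  far <- matrix(30, 3, 3)
  expect_equal(masked_mse(matrix(1, 3, 3), training_target(far)), 0)
  # 2x2 toy with errors 1 and 2 on the two masked (off-diagonal) pairs
  t2 <- matrix(c(0, 6, 6, 0), 2, 2)
  p2 <- matrix(c(0, 7, 8, 0), 2, 2)
  expect_equal(masked_mse(p2, training_target(t2)), mean(c(1, 4)))
  # bin labels agree with the discretizer
  expect_equal(tg$bin_labels, discretize(truth))
})

test_that("distogram_cross_entropy has the right closed forms", {
  truth <- matrix(c(0, 6, 6, 0), 2, 2)
  tg <- training_target(truth)
  L <- 2
  onehot <- array(0, dim = c(L, L, 25))
  for (i in 1:L) for (j in 1:L) onehot[i, j, tg$bin_labels[i, j]] <- 1
  expect_equal(distogram_cross_entropy(onehot, tg), 0, tolerance = 1e-9)
  unif <- array(1 / 25, dim = c(L, L, 25))
  expect_equal(distogram_cross_entropy(unif, tg), log(25))
  half <- array((1 - 0.5) / 24, dim = c(L, L, 25))
  for (i in 1:L) for (j in 1:L) half[i, j, tg$bin_labels[i, j]] <- 0.5
  expect_equal(distogram_cross_entropy(half, tg), log(2))
})

test_that("loss weights isolate the two tasks exactly", {
  set.seed(91)
  L <- 6
  spec <- network_spec("COV", input_channels = 5, trunk_width = 6,
                       residual_blocks = 1, se_reduction = 2)
  model <- build_network(spec)
  x <- array(rnorm(L * L * 5), dim = c(L, L, 5))
  tg <- training_target(generate_structure(L + 4, seed = 91)$distmap[1:L, 1:L])
  both <- coevdist:::.loss_and_grad(model, x, tg, 1, 1, train = FALSE)
  reg <- coevdist:::.loss_and_grad(model, x, tg, 1, 0, train = FALSE)
  cls <- coevdist:::.loss_and_grad(model, x, tg, 0, 1, train = FALSE)
  expect_equal(reg$loss, both$mse)
  expect_equal(cls$loss, both$ce)
  expect_equal(both$loss, both$mse + both$ce)
})

test_that("gradient flow reaches both heads", {
  set.seed(92)
  L <- 6
  spec <- network_spec("COV", input_channels = 5, trunk_width = 6,
                       residual_blocks = 1, se_reduction = 2)
  model <- build_network(spec)
  x <- array(rnorm(L * L * 5) + 1, dim = c(L, L, 5))
  tg <- training_target(generate_structure(L + 4, seed = 92)$distmap[1:L, 1:L])
  lg <- coevdist:::.loss_and_grad(model, x, tg, 1, 1, train = FALSE)
  # locate the two head parameter slices in the flat vector
  n_all <- length(lg$grad)
  n_cls <- length(nn_flatten_params(model$net$layers[[4]]))
  n_reg <- length(nn_flatten_params(model$net$layers[[3]]))
  g_cls <- lg$grad[(n_all - n_cls + 1):n_all]
  g_reg <- lg$grad[(n_all - n_cls - n_reg + 1):(n_all - n_cls)]
  expect_gt(sqrt(sum(g_reg^2)), 0)
  expect_gt(sqrt(sum(g_cls^2)), 0)
})

test_that("training descends and is deterministic given the seed", {
  set.seed(93)
  # tiny 3-target stream, 3 epochs
  ds <- suppressWarnings(                 # deliberately tight PLM budget
    make_dataset(3, L_range = c(18, 20), n_sequences = 60,
                 branches = "COV", plm_budget = 10, seed = 93))
  data <- lapply(ds$targets, function(t)
    list(input = t$inputs$COV, target = t$target))
  spec <- network_spec("COV", trunk_width = 8, residual_blocks = 1,
                       se_reduction = 4)
  sch <- training_schedule(epochs = 3, adam_epochs = 3, seed = 5)
  r1 <- suppressWarnings(train_network(build_network(spec), data, sch))
  expect_lt(r1$history$loss[3], r1$history$loss[1])
  r2 <- suppressWarnings(train_network(build_network(spec), data, sch))
  expect_equal(r1$history$loss, r2$history$loss, tolerance = 1e-6)
  # the Adam -> SGD switch keeps descending without blowing up
  sch2 <- training_schedule(epochs = 4, adam_epochs = 2, seed = 5)
  r3 <- suppressWarnings(train_network(build_network(spec), data, sch2))
  expect_true(all(is.finite(r3$history$loss)))
})

test_that("validation_score combines both heads per the protocol", {
  set.seed(94)
  L <- 40
  # scripted truth with >= L/2 long-range contacts so a perfect prediction
  # can reach precision 1.0
  truth <- matrix(20, L, L); diag(truth) <- 0
  lr <- which(upper.tri(truth) & col(truth) - row(truth) >= 24)
  planted <- sample(lr, 25)
  truth[planted] <- 6; truth <- pmin(truth, t(truth))
  onehot_of <- function(D) {
    P <- array(0, dim = c(L, L, 25))
    labs <- discretize(D)
    for (i in 1:L) for (j in 1:L) P[i, j, labs[i, j]] <- 1
    P
  }
  expect_equal(validation_score(truth, onehot_of(truth), truth), 1.0)
  # anti-perfect: closest-scored pairs are exactly the non-contacts
  anti <- truth
  anti[truth == 6] <- 20; anti[truth == 20] <- 6; diag(anti) <- 0
  expect_equal(validation_score(anti, onehot_of(anti), truth), 0)
  # short L: no long-range pairs -> NA with message
  expect_message(v <- validation_score(matrix(5, 10, 10),
                                       array(1 / 25, dim = c(10, 10, 25)),
                                       matrix(5, 10, 10)),
                 "no eligible")
  expect_true(is.na(v))
})
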