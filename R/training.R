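#' Build training targets from a true distance map
#'
#' The regression branch is supervised only where the true distance is below
#' 16 A (larger distances are neither useful nor predictable); the
#' classification branch is supervised on all 25 bins including the >= 16 A
#' bin. The diagonal is always masked out.
#'
#' @param true_distances L x L symmetric Cb-Cb distance map (A; Ca for
#'   glycine).
#' @param mask_cutoff regression mask cutoff; default 16 A.
#' @return A `training_target`: list of `true_distances`, `regression_mask`
#'   (logical L x L), `bin_labels` (integer L x L in 1..25).
#' @export
training_target <- function(true_distances, mask_cutoff = 16) {
  L <- nrow(true_distances)
  mask <- true_distances < mask_cutoff
  diag(mask) <- FALSE
  labs <- discretize(true_distances)
  structure(list(true_distances = true_distances, regression_mask = mask,
                 bin_labels = labs),
            class = "training_target")
}

#' Masked mean squared error of a real-value distance prediction
#'
#' Mean of squared A differences over masked-in pairs (true distance <
#' 16 A); 0 when the mask is empty.
#'
#' @param pred L x L predicted distance map.
#' @param target a [training_target()].
#' @return Nonnegative scalar (A^2).
#' @export
masked_mse <- function(pred, target) {
  m <- target$regression_mask
  if (!any(m)) return(0)
  mean((pred[m] - target$true_distances[m])^2)
}

#' Cross-entropy of a distogram prediction
#'
#' Mean over off-diagonal pairs of `-log p(true bin)`; probabilities are
#' clipped at `eps` to avoid infinities.
#'
#' @param pred L x L x 25 distogram.
#' @param target a [training_target()].
#' @param eps probability floor; default 1e-10.
#' @return Nonnegative scalar (nats).
#' @export
distogram_cross_entropy <- function(pred, target, eps = 1e-10) {
  L <- nrow(target$bin_labels)
  off <- which(row(target$bin_labels) != col(target$bin_labels))
  idx <- cbind(off, as.vector(target$bin_labels)[off])
  Pm <- matrix(pred, L * L, dim(pred)[3])
  -mean(log(pmax(Pm[idx], eps)))
}

#' Optimizer schedule
#'
#' Adam with learning rate 0.001 for epochs <= `adam_epochs` (default 30),
#' then momentum SGD with learning rate 0.01 and momentum 0.9; batch size is
#' fixed at 1 (one target per gradient step). `adam_epochs` shrinks for
#' desk-scale runs.
#'
#' @param epochs total epochs.
#' @param adam_epochs epochs run with Adam before the SGD switch; default 30.
#' @param adam_lr,sgd_lr,momentum optimizer constants.
#' @param seed RNG seed controlling init, shuffling and dropout.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(epochs = 40L, adam_epochs = 30L,
                              adam_lr = 0.001, sgd_lr = 0.01,
                              momentum = 0.9, seed = 1L) {
  stopifnot(adam_lr > 0, sgd_lr > 0, momentum >= 0, momentum < 1)
  list(epochs = as.integer(epochs), adam_epochs = as.integer(adam_epochs),
       adam_lr = adam_lr, sgd_lr = sgd_lr, momentum = momentum,
       batch_size = 1L, seed = as.integer(seed))
}

# per-sample loss and flat gradient through both heads
.loss_and_grad <- function(model, x, target, w_reg = 1, w_cls = 1,
                           train = TRUE) {
  fwd <- .model_forward(model, x, train = train)
  L <- fwd$L; B <- model$spec$bins
  m <- as.vector(target$regression_mask)
  nm <- sum(m)
  err <- fwd$real - as.vector(target$true_distances)
  mse <- if (nm > 0) sum((err[m])^2) / nm else 0
  d_real <- numeric(L * L)
  if (nm > 0 && w_reg != 0) d_real[m] <- w_reg * 2 * err[m] / nm
  P <- .softmax_rows(fwd$logits)
  off <- row(target$bin_labels) != col(target$bin_labels)
  offv <- as.vector(off)
  idx <- cbind(seq_len(L * L), as.vector(target$bin_labels))
  ce <- -mean(log(pmax(P[idx][offv], 1e-10)))
  d_logits <- matrix(0, L * L, B)
  if (w_cls != 0) {
    noff <- sum(offv)
    G <- P
    G[idx] <- G[idx] - 1
    G[!offv, ] <- 0
    d_logits <- w_cls * G / noff
  }
  grads <- .model_backward(model, fwd, d_real, d_logits)
  list(loss = w_reg * mse + w_cls * ce, mse = mse, ce = ce,
       grad = nn_flatten_grads(grads))
}

#' Train a dual-head network on a stream of targets
#'
#' Batch-of-1 multi-task training: combined loss `w_reg * masked MSE +
#' w_cls * distogram cross-entropy`, He-normal initialization, Adam for the
#' first `adam_epochs` epochs then momentum SGD (optimizer state is
#' re-initialized at the switch). Deterministic given `schedule$seed`. Set
#' `w_cls = 0` for the regression-only ablation (or `w_reg = 0` for
#' classification-only).
#'
#' @param model a freshly built (or resumed) `dist_network`.
#' @param dataset list of `list(input = branch_input/array, target =
#'   training_target)` entries.
#' @param schedule a [training_schedule()].
#' @param w_reg,w_cls loss weights; default 1 and 1.
#' @param validation optional dataset in the same format; when given, the
#'   top-L/2 long-range validation precision is computed each epoch and the
#'   best-scoring checkpoint is retained.
#' @param verbose print per-epoch lines? Default FALSE.
#' @return List with `model` (best validation score if validation given,
#'   else final), `history` (data.frame epoch/loss/mse/ce/val_precision),
#'   `final_model`.
#' @export
train_network <- function(model, dataset, schedule = training_schedule(),
                          w_reg = 1, w_cls = 1, validation = NULL,
                          verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  set.seed(schedule$seed)
  # He-normal re-initialization under the training seed
  model <- build_network(model$spec)
  theta <- nn_flatten_params(model$net)
  np <- length(theta)
  adam_m <- numeric(np); adam_v <- numeric(np); adam_t <- 0L
  sgd_v <- numeric(np)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), mse = numeric(0),
                     ce = numeric(0), val_precision = numeric(0))
  best <- list(score = -Inf, theta = theta)
  for (ep in seq_len(schedule$epochs)) {
    ord <- sample.int(length(dataset))
    tot <- c(loss = 0, mse = 0, ce = 0)
    for (s in ord) {
      model$net <- nn_set_params(model$net, theta)
      lg <- .loss_and_grad(model, dataset[[s]]$input, dataset[[s]]$target,
                           w_reg, w_cls, train = TRUE)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, ", sample ", s,
             " (loss = ", lg$loss, "); aborting")
      g <- lg$grad
      if (ep <= schedule$adam_epochs) {
        adam_t <- adam_t + 1L
        adam_m <- 0.9 * adam_m + 0.1 * g
        adam_v <- 0.999 * adam_v + 0.001 * g * g
        mhat <- adam_m / (1 - 0.9^adam_t)
        vhat <- adam_v / (1 - 0.999^adam_t)
        theta <- theta - schedule$adam_lr * mhat / (sqrt(vhat) + 1e-8)
      } else {
        sgd_v <- schedule$momentum * sgd_v - schedule$sgd_lr * g
        theta <- theta + sgd_v
      }
      tot <- tot + c(lg$loss, lg$mse, lg$ce)
    }
    model$net <- nn_set_params(model$net, theta)
    vp <- NA_real_
    if (!is.null(validation)) {
      vp <- mean(vapply(validation, function(v) {
        pr <- predict_dual(model, v$input)
        sc <- validation_score(pr$real_distance, pr$distogram,
                               v$target$true_distances)
        if (is.na(sc)) 0 else sc
      }, numeric(1)))
      if (vp > best$score) best <- list(score = vp, theta = theta)
    }
    avg <- tot / length(dataset)
    hist <- rbind(hist, data.frame(epoch = ep, loss = avg[["loss"]],
                                   mse = avg[["mse"]], ce = avg[["ce"]],
                                   val_precision = vp))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  mse %.4f  ce %.4f  val %.3f",
                      ep, avg[["loss"]], avg[["mse"]], avg[["ce"]], vp))
  }
  final_model <- model
  if (!is.null(validation) && is.finite(best$score)) {
    model$net <- nn_set_params(model$net, best$theta)
  }
  list(model = model, history = hist, final_model = final_model)
}

#' Top-L/2 long-range validation precision from both heads
#'
#' Converts the real-value map (1/d scores) and the distogram (summed
#' probability <= 8 A) to contact scores, min-max rescales each to [0, 1],
#' averages them, and scores top-L/2 precision at sequence separation >= 24
#' against true contacts (<= 8 A).
#'
#' @param real_map L x L predicted distances.
#' @param distogram L x L x 25 predicted distogram.
#' @param truth L x L true distance map.
#' @return Precision in [0, 1], or `NA` (with a message) when no long-range
#'   pairs exist (L < 26).
#' @export
validation_score <- function(real_map, distogram, truth) {
  L <- nrow(real_map)
  s1 <- rescale01(realdist_to_contact(real_map))
  s2 <- rescale01(distogram_to_contact(distogram))
  contact_precision((s1 + s2) / 2, truth, k = floor(L / 2))
}

#' Min-max rescale a matrix to [0, 1]
#' @param M numeric matrix.
#' @return Rescaled matrix (all-constant input maps to 0).
#' @export
rescale01 <- function(M) {
  r <- range(M, finite = TRUE)
  if (r[2] - r[1] < 1e-300) return(M * 0)
  (M - r[1]) / (r[2] - r[1])
}
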