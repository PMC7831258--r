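#' Network specification for one branch
#'
#' Captures the architecture hyperparameters of one of the four residual
#' convolutional branches. Defaults reproduce the full-scale design: trunk
#' width 64, residual-block counts COV 16 / PLM 20 / PRE 16 / OTHER 22,
#' dropout 0.2 inside PLM and PRE blocks, SE reduction 16, Maxout over
#' channel-pair groups, dual heads (1-channel regression, 25-bin
#' classification). All fields are overridable for desk-scale models.
#'
#' @param branch `"COV"`, `"PLM"`, `"PRE"` or `"OTHER"`.
#' @param input_channels defaults to [branch_channels()] of the branch.
#' @param trunk_width channels inside the residual trunk; default 64.
#' @param residual_blocks default by branch (16/20/16/22).
#' @param dropout_rate default 0.2 for PLM/PRE, 0 otherwise.
#' @param se_reduction SE bottleneck reduction ratio; default 16.
#' @param maxout_groups group size of the Maxout reduction; default 2.
#' @param bins distogram bins; default 25.
#' @return A `network_spec` object.
#' @export
network_spec <- function(branch, input_channels = NULL, trunk_width = 64L,
                         residual_blocks = NULL, dropout_rate = NULL,
                         se_reduction = 16L, maxout_groups = 2L, bins = 25L) {
  branch <- match.arg(branch, c("COV", "PLM", "PRE", "OTHER"))
  if (is.null(input_channels)) input_channels <- branch_channels(branch)
  if (is.null(residual_blocks))
    residual_blocks <- c(COV = 16L, PLM = 20L, PRE = 16L, OTHER = 22L)[[branch]]
  if (is.null(dropout_rate))
    dropout_rate <- if (branch %in% c("PLM", "PRE")) 0.2 else 0
  structure(list(branch = branch,
                 input_channels = as.integer(input_channels),
                 trunk_width = as.integer(trunk_width),
                 residual_blocks = as.integer(residual_blocks),
                 dropout_rate = dropout_rate,
                 se_reduction = as.integer(se_reduction),
                 maxout_groups = as.integer(maxout_groups),
                 bins = as.integer(bins)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec %s: %d -> width %d, %d residual blocks, dropout %.2g\n",
              x$branch, x$input_channels, x$trunk_width, x$residual_blocks,
              x$dropout_rate))
  invisible(x)
}

.cov_block <- function(w, red) {
  nn_residual(nn_rcin(w), nn_conv(w, w, 3L, 3L),
              nn_rcin(w), nn_conv(w, w, 3L, 3L),
              nn_se(w, red))
}

# bottleneck-style block: entry 3x3, middle stage decomposed into
# 3x3 + 7x1 + 1x7, three RCIN normalizations, SE, dropout
.plm_block <- function(w, red, drop) {
  nn_residual(nn_rcin(w), nn_conv(w, w, 3L, 3L),
              nn_rcin(w), nn_conv(w, w, 3L, 3L),
              nn_conv(w, w, 7L, 1L), nn_conv(w, w, 1L, 7L),
              nn_rcin(w), nn_se(w, red), nn_dropout(drop))
}

# two stacked sub-blocks (conv 3x3, RCIN, dropout, SE); the shortcut spans
# the whole block
.pre_block <- function(w, red, drop) {
  sub <- function() list(nn_conv(w, w, 3L, 3L), nn_rcin(w),
                         nn_dropout(drop), nn_se(w, red))
  do.call(nn_residual, c(sub(), sub()))
}

#' Build a dual-head residual network from a spec
#'
#' Constructs the branch trunk (stem + residual blocks), the pre-head
#' convolutional instance-normalization layer, and the two 1x1-convolution
#' heads. Weights are He-normal initialized from the current RNG state, so
#' seed before calling for reproducibility.
#'
#' @param spec a [network_spec()].
#' @return A `dist_network` object.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$trunk_width; red <- spec$se_reduction
  g <- spec$maxout_groups; Cin <- spec$input_channels
  drop <- spec$dropout_rate
  stem <- switch(spec$branch,
    COV = nn_seq(nn_rcin(Cin), nn_maxout(Cin, w, g)),
    PLM = nn_seq(nn_instnorm(Cin), nn_maxout(Cin, w, g)),
    PRE = nn_seq(nn_instnorm(Cin), nn_conv(Cin, w), nn_rcin(w)),
    OTHER = nn_seq(nn_instnorm(Cin), nn_conv(Cin, w), nn_rcin(w)))
  mkblock <- switch(spec$branch,
    COV = function() .cov_block(w, red),
    PLM = function() .plm_block(w, red, drop),
    PRE = function() .pre_block(w, red, drop),
    OTHER = function() .pre_block(w, red, 0))
  blocks <- lapply(seq_len(spec$residual_blocks), function(k) mkblock())
  trunk <- nn_seq(stem, do.call(nn_seq, blocks))
  head_pre <- nn_seq(nn_conv(w, w), nn_instnorm(w))
  head_reg <- nn_conv(w, 1L)
  head_cls <- nn_conv(w, spec$bins)
  structure(list(spec = spec,
                 net = nn_seq(trunk, head_pre, head_reg, head_cls)),
            class = "dist_network")
}

#' @export
print.dist_network <- function(x, ...) {
  cat(architecture_summary(x), sep = "\n")
  invisible(x)
}

#' Count the residual blocks of a built network
#' @param model a `dist_network`.
#' @return Integer count (by introspection of the layer tree).
#' @export
count_residual_blocks <- function(model) {
  n <- 0L
  walk <- function(l) {
    if (identical(l$type, "residual")) n <<- n + 1L
    if (!is.null(l$layers)) lapply(l$layers, walk)
    invisible(NULL)
  }
  walk(model$net)
  n
}

#' Text summary of a built architecture
#' @param model a `dist_network`.
#' @return Character vector of report lines.
#' @export
architecture_summary <- function(model) {
  s <- model$spec
  c(sprintf("branch: %s", s$branch),
    sprintf("input_channels: %d", s$input_channels),
    sprintf("trunk_width: %d", s$trunk_width),
    sprintf("residual_blocks: %d", count_residual_blocks(model)),
    sprintf("dropout_rate: %g", s$dropout_rate),
    sprintf("heads: regression=1, classification=%d", s$bins),
    sprintf("parameters: %d", length(nn_flatten_params(model$net))))
}

# core forward pass: x is a branch_input or raw L x L x C array.
# Returns real-value head (post-ReLU), classification logits, and caches.
.model_forward <- function(model, x, train = FALSE) {
  if (inherits(x, "branch_input")) x <- x$tensor
  d <- dim(x)
  L <- d[1]
  if (d[3] != model$spec$input_channels)
    stop("input has ", d[3], " channels; ", model$spec$branch,
         " network expects ", model$spec$input_channels)
  xm <- matrix(x, L * L, d[3])
  pl <- model$net$layers
  ftr <- nn_forward(pl[[1]], xm, L, train)
  fhp <- nn_forward(pl[[2]], ftr$y, L, train)
  freg <- nn_forward(pl[[3]], fhp$y, L, train)
  fcls <- nn_forward(pl[[4]], fhp$y, L, train)
  real <- pmax(freg$y[, 1], 0)
  list(real = real, logits = fcls$y, L = L,
       cache = list(trunk = ftr$cache, head_pre = fhp$cache,
                    reg = freg$cache, cls = fcls$cache,
                    reg_mask = freg$y[, 1] > 0))
}

# backward from head gradients (d_real on post-ReLU output, d_logits raw)
.model_backward <- function(model, fwd, d_real, d_logits) {
  pl <- model$net$layers
  breg <- nn_backward(pl[[3]], matrix(d_real * fwd$cache$reg_mask, ncol = 1),
                      fwd$cache$reg)
  bcls <- nn_backward(pl[[4]], d_logits, fwd$cache$cls)
  bhp <- nn_backward(pl[[2]], breg$dx + bcls$dx, fwd$cache$head_pre)
  btr <- nn_backward(pl[[1]], bhp$dx, fwd$cache$trunk)
  # gradient structure mirrors nn_seq(trunk, head_pre, head_reg, head_cls)
  list(btr$grads, bhp$grads, breg$grads, bcls$grads)
}

.softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

#' Predict a dual distance output for one branch input
#'
#' Runs the forward pass and returns the real-value distance map (ReLU head)
#' and the 25-bin distogram (softmax head). By default both are symmetrized:
#' the distance map by transpose-averaging, the distogram by averaging the
#' `(i,j)` and `(j,i)` bin vectors (still a probability simplex).
#'
#' @param model a `dist_network`.
#' @param x a `branch_input` or `L x L x C` array.
#' @param symmetrize average with the transpose? Default TRUE.
#' @return List with `real_distance` (L x L) and `distogram` (L x L x bins).
#' @export
predict_dual <- function(model, x, symmetrize = TRUE) {
  fwd <- .model_forward(model, x, train = FALSE)
  L <- fwd$L; B <- model$spec$bins
  D <- matrix(fwd$real, L, L)
  P <- array(.softmax_rows(fwd$logits), dim = c(L, L, B))
  if (symmetrize) {
    D <- (D + t(D)) / 2
    P <- (P + aperm(P, c(2, 1, 3))) / 2
  }
  list(real_distance = D, distogram = P)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are JSON files holding the [network_spec()] and the flat
#' parameter vector at full precision, so a reloaded model reproduces
#' predictions bit-for-bit (up to decimal round-trip).
#'
#' @param model a `dist_network`.
#' @param path file path (`.json`).
#' @return `save_checkpoint` returns the path; `load_checkpoint` the model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "coevdist-checkpoint-1",
              spec = unclass(model$spec),
              params = nn_flatten_params(model$net))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("not a checkpoint file: ", path, " (",
                         conditionMessage(e), ")"))
  if (!identical(obj$format, "coevdist-checkpoint-1"))
    stop("not a checkpoint file: ", path)
  s <- obj$spec
  spec <- network_spec(s$branch, s$input_channels, s$trunk_width,
                       s$residual_blocks, s$dropout_rate, s$se_reduction,
                       s$maxout_groups, s$bins)
  model <- build_network(spec)
  model$net <- nn_set_params(model$net, as.numeric(obj$params))
  model
}
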