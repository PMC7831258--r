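# Minimal dense-tensor neural-network layers with analytic backprop.
#
# No deep-learning framework exists in the supported R stack, so the layers
# the architectures need (2D convolution, Maxout, instance/row/column
# normalization, squeeze-and-excitation gating, dropout) are implemented
# here directly. Activations travel as an N x C matrix, N = L * L pixels of
# the pairwise map in column-major order (p = i + (j-1) L); every layer has
# a forward returning (output, cache) and a backward returning the input
# gradient plus parameter gradients. Correctness is pinned by a central
# finite-difference check in the test suite.

.nn_eps <- 1e-5

# ---- initializers ---------------------------------------------------------

.he_normal <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# ---- conv -----------------------------------------------------------------

# neighbor index maps for same-padded convolution on an L x L grid; NA = pad
.conv_offsets <- function(kh, kw) {
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  expand.grid(dh = seq_len(kh) - (kh + 1L) %/% 2L,
              dw = seq_len(kw) - (kw + 1L) %/% 2L)
}

.conv_index <- function(L, offs) {
  ij <- expand.grid(i = seq_len(L), j = seq_len(L))
  lapply(seq_len(nrow(offs)), function(o) {
    ii <- ij$i + offs$dh[o]; jj <- ij$j + offs$dw[o]
    ok <- ii >= 1 & ii <= L & jj >= 1 & jj <= L
    idx <- ifelse(ok, ii + (jj - 1L) * L, NA_integer_)
    idx
  })
}

nn_conv <- function(cin, cout, kh = 1L, kw = 1L) {
  fan_in <- kh * kw * cin
  list(type = "conv",
       cfg = list(cin = cin, cout = cout, kh = kh, kw = kw),
       params = list(W = .he_normal(fan_in, cout, fan_in),
                     b = numeric(cout)))
}

.conv_im2col <- function(x, L, cfg) {
  if (cfg$kh == 1L && cfg$kw == 1L) return(x)
  offs <- .conv_offsets(cfg$kh, cfg$kw)
  idxs <- .conv_index(L, offs)
  C <- cfg$cin; N <- nrow(x)
  Xc <- matrix(0, N, nrow(offs) * C)
  for (o in seq_along(idxs)) {
    idx <- idxs[[o]]
    ok <- !is.na(idx)
    Xc[ok, (o - 1L) * C + seq_len(C)] <- x[idx[ok], , drop = FALSE]
  }
  Xc
}

fwd_conv <- function(layer, x, L, train, env) {
  Xc <- .conv_im2col(x, L, layer$cfg)
  y <- Xc %*% layer$params$W
  y <- sweep(y, 2, layer$params$b, `+`)
  list(y = y, cache = list(Xc = Xc, L = L))
}

bwd_conv <- function(layer, dy, cache) {
  cfg <- layer$cfg
  gW <- crossprod(cache$Xc, dy)
  gb <- colSums(dy)
  dXc <- dy %*% t(layer$params$W)
  if (cfg$kh == 1L && cfg$kw == 1L) {
    dx <- dXc
  } else {
    L <- cache$L
    offs <- .conv_offsets(cfg$kh, cfg$kw)
    idxs <- .conv_index(L, offs)
    C <- cfg$cin
    dx <- matrix(0, nrow(dy), C)
    for (o in seq_along(idxs)) {
      idx <- idxs[[o]]
      ok <- !is.na(idx)
      dx[idx[ok], ] <- dx[idx[ok], ] + dXc[ok, (o - 1L) * C + seq_len(C)]
    }
  }
  list(dx = dx, grads = list(W = gW, b = gb))
}

# ---- relu -----------------------------------------------------------------

nn_relu <- function() list(type = "relu", cfg = list(), params = list())
fwd_relu <- function(layer, x, L, train, env) {
  y <- pmax(x, 0)
  list(y = y, cache = list(mask = x > 0))
}
bwd_relu <- function(layer, dy, cache) list(dx = dy * cache$mask, grads = list())

# ---- maxout ---------------------------------------------------------------

# 1x1 conv expansion to cout * groups channels, elementwise max over groups
nn_maxout <- function(cin, cout, groups = 2L) {
  l <- nn_conv(cin, cout * groups)
  l$type <- "maxout"
  l$cfg$groups <- as.integer(groups)
  l$cfg$cout_eff <- as.integer(cout)
  l
}

fwd_maxout <- function(layer, x, L, train, env) {
  g <- layer$cfg$groups; cout <- layer$cfg$cout_eff
  z <- sweep(x %*% layer$params$W, 2, layer$params$b, `+`)
  dim(z) <- c(nrow(z), g, cout)          # channel layout: group fastest
  y <- apply(z, c(1, 3), max)
  amax <- apply(z, c(1, 3), which.max)
  list(y = y, cache = list(x = x, amax = amax, g = g, cout = cout))
}

bwd_maxout <- function(layer, dy, cache) {
  g <- cache$g; cout <- cache$cout; N <- nrow(dy)
  dz <- array(0, dim = c(N, g, cout))
  dz[cbind(rep(seq_len(N), cout), as.vector(cache$amax),
           rep(seq_len(cout), each = N))] <- as.vector(dy)
  dim(dz) <- c(N, g * cout)
  gW <- crossprod(cache$x, dz)
  gb <- colSums(dz)
  list(dx = dz %*% t(layer$params$W), grads = list(W = gW, b = gb))
}

# ---- normalizations -------------------------------------------------------

# shared helper: normalize x over groups defined by a factor of equal sizes.
# Returns xhat plus cache for the standard normalization backward.
.norm_fwd <- function(x, gidx, m) {
  mu <- rowsum(x, gidx, reorder = TRUE) / m
  xc <- x - mu[gidx, , drop = FALSE]
  v <- rowsum(xc * xc, gidx, reorder = TRUE) / m
  istd <- 1 / sqrt(v + .nn_eps)
  xhat <- xc * istd[gidx, , drop = FALSE]
  list(xhat = xhat, istd = istd, gidx = gidx, m = m)
}

.norm_bwd <- function(dxhat, cache) {
  gidx <- cache$gidx; m <- cache$m
  s1 <- rowsum(dxhat, gidx, reorder = TRUE) / m
  s2 <- rowsum(dxhat * cache$xhat, gidx, reorder = TRUE) / m
  (dxhat - s1[gidx, , drop = FALSE] -
     cache$xhat * s2[gidx, , drop = FALSE]) * cache$istd[gidx, , drop = FALSE]
}

# instance norm: per channel over all pixels, learned per-channel affine
nn_instnorm <- function(C) {
  list(type = "instnorm", cfg = list(C = C),
       params = list(gamma = rep(1, C), beta = numeric(C)))
}

fwd_instnorm <- function(layer, x, L, train, env) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + .nn_eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  list(y = y, cache = list(xhat = xhat, istd = istd))
}

bwd_instnorm <- function(layer, dy, cache) {
  ggamma <- colSums(dy * cache$xhat)
  gbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, layer$params$gamma, `*`)
  m <- nrow(dy)
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(sweep(sweep(dxhat, 2, s1), 1, rep(1, m), `*`) -
                sweep(cache$xhat, 2, s2, `*`), 2, cache$istd, `*`)
  list(dx = dx, grads = list(gamma = ggamma, beta = gbeta))
}

# row / column norm: per (row, channel) or (column, channel), no affine.
# With pixel index p = i + (j-1) L: row groups share i, column groups share j.
nn_rownorm <- function() list(type = "rownorm", cfg = list(), params = list())
nn_colnorm <- function() list(type = "colnorm", cfg = list(), params = list())

.grid_gidx <- function(L, axis) {
  if (axis == "row") rep(seq_len(L), times = L) else rep(seq_len(L), each = L)
}

fwd_rownorm <- function(layer, x, L, train, env) {
  c(list(), .rcnorm_fwd(x, L, "row"))
}
fwd_colnorm <- function(layer, x, L, train, env) {
  c(list(), .rcnorm_fwd(x, L, "col"))
}
.rcnorm_fwd <- function(x, L, axis) {
  cache <- .norm_fwd(x, .grid_gidx(L, axis), L)
  list(y = cache$xhat, cache = cache)
}
bwd_rownorm <- function(layer, dy, cache) list(dx = .norm_bwd(dy, cache), grads = list())
bwd_colnorm <- function(layer, dy, cache) list(dx = .norm_bwd(dy, cache), grads = list())

# ---- RCIN block -----------------------------------------------------------

# instance-, row- and column-normalized views concatenated channelwise,
# fused back to C channels by a 1x1 convolution, then ReLU. The wiring of
# the three normalizations is a package design choice (the originating
# description lists the ingredients but not their composition).
nn_rcin <- function(C) {
  inl <- nn_instnorm(C)
  fuse <- nn_conv(3L * C, C)
  list(type = "rcin", cfg = list(C = C),
       params = list(gamma = inl$params$gamma, beta = inl$params$beta,
                     W = fuse$params$W, b = fuse$params$b))
}

fwd_rcin <- function(layer, x, L, train, env) {
  C <- layer$cfg$C
  inl <- list(type = "instnorm", cfg = list(C = C),
              params = list(gamma = layer$params$gamma, beta = layer$params$beta))
  fi <- fwd_instnorm(inl, x, L, train, env)
  fr <- .rcnorm_fwd(x, L, "row")
  fc <- .rcnorm_fwd(x, L, "col")
  z <- cbind(fi$y, fr$y, fc$y)
  h <- sweep(z %*% layer$params$W, 2, layer$params$b, `+`)
  y <- pmax(h, 0)
  list(y = y, cache = list(ci = fi$cache, cr = fr$cache, cc = fc$cache,
                           z = z, mask = h > 0, C = C))
}

bwd_rcin <- function(layer, dy, cache) {
  C <- cache$C
  dh <- dy * cache$mask
  gW <- crossprod(cache$z, dh)
  gb <- colSums(dh)
  dz <- dh %*% t(layer$params$W)
  inl <- list(type = "instnorm", cfg = list(C = C),
              params = list(gamma = layer$params$gamma, beta = layer$params$beta))
  bi <- bwd_instnorm(inl, dz[, seq_len(C), drop = FALSE], cache$ci)
  dxr <- .norm_bwd(dz[, C + seq_len(C), drop = FALSE], cache$cr)
  dxc <- .norm_bwd(dz[, 2L * C + seq_len(C), drop = FALSE], cache$cc)
  list(dx = bi$dx + dxr + dxc,
       grads = list(gamma = bi$grads$gamma, beta = bi$grads$beta, W = gW, b = gb))
}

# ---- squeeze-and-excitation -----------------------------------------------

nn_se <- function(C, reduction = 16L) {
  r <- max(1L, C %/% reduction)
  if (C %% r != 0)
    stop("SE: channels ", C, " not divisible by bottleneck width ", r)
  list(type = "se", cfg = list(C = C, r = r),
       params = list(W1 = .he_normal(C, r, C), b1 = numeric(r),
                     W2 = .he_normal(r, C, r), b2 = numeric(C)))
}

fwd_se <- function(layer, x, L, train, env) {
  p <- layer$params
  z <- colMeans(x)                                  # squeeze
  h <- pmax(as.vector(z %*% p$W1) + p$b1, 0)        # bottleneck
  s <- 1 / (1 + exp(-(as.vector(h %*% p$W2) + p$b2)))  # gates in (0,1)
  y <- sweep(x, 2, s, `*`)
  list(y = y, cache = list(x = x, z = z, h = h, s = s))
}

bwd_se <- function(layer, dy, cache) {
  p <- layer$params
  x <- cache$x; s <- cache$s; h <- cache$h
  ds <- colSums(dy * x)
  dpre2 <- ds * s * (1 - s)
  gW2 <- outer(h, dpre2)
  gb2 <- dpre2
  dh <- as.vector(p$W2 %*% dpre2) * (h > 0)
  gW1 <- outer(cache$z, dh)
  gb1 <- dh
  dz <- as.vector(p$W1 %*% dh)
  dx <- sweep(dy, 2, s, `*`) +
    matrix(dz, nrow(x), length(dz), byrow = TRUE) / nrow(x)
  list(dx = dx, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# ---- dropout --------------------------------------------------------------

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", cfg = list(rate = rate), params = list())
}

fwd_dropout <- function(layer, x, L, train, env) {
  r <- layer$cfg$rate
  if (!train || r == 0) return(list(y = x, cache = list(mask = NULL)))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= r) / (1 - r)
  list(y = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, dy, cache) {
  if (is.null(cache$mask)) list(dx = dy, grads = list())
  else list(dx = dy * cache$mask, grads = list())
}

# ---- composites -----------------------------------------------------------

nn_seq <- function(...) list(type = "seq", cfg = list(), params = list(),
                             layers = list(...))

# residual block: body layers, skip add, then ReLU on the sum
nn_residual <- function(...) list(type = "residual", cfg = list(),
                                  params = list(), layers = list(...))

fwd_seq <- function(layer, x, L, train, env) {
  caches <- vector("list", length(layer$layers))
  for (k in seq_along(layer$layers)) {
    r <- nn_forward(layer$layers[[k]], x, L, train, env)
    x <- r$y
    caches[[k]] <- r$cache
  }
  list(y = x, cache = caches)
}

bwd_seq <- function(layer, dy, cache) {
  grads <- vector("list", length(layer$layers))
  for (k in rev(seq_along(layer$layers))) {
    r <- nn_backward(layer$layers[[k]], dy, cache[[k]])
    dy <- r$dx
    grads[[k]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

fwd_residual <- function(layer, x, L, train, env) {
  r <- fwd_seq(layer, x, L, train, env)
  s <- x + r$y
  list(y = pmax(s, 0), cache = list(body = r$cache, mask = s > 0))
}

bwd_residual <- function(layer, dy, cache) {
  ds <- dy * cache$mask
  r <- bwd_seq(layer, ds, cache$body)
  list(dx = r$dx + ds, grads = r$grads)
}

# ---- dispatch -------------------------------------------------------------

#' Run one layer (or composite) forward
#'
#' Low-level building block of the network module; exposed mainly for tests.
#'
#' @param layer a layer object created by one of the `nn_*` constructors.
#' @param x `N x C` activation matrix, `N = L^2` pixels column-major.
#' @param L map side length.
#' @param train training mode (enables dropout).
#' @param env optional environment (unused hook for instrumentation).
#' @return List with `y` (output matrix) and `cache` for [nn_backward()].
#' @export
nn_forward <- function(layer, x, L, train = FALSE, env = NULL) {
  switch(layer$type,
         conv = fwd_conv(layer, x, L, train, env),
         relu = fwd_relu(layer, x, L, train, env),
         maxout = fwd_maxout(layer, x, L, train, env),
         instnorm = fwd_instnorm(layer, x, L, train, env),
         rownorm = fwd_rownorm(layer, x, L, train, env),
         colnorm = fwd_colnorm(layer, x, L, train, env),
         rcin = fwd_rcin(layer, x, L, train, env),
         se = fwd_se(layer, x, L, train, env),
         dropout = fwd_dropout(layer, x, L, train, env),
         seq = fwd_seq(layer, x, L, train, env),
         residual = fwd_residual(layer, x, L, train, env),
         stop("unknown layer type: ", layer$type))
}

#' Backpropagate through one layer (or composite)
#'
#' @param layer the layer used in the matching [nn_forward()] call.
#' @param dy gradient of the loss with respect to the layer output.
#' @param cache cache returned by [nn_forward()].
#' @return List with `dx` and `grads` (structure mirrors `layer$params`).
#' @export
nn_backward <- function(layer, dy, cache) {
  switch(layer$type,
         conv = bwd_conv(layer, dy, cache),
         relu = bwd_relu(layer, dy, cache),
         maxout = bwd_maxout(layer, dy, cache),
         instnorm = bwd_instnorm(layer, dy, cache),
         rownorm = bwd_rownorm(layer, dy, cache),
         colnorm = bwd_colnorm(layer, dy, cache),
         rcin = bwd_rcin(layer, dy, cache),
         se = bwd_se(layer, dy, cache),
         dropout = bwd_dropout(layer, dy, cache),
         seq = bwd_seq(layer, dy, cache),
         residual = bwd_residual(layer, dy, cache),
         stop("unknown layer type: ", layer$type))
}

# ---- parameter flattening -------------------------------------------------

# deterministic depth-first traversal; leaves are numeric arrays
.walk_params <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- layer$params
  if (!is.null(layer$layers))
    out <- c(out, lapply(layer$layers, .walk_params))
  out
}

#' Flatten all parameters of a layer tree into one numeric vector
#' @param layer a layer or network trunk object.
#' @return Numeric vector.
#' @export
nn_flatten_params <- function(layer) {
  unlist(.walk_params(layer), use.names = FALSE)
}

# write a flat vector back into the layer tree, in traversal order
.inject <- function(layer, v, pos) {
  for (nm in names(layer$params)) {
    n <- length(layer$params[[nm]])
    val <- v[pos + seq_len(n)]
    dim(val) <- dim(layer$params[[nm]])
    layer$params[[nm]] <- val
    pos <- pos + n
  }
  if (!is.null(layer$layers)) {
    for (k in seq_along(layer$layers)) {
      r <- .inject(layer$layers[[k]], v, pos)
      layer$layers[[k]] <- r$layer
      pos <- r$pos
    }
  }
  list(layer = layer, pos = pos)
}

#' Write a flat parameter vector back into a layer tree
#' @param layer layer tree with the same shapes.
#' @param v numeric vector from [nn_flatten_params()].
#' @return The updated layer tree.
#' @export
nn_set_params <- function(layer, v) {
  r <- .inject(layer, v, 0L)
  if (r$pos != length(v)) stop("parameter vector length mismatch: used ",
                               r$pos, " of ", length(v))
  r$layer
}

# flatten a gradient structure returned by nn_backward (mirrors params)
nn_flatten_grads <- function(grads) unlist(grads, use.names = FALSE)
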