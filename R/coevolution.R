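#' Pair channel blocks
#'
#' A pair channel block is an `L x L x k` array of pairwise features plus a
#' name and a symmetry tag. Coevolution tensors (COV/PRE/PLM) have k = 441
#' channels, one per ordered amino-acid pair `(a, b)` flattened as
#' `channel = 21 * (a - 1) + b`, and satisfy `T[i,j,(a,b)] = T[j,i,(b,a)]`.
#' Scalar statistics have k = 1 and are symmetric in `(i, j)`.
#'
#' @param name channel-group label.
#' @param values `L x L x k` array (an `L x L` matrix is promoted to k = 1).
#' @param symmetry `"pair_transpose"` (441-channel rule) or `"scalar"`.
#' @return An object of class `pair_block`.
#' @export
pair_block <- function(name, values, symmetry = c("scalar", "pair_transpose")) {
  symmetry <- match.arg(symmetry)
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, dim(values)[1] == dim(values)[2])
  if (!all(is.finite(values))) stop("non-finite values in block ", name)
  structure(list(name = name, values = values, symmetry = symmetry),
            class = "pair_block")
}

#' @export
print.pair_block <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("pair_block '%s': %d x %d x %d (%s symmetry)\n",
              x$name, d[1], d[2], d[3], x$symmetry))
  invisible(x)
}

# channel index for amino-acid pair (a, b) in a 441-channel block
.pair_chan <- function(a, b, q = 21L) (a - 1L) * q + b

# permutation sending channel (a,b) -> (b,a); used by the transpose rule
.pair_chan_swap <- function(q = 21L) {
  ab <- expand.grid(b = seq_len(q), a = seq_len(q))   # channel order: b fastest
  .pair_chan(ab$b, ab$a, q)
}

#' Covariance feature tensor
#'
#' `C_ij(a,b) = f_ij(a,b) - f_i(a) * f_j(b)` over the 21-state alphabet —
#' the raw covariation signal of the alignment.
#'
#' @param freqs output of [column_frequencies()].
#' @return A 441-channel [pair_block()] named `"COV"`.
#' @export
covariance_tensor <- function(freqs) {
  L <- nrow(freqs$f1); q <- 21L
  f1 <- freqs$f1
  outer_f <- array(0, dim = c(L, L, q, q))
  for (a in seq_len(q)) for (b in seq_len(q))
    outer_f[, , a, b] <- tcrossprod(f1[, a], f1[, b])
  # freqs$f2 is [i,j,a,b]; channel = (a-1)*q + b means b varies fastest,
  # so reorder to [i,j,b,a] before collapsing the last two dims
  Cb <- aperm(freqs$f2 - outer_f, c(1, 2, 4, 3))
  dim(Cb) <- c(L, L, q * q)
  pair_block("COV", Cb, "pair_transpose")
}

#' Shrunk precision (inverse covariance) feature tensor
#'
#' Flattens the covariance tensor to a `(21 L) x (21 L)` matrix, shrinks it
#' toward its diagonal, inverts, and reshapes back — the sparse-inverse
#' covariance route to direct couplings.
#'
#' @param cov a COV [pair_block()].
#' @param shrinkage shrinkage weight `lambda` in `[0, 1]`: the inverted
#'   matrix is `(1 - lambda) C + lambda diag(diag(C))` with a small ridge on
#'   zero diagonal entries. Default 0.1.
#' @return A 441-channel [pair_block()] named `"PRE"`.
#' @export
precision_tensor <- function(cov, shrinkage = 0.1) {
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  v <- cov$values
  L <- dim(v)[1]; q <- 21L
  # big matrix M[(i-1)q+a, (j-1)q+b] = C[i,j,(a,b)]
  M <- matrix(aperm(array(v, c(L, L, q, q)), c(4, 1, 3, 2)), L * q, L * q)
  d <- diag(M)
  S <- (1 - shrinkage) * M
  diag(S) <- (1 - shrinkage) * d + shrinkage * pmax(d, 1e-8)
  P <- tryCatch(solve(S), error = function(e)
    stop("covariance matrix is singular; use a nonzero shrinkage (got lambda = ",
         shrinkage, "): ", conditionMessage(e)))
  P <- (P + t(P)) / 2
  out <- aperm(array(P, c(q, L, q, L)), c(2, 4, 3, 1))  # -> [i,j,b,a] so channel=(a-1)q+b
  dim(out) <- c(L, L, q * q)
  pair_block("PRE", out, "pair_transpose")
}

# ---- pseudolikelihood Potts model -----------------------------------------

# index helpers for the flat parameter vector: L*q fields then npair*q*q
# couplings for pairs (i<j) in column-major pair order
.plm_layout <- function(L, q = 21L) {
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  list(L = L, q = q, nh = L * q, pairs = pairs, npair = nrow(pairs))
}

# build the (Lq x Lq) symmetric coupling matrix from flat parameters
.plm_jmat <- function(theta, lay) {
  q <- lay$q; L <- lay$L
  J <- matrix(0, L * q, L * q)
  off <- lay$nh
  blk <- q * q
  for (p in seq_len(lay$npair)) {
    i <- lay$pairs[p, 1]; j <- lay$pairs[p, 2]
    Jij <- matrix(theta[off + (p - 1L) * blk + seq_len(blk)], q, q)
    ri <- (i - 1L) * q + seq_len(q); rj <- (j - 1L) * q + seq_len(q)
    J[ri, rj] <- Jij
    J[rj, ri] <- t(Jij)
  }
  J
}

# negative log pseudolikelihood and gradient; X is n x (Lq) one-hot, w weights
.plm_nll <- function(theta, lay, X, w, l2_couplings, l2_fields, want_grad) {
  q <- lay$q; L <- lay$L; n <- nrow(X)
  H <- matrix(theta[seq_len(lay$nh)], q, L)      # column i = fields of site i
  J <- .plm_jmat(theta, lay)
  Z <- X %*% J + matrix(rep(as.vector(H), each = n), n, L * q)
  # per-site softmax over each q-column block
  nll <- 0
  G <- if (want_grad) matrix(0, n, L * q) else NULL
  for (i in seq_len(L)) {
    cols <- (i - 1L) * q + seq_len(q)
    Zi <- Z[, cols, drop = FALSE]
    m <- apply(Zi, 1, max)
    lse <- m + log(rowSums(exp(Zi - m)))
    realized <- rowSums(Zi * X[, cols, drop = FALSE])
    nll <- nll - sum(w * (realized - lse))
    if (want_grad) {
      P <- exp(Zi - lse)
      G[, cols] <- w * (P - X[, cols, drop = FALSE])
    }
  }
  off <- lay$nh; blk <- q * q
  thJ <- theta[off + seq_len(lay$npair * blk)]
  nll <- nll + l2_fields * sum(H^2) + l2_couplings * sum(thJ^2)
  if (!want_grad) return(nll)
  A <- crossprod(G, X)                           # (Lq) x (Lq)
  A <- A + t(A)
  gh <- as.vector(vapply(seq_len(L), function(i)
    colSums(G[, (i - 1L) * q + seq_len(q), drop = FALSE]), numeric(q))) +
    2 * l2_fields * as.vector(H)
  gJ <- numeric(lay$npair * blk)
  for (p in seq_len(lay$npair)) {
    i <- lay$pairs[p, 1]; j <- lay$pairs[p, 2]
    ri <- (i - 1L) * q + seq_len(q); rj <- (j - 1L) * q + seq_len(q)
    gJ[(p - 1L) * blk + seq_len(blk)] <- as.vector(A[ri, rj])
  }
  gJ <- gJ + 2 * l2_couplings * thJ
  list(value = nll, grad = c(gh, gJ))
}

#' Potts coupling tensor by pseudolikelihood maximization
#'
#' Fits a 21-state Potts model (fields `h_i(a)`, couplings `J_ij(a,b)`) to a
#' weighted alignment by maximizing the L2-regularized pseudolikelihood with
#' L-BFGS, the estimator popularized by plmDCA/CCMpred. Couplings are
#' symmetric by construction (`J_ij(a,b) = J_ji(b,a)`).
#'
#' @param msa an `msa` with weights computed; L >= 2.
#' @param l2_couplings coupling penalty; default `0.2 * (L - 1)`.
#' @param l2_fields field penalty; default 0.01.
#' @param optimizer_budget L-BFGS iteration cap; default 100.
#' @return A 441-channel [pair_block()] named `"PLM"` with attribute
#'   `"fit"` holding fields, final objective and convergence flag.
#' @export
plm_tensor <- function(msa, l2_couplings = NULL, l2_fields = 0.01,
                       optimizer_budget = 100L) {
  if (is.null(msa$weights)) stop("call compute_weights() first")
  L <- ncol(msa$x); q <- 21L
  if (L < 2) stop("PLM requires L >= 2")
  if (is.null(l2_couplings)) l2_couplings <- 0.2 * (L - 1)
  stopifnot(l2_couplings > 0, l2_fields > 0)
  n <- nrow(msa$x)
  lay <- .plm_layout(L, q)
  X <- matrix(0, n, L * q)
  X[cbind(rep(seq_len(n), L),
          (rep(seq_len(L), each = n) - 1L) * q + as.vector(msa$x))] <- 1
  w <- msa$weights
  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    r <- .plm_nll(th, lay, X, w, l2_couplings, l2_fields, want_grad = TRUE)
    cache$grad <- r$grad
    r$value
  }
  gr <- function(th) cache$grad
  th0 <- numeric(lay$nh + lay$npair * q * q)
  res <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = as.integer(optimizer_budget),
                                     factr = 1e9))
  if (res$convergence != 0)
    warning("PLM optimizer did not fully converge within budget (",
            optimizer_budget, " iterations); returning best iterate")
  theta <- res$par
  out <- array(0, dim = c(L, L, q * q))
  swap <- .pair_chan_swap(q)
  blk <- q * q; off <- lay$nh
  for (p in seq_len(lay$npair)) {
    i <- lay$pairs[p, 1]; j <- lay$pairs[p, 2]
    Jij <- matrix(theta[off + (p - 1L) * blk + seq_len(blk)], q, q)
    v <- as.vector(t(Jij))               # channel (a,b) = (a-1)q + b
    out[i, j, ] <- v
    out[j, i, ] <- v[swap]
  }
  b <- pair_block("PLM", out, "pair_transpose")
  attr(b, "fit") <- list(fields = matrix(theta[seq_len(lay$nh)], q, L),
                         nll = res$value, convergence = res$convergence)
  b
}

#' Evaluate the PLM objective and gradient directly
#'
#' Exposed for gradient-checking: returns the weighted, regularized negative
#' log pseudolikelihood and its analytic gradient at a parameter vector.
#'
#' @inheritParams plm_tensor
#' @param theta flat parameter vector (`L*21` fields then `q^2` couplings per
#'   `i < j` pair in row-major pair order); zeros if NULL.
#' @return List with `value` and `grad`.
#' @export
plm_objective <- function(msa, theta = NULL, l2_couplings = NULL,
                          l2_fields = 0.01) {
  if (is.null(msa$weights)) stop("call compute_weights() first")
  L <- ncol(msa$x); q <- 21L; n <- nrow(msa$x)
  if (is.null(l2_couplings)) l2_couplings <- 0.2 * (L - 1)
  lay <- .plm_layout(L, q)
  if (is.null(theta)) theta <- numeric(lay$nh + lay$npair * q * q)
  X <- matrix(0, n, L * q)
  X[cbind(rep(seq_len(n), L),
          (rep(seq_len(L), each = n) - 1L) * q + as.vector(msa$x))] <- 1
  .plm_nll(theta, lay, X, msa$weights, l2_couplings, l2_fields, TRUE)
}

#' Coupling-based contact score with average-product correction
#'
#' `S_ij` is the Frobenius norm of the coupling block `J_ij` over the 20
#' non-gap states. The average-product correction (APC) subtracts
#' `S_i. * S_.j / S_..` to remove background row/column effects; an APC'd
#' rank-1 score matrix is exactly zero.
#'
#' @param plm a PLM [pair_block()] (or any 441-channel block).
#' @param apc apply the correction? Default TRUE.
#' @return A 1-channel [pair_block()] named `"contact_score"` with zeroed
#'   diagonal.
#' @export
coupling_contact_score <- function(plm, apc = TRUE) {
  v <- plm$values
  L <- dim(v)[1]; q <- 21L
  nog <- as.vector(outer(seq_len(q - 1), seq_len(q - 1),
                         function(a, b) .pair_chan(a, b, q)))
  S <- sqrt(apply(v[, , nog, drop = FALSE]^2, c(1, 2), sum))
  S <- (S + t(S)) / 2
  diag(S) <- 0
  if (apc) S <- apc_correct(S)
  pair_block("contact_score", S, "scalar")
}

#' Average-product correction of a symmetric score matrix
#'
#' @param S symmetric score matrix with zero diagonal.
#' @return `S - rowMeans %o% colMeans / grand mean`, diagonal zeroed.
#' @export
apc_correct <- function(S) {
  L <- nrow(S)
  ri <- rowSums(S) / (L - 1)
  tot <- sum(S) / (L * (L - 1))
  if (tot == 0) return(S * 0)
  out <- S - outer(ri, ri) / tot
  diag(out) <- 0
  out
}

#' Scalar coevolution statistics
#'
#' From weighted frequencies computes six symmetric `L x L` statistics:
#' mutual information `MI_ij = sum f_ij log(f_ij / (f_i f_j))`; joint entropy
#' `H_ij = -sum f_ij log f_ij`; normalized MI `MI_ij / H_ij` (0 where
#' `H_ij = 0`); per-column Shannon entropy sum `H_i + H_j`; Pearson
#' correlation between hydropathy-encoded columns under the joint pair
#' distribution; and the mean contact potential
#' `sum_{a,b in 20x20} f_ij(a,b) U(a,b)` for the bundled potential
#' [contact_potential()]. The gap is kept as a 21st state in MI/entropy so
#' the distributions stay exactly normalized; `0 log 0` is taken as 0.
#'
#' @param freqs output of [column_frequencies()].
#' @return Named list of 1-channel [pair_block()]s: `mutual_information`,
#'   `normalized_mi`, `joint_entropy`, `shannon_entropy_sum`,
#'   `pearson_correlation`, `mean_contact_potential`.
#' @export
information_statistics <- function(freqs) {
  f1 <- freqs$f1; f2 <- freqs$f2
  L <- nrow(f1); q <- 21L
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  Hcol <- -rowSums(xlogx(f1))
  MI <- matrix(0, L, L); H2 <- matrix(0, L, L)
  PC <- matrix(0, L, L); CP <- matrix(0, L, L)
  enc <- aa_hydropathy()                          # length 21, gap = 0
  U <- contact_potential()                        # 20 x 20
  for (i in seq_len(L)) for (j in i:L) {
    fij <- f2[i, j, , ]
    pij <- tcrossprod(f1[i, ], f1[j, ])
    pos <- fij > 0 & pij > 0
    MI[i, j] <- MI[j, i] <- sum(fij[pos] * log(fij[pos] / pij[pos]))
    H2[i, j] <- H2[j, i] <- -sum(xlogx(fij))
    Exy <- sum(fij * outer(enc, enc))
    Ex <- sum(f1[i, ] * enc); Ey <- sum(f1[j, ] * enc)
    Vx <- sum(f1[i, ] * enc^2) - Ex^2; Vy <- sum(f1[j, ] * enc^2) - Ey^2
    PC[i, j] <- PC[j, i] <- if (Vx > 1e-12 && Vy > 1e-12)
      (Exy - Ex * Ey) / sqrt(Vx * Vy) else 0
    CP[i, j] <- CP[j, i] <- sum(fij[1:20, 1:20] * U)
  }
  NMI <- ifelse(H2 > 0, MI / H2, 0)
  ES <- outer(Hcol, Hcol, `+`)
  list(mutual_information = pair_block("mutual_information", pmax(MI, 0)),
       normalized_mi = pair_block("normalized_mi", NMI),
       joint_entropy = pair_block("joint_entropy", H2),
       shannon_entropy_sum = pair_block("shannon_entropy_sum", ES),
       pearson_correlation = pair_block("pearson_correlation", PC),
       mean_contact_potential = pair_block("mean_contact_potential", CP))
}

#' Kyte-Doolittle hydropathy encoding of the 21-state alphabet
#'
#' Numeric per-residue encoding used for the Pearson-correlation statistic;
#' the gap state encodes as 0.
#'
#' @return Named numeric vector of length 21.
#' @export
aa_hydropathy <- function() {
  h <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
         I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
         R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  out <- c(h[aa_alphabet()[1:20]], "-" = 0)
  names(out) <- aa_alphabet()
  out
}

#' Synthetic pairwise contact potential (20 x 20)
#'
#' A hydropathy-derived stand-in for a statistical contact potential:
#' `U(a,b) = -h_a * h_b / 10` on the Kyte-Doolittle scale, so
#' hydrophobic-hydrophobic pairs score favorably (negative). This matrix is
#' SYNTHETIC — constructed, not fitted to structures — and only plays the
#' role of a fixed, documented pairwise preference table for the
#' mean-contact-potential feature channel.
#'
#' @return Symmetric 20 x 20 matrix with dimnames over the standard residues.
#' @export
contact_potential <- function() {
  h <- aa_hydropathy()[1:20]
  U <- -outer(h, h) / 10
  dimnames(U) <- list(aa_alphabet()[1:20], aa_alphabet()[1:20])
  U
}
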