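#' The 25-bin distance discretization scheme
#'
#' One open bin below 4.5 A, 23 half-open bins of width 0.5 A on [4.5, 16),
#' and one open bin at >= 16 A. Interior representatives are bin midpoints;
#' the open bins use 4.25 A (a physical Cb-Cb floor near 4 A) and 16.25 A.
#'
#' @return List with `edges` (length 24 inner boundaries, 4.5 .. 16),
#'   `lower`/`upper` per-bin bounds, and `representatives` (length 25, A).
#' @export
bin_scheme <- function() {
  edges <- seq(4.5, 16, by = 0.5)        # 24 boundaries -> 25 bins
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  reps <- c(4.25, edges[1:23] + 0.25, 16.25)
  list(edges = edges, lower = lower, upper = upper, representatives = reps,
       n_bins = 25L)
}

#' Discretize distances into the 25-bin scheme
#'
#' Half-open convention `[lower, upper)`: d < 4.5 -> bin 1, d >= 16 -> bin
#' 25 (1-based bin indices; subtract 1 for the 0-based labels some formats
#' use).
#'
#' @param d nonnegative distances (vector, matrix or array), in A.
#' @return Integer bin indices in 1..25, same shape as `d`.
#' @export
discretize <- function(d) {
  if (any(d < 0)) stop("negative distance")
  b <- findInterval(d, bin_scheme()$edges) + 1L
  if (!is.null(dim(d))) dim(b) <- dim(d)
  b
}

#' Convert a real-value distance map to relative contact scores
#'
#' Score = `1 / max(d, eps)`, so closer pairs rank higher; scores are
#' relative (only the ranking is contract-bound). Diagonal zeroed.
#'
#' @param D L x L distance map (A).
#' @param eps floor avoiding unbounded scores; default 0.1 A.
#' @return L x L score matrix.
#' @export
realdist_to_contact <- function(D, eps = 0.1) {
  if (any(D < 0)) stop("negative distance")
  S <- 1 / pmax(D, eps)
  diag(S) <- 0
  S
}

#' Convert a distogram to contact probabilities
#'
#' Contact probability = sum of bin probabilities for bins entirely below
#' the threshold (default 8 A: bin 1 plus the seven bins covering
#' [4.5, 8.0)).
#'
#' @param P L x L x 25 distogram.
#' @param threshold contact threshold in A; default 8.
#' @return L x L matrix of probabilities in [0, 1].
#' @export
distogram_to_contact <- function(P, threshold = 8) {
  bs <- bin_scheme()
  keep <- which(bs$upper <= threshold + 1e-9)
  apply(P[, , keep, drop = FALSE], c(1, 2), sum)
}

#' Convert a distogram to a real-value distance map with uncertainties
#'
#' Per pair: mean = probability-weighted mean of bin representatives, std =
#' the corresponding standard deviation. By default the open >= 16 A bin is
#' excluded and the remaining mass renormalized; pairs with (almost) all
#' mass in the excluded bin are flagged unpredictable (`NA` in both outputs)
#' so downstream restraint generation skips them.
#'
#' @param P L x L x 25 distogram.
#' @param include_last include the >= 16 A bin (representative 16.25 A)?
#'   Default FALSE.
#' @param min_mass minimum included mass below which a pair is flagged
#'   unpredictable; default 1e-6.
#' @return List with `mean` and `std` (L x L matrices, A; NA = flagged).
#' @export
distogram_to_realdist <- function(P, include_last = FALSE, min_mass = 1e-6) {
  bs <- bin_scheme()
  reps <- bs$representatives
  keep <- if (include_last) seq_len(25L) else seq_len(24L)
  Pk <- P[, , keep, drop = FALSE]
  mass <- apply(Pk, c(1, 2), sum)
  m1 <- apply(sweep(Pk, 3, reps[keep], `*`), c(1, 2), sum)
  m2 <- apply(sweep(Pk, 3, reps[keep]^2, `*`), c(1, 2), sum)
  mean <- m1 / mass
  std <- sqrt(pmax(m2 / mass - mean^2, 0))
  bad <- mass < min_mass
  mean[bad] <- NA_real_; std[bad] <- NA_real_
  list(mean = mean, std = std)
}

#' Elementwise ensemble average of prediction maps
#'
#' Averages real-value maps, contact maps, or distograms from the network x
#' MSA ensemble. Distograms (3D arrays) are renormalized per pair after
#' averaging (a no-op up to float error, since a mean of simplexes is a
#' simplex).
#'
#' @param maps nonempty list of equally shaped matrices or arrays.
#' @return The averaged map.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) == 0) stop("empty map list")
  d0 <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d0)) stop("shape mismatch in ensemble")
  if (length(maps) == 1) return(maps[[1]])
  # sum each element over the maps in sorted-value order, so the result is
  # bit-identical under any permutation of the input list
  M <- vapply(maps, as.vector, numeric(prod(d0)))
  out <- apply(M, 1, function(v) sum(sort(v))) / length(maps)
  dim(out) <- d0
  if (length(d0) == 3) {
    s <- apply(out, c(1, 2), sum)
    out <- sweep(out, c(1, 2), s, `/`)
  }
  out
}

#' Symmetrize a square map by transpose-averaging
#' @param M square matrix.
#' @return `(M + t(M)) / 2`.
#' @export
symmetrize <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("symmetrize needs a square matrix")
  (M + t(M)) / 2
}

#' Write / read a square matrix as a plain-text table
#' @param M matrix; `path` file path.
#' @param path file path.
#' @export
write_matrix_txt <- function(M, path) {
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
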