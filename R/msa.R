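#' Construct an MSA object
#'
#' An MSA holds aligned sequences over the 21-state alphabet (see
#' [aa_alphabet()]) as an integer matrix with one row per sequence. Sequence
#' weights and the effective sequence count `neff` are unset until
#' [compute_weights()] is called.
#'
#' @param seqs character vector of aligned sequences of equal length, or an
#'   integer matrix of encoded states (1..21).
#' @param ids sequence identifiers (recycled default if missing).
#' @param query_index row index of the target sequence.
#' @param wildcard wildcard policy passed to the encoder, see [aa_encode()].
#' @return An object of class `msa` with fields `ids`, `x` (n x L integer
#'   matrix), `query_index`, `weights` (NULL until computed), `neff`.
#' @export
new_msa <- function(seqs, ids = NULL, query_index = 1L, wildcard = "gap") {
  if (is.character(seqs)) {
    if (length(seqs) == 0L) stop("empty alignment")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    if (lens[1] < 1L) stop("alignment has zero columns")
    x <- matrix(aa_encode(unlist(strsplit(seqs, "")), wildcard = wildcard),
                nrow = length(seqs), byrow = TRUE)
  } else {
    x <- seqs
    storage.mode(x) <- "integer"
    if (nrow(x) == 0L || ncol(x) == 0L) stop("empty alignment")
    if (any(x < 1L | x > 21L)) stop("encoded states must lie in 1..21")
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(x)))
  structure(list(ids = as.character(ids), x = x,
                 query_index = as.integer(query_index),
                 weights = NULL, neff = NULL),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns%s\n", nrow(x$x), ncol(x$x),
              if (!is.null(x$neff)) sprintf(", Neff = %.2f", x$neff) else ""))
  invisible(x)
}

#' Number of columns (target length L) of an MSA
#' @param msa an `msa` object.
#' @export
msa_length <- function(msa) ncol(msa$x)

#' Number of rows (sequences) of an MSA
#' @param msa an `msa` object.
#' @export
msa_depth <- function(msa) nrow(msa$x)

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)   # tolerate Windows line endings
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, A3M (lowercase letters are insertions relative to
#' the query and are deleted), and plain one-sequence-per-line `.aln` files.
#' Non-standard residue codes are handled per the wildcard policy (default:
#' mapped to gap).
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"a3m"`, `"aln"`; `"auto"` guesses from
#'   the file extension and content.
#' @param wildcard see [aa_encode()].
#' @return An [new_msa()] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m", "aln"),
                     wildcard = "gap") {
  format <- match.arg(format)
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "a3m") "a3m"
      else if (startsWith(lines[1], ">")) "fasta"
      else "aln"
  }
  if (format == "aln") {
    seqs <- trimws(lines)
    ids <- paste0("seq", seq_along(seqs))
  } else {
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no FASTA headers in ", path)
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1)
    starts <- hdr + 1L
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(k) {
      if (starts[k] > ends[k]) "" else
        paste(lines[starts[k]:ends[k]], collapse = "")
    }, "")
    if (any(!nzchar(seqs))) stop("record with empty sequence in ", path)
    if (format == "a3m") # drop insert states (lowercase) relative to query
      seqs <- gsub("[a-z.]", "", seqs)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "),
         if (format == "a3m") " (after a3m insert removal)" else "")
  new_msa(seqs, ids = ids, wildcard = wildcard)
}

#' Write an MSA as aligned FASTA
#' @param msa an `msa` object.
#' @param path output file.
#' @export
write_msa <- function(msa, path) {
  ab <- aa_alphabet()
  seqs <- apply(msa$x, 1, function(r) paste(ab[r], collapse = ""))
  writeLines(paste0(">", msa$ids, "\n", seqs), path)
  invisible(path)
}

#' Sequence weights and effective sequence count
#'
#' Weight of sequence s is 1 / (number of sequences, including s, with
#' fractional identity >= `identity_threshold` to s); positions where either
#' sequence has a gap count as mismatches. `neff` is the sum of weights —
#' the standard identity-clustering reweighting of direct coupling analysis.
#'
#' @param msa an `msa` object.
#' @param identity_threshold fraction in (0, 1]; default 0.8.
#' @return The MSA with `weights` and `neff` set.
#' @export
compute_weights <- function(msa, identity_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  x <- msa$x
  n <- nrow(x); L <- ncol(x)
  # one-hot encode excluding gaps so that gap-vs-anything is a mismatch;
  # matches between two gaps also count as mismatches under this encoding
  oh <- matrix(0, n, L * 21L)
  idx <- cbind(rep(seq_len(n), L), (rep(seq_len(L), each = n) - 1L) * 21L + as.vector(x))
  keep <- as.vector(x) != aa_gap_index()
  oh[idx[keep, , drop = FALSE]] <- 1
  matches <- tcrossprod(oh)              # n x n counts of identical non-gap positions
  diag(matches) <- L                     # a sequence always matches itself
  cluster <- rowSums(matches >= identity_threshold * L - 1e-9)
  msa$weights <- 1 / cluster
  msa$neff <- sum(msa$weights)
  msa
}

#' Weighted column and column-pair frequencies
#'
#' Computes pseudocount-regularized, weight-normalized marginal frequencies
#' `f_i(a)` (L x 21) and pair frequencies `f_ij(a,b)` (L x L x 21 x 21). Each
#' marginal sums to 1; each pair table sums to 1 and satisfies
#' `f_ij(a,b) = f_ji(b,a)`; the diagonal satisfies `f_ii(a,a) = f_i(a)`.
#' Pseudocount `pc` adds `pc` total uniform mass per table before
#' normalization (i.e. `pc/21` per marginal cell, `pc/441` per pair cell).
#'
#' @param msa an `msa` with weights computed.
#' @param pseudocount nonnegative real; default 0.5.
#' @return List with `f1` (L x 21), `f2` (L x L x 21 x 21), `neff`.
#' @export
column_frequencies <- function(msa, pseudocount = 0.5) {
  if (is.null(msa$weights)) stop("call compute_weights() first")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  x <- msa$x
  n <- nrow(x); L <- ncol(x); q <- 21L
  w <- msa$weights
  oh <- matrix(0, n, L * q)              # full one-hot incl. gap state
  oh[cbind(rep(seq_len(n), L),
           (rep(seq_len(L), each = n) - 1L) * q + as.vector(x))] <- 1
  W <- sum(w)
  f1m <- crossprod(oh, w)                # (L*q) x 1 weighted counts
  f1 <- matrix(f1m, nrow = L, byrow = TRUE)
  f1 <- (f1 + pseudocount / q) / (W + pseudocount)
  pair <- crossprod(oh * sqrt(w))        # sym (L*q) x (L*q): sum_s w_s x_s x_s^T
  pair <- (pair + pseudocount / (q * q)) / (W + pseudocount)
  # reorder to [L, L, q, q]: pair[(i-1)q+a, (j-1)q+b] -> f2[i,j,a,b]
  f2 <- aperm(array(pair, dim = c(q, L, q, L)), c(2, 4, 1, 3))
  # diagonal pair tables are degenerate: set f_ii = diag(f_i) exactly so the
  # consistency invariant f_ii(a,a) = f_i(a) holds for any pseudocount
  for (i in seq_len(L)) f2[i, i, , ] <- diag(f1[i, ])
  list(f1 = f1, f2 = f2, neff = W, pseudocount = pseudocount)
}
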