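# shared fixtures and independent oracles, built in code at test time

toy_msa <- function(seqs = c("ACDEF", "ACDEF", "ACDDF", "AC-EF")) {
  compute_weights(new_msa(seqs))
}

# naive O(n * L^2) counting oracle for weighted frequencies, pseudocount pc
# spread as pc/21 per marginal cell and pc/441 per pair cell
oracle_frequencies <- function(msa, pc = 0) {
  x <- msa$x; w <- msa$weights
  n <- nrow(x); L <- ncol(x); q <- 21
  W <- sum(w)
  f1 <- matrix(pc / q, L, q)
  for (s in seq_len(n)) for (i in seq_len(L))
    f1[i, x[s, i]] <- f1[i, x[s, i]] + w[s]
  f1 <- f1 / (W + pc)
  f2 <- array(pc / (q * q), dim = c(L, L, q, q))
  for (s in seq_len(n)) for (i in seq_len(L)) for (j in seq_len(L))
    f2[i, j, x[s, i], x[s, j]] <- f2[i, j, x[s, i], x[s, j]] + w[s]
  f2 <- f2 / (W + pc)
  for (i in seq_len(L)) f2[i, i, , ] <- diag(f1[i, ])
  list(f1 = f1, f2 = f2)
}

# random MSA over the 21-state alphabet (gap-sparse), fixed seed upstream
random_msa <- function(n, L, gap_frac = 0.05) {
  probs <- c(rep((1 - gap_frac) / 20, 20), gap_frac)
  x <- matrix(sample.int(21, n * L, replace = TRUE, prob = probs), n, L)
  compute_weights(new_msa(x))
}

# symmetric toy distance map with controlled values
toy_distmap <- function(L, seed = 1) {
  set.seed(seed)
  co <- generate_structure(L, seed = seed)$distmap
  co
}

# enumeration oracle: rank eligible pairs, count true contacts in the top k
oracle_precision <- function(scores, truth, k, min_sep = 24, thr = 8) {
  L <- nrow(scores)
  recs <- NULL
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    if (j - i >= min_sep)
      recs <- rbind(recs, c(i, j, scores[i, j], truth[i, j]))
  }
  if (is.null(recs)) return(NA_real_)
  recs <- recs[order(-recs[, 3], recs[, 1], recs[, 2]), , drop = FALSE]
  k <- min(floor(k), nrow(recs))
  mean(recs[seq_len(k), 4] <= thr)
}

# write a temp fasta and return the path
write_temp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs)),
                             ext = ".fasta") {
  p <- tempfile(fileext = ext)
  writeLines(paste0(">", ids, "\n", seqs), p)
  p
}
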