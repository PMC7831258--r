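#' MSA-derived sequence profile
#'
#' Weighted per-column amino-acid frequencies over the 20 standard residues
#' (gaps excluded, renormalized) — the in-package substitute for an external
#' PSI-BLAST profile so the pipeline runs with no external binaries.
#'
#' @param msa an `msa` with weights computed.
#' @param log_odds if TRUE, return log2 odds against a uniform background
#'   (with a 0.01 floor) instead of frequencies.
#' @return `L x 20` matrix; rows sum to 1 when `log_odds = FALSE`.
#' @export
msa_profile <- function(msa, log_odds = FALSE) {
  if (is.null(msa$weights)) stop("call compute_weights() first")
  L <- ncol(msa$x); n <- nrow(msa$x)
  w <- msa$weights
  P <- matrix(0, L, 20L)
  for (i in seq_len(L)) {
    tab <- tapply(w, factor(msa$x[, i], levels = 1:21), sum)
    tab[is.na(tab)] <- 0
    p <- tab[1:20]
    s <- sum(p)
    P[i, ] <- if (s > 0) p / s else rep(1 / 20, 20)  # all-gap column: uniform
  }
  colnames(P) <- aa_alphabet()[1:20]
  if (log_odds) P <- log2(pmax(P, 0.01) / 0.05)
  P
}

#' Expand a 1D per-residue feature into a pairwise tensor
#'
#' Cell `(i, j)` carries the concatenation `feature(i), feature(j)`, so an
#' `L x k` feature becomes `L x L x 2k` and transposing swaps the halves:
#' `T[i,j,1:k] = T[j,i,(k+1):2k]`.
#'
#' @param onedim `L x k` matrix (a vector is treated as `L x 1`).
#' @return `L x L x 2k` array.
#' @export
pairwise_expand <- function(onedim) {
  if (is.vector(onedim)) onedim <- matrix(onedim, ncol = 1L)
  L <- nrow(onedim); k <- ncol(onedim)
  out <- array(0, dim = c(L, L, 2L * k))
  for (c in seq_len(k)) {
    out[, , c] <- matrix(onedim[, c], L, L)              # feature(i) by row
    out[, , k + c] <- matrix(onedim[, c], L, L, byrow = TRUE)  # feature(j)
  }
  out
}

#' Read a whitespace-table 1D feature file
#'
#' Adapter for externally computed per-residue features (PSI-BLAST PSSM-style
#' scores, 3-state secondary-structure probabilities, solvent
#' accessibility): a plain whitespace table with one row per residue,
#' optional header and optional leading index/residue columns (non-numeric
#' columns are dropped).
#'
#' @param path file path.
#' @param ncol_expect if given, error unless the numeric table has this many
#'   columns.
#' @return Numeric matrix with one row per residue.
#' @export
read_feature_table <- function(path, ncol_expect = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", fill = FALSE)
  if (nrow(df) > 0 && !all(vapply(df, is.numeric, TRUE))) {
    first <- suppressWarnings(vapply(df[1, ], function(v) is.na(as.numeric(v)), TRUE))
    if (any(!first) && any(first)) {
      # header-less with text columns vs. header row: retry with header
      df2 <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                               comment.char = "#")
      if (all(vapply(df2, is.numeric, TRUE))) df <- df2
    }
  }
  df <- df[, vapply(df, is.numeric, TRUE), drop = FALSE]
  if (ncol(df) == 0) stop("no numeric columns in feature table ", path)
  m <- as.matrix(df)
  if (!is.null(ncol_expect) && ncol(m) != ncol_expect)
    stop("feature table ", path, " has ", ncol(m), " numeric columns; expected ",
         ncol_expect)
  unname(m)
}

#' Per-branch input channel contracts
#'
#' The four network branches consume fixed channel stacks: COV = 441 pair
#' channels + 40 expanded profile + contact score + Pearson = 483; PLM =
#' 441 + 40 + Pearson = 482; PRE = 441 + 40 + joint entropy + 2 expanded
#' column-entropy = 484; OTHER (configurable default) = 40 profile + 6
#' expanded secondary structure + 2 expanded solvent accessibility + MI,
#' normalized MI, joint entropy, entropy sum, Pearson = 53.
#'
#' @param branch `"COV"`, `"PLM"`, `"PRE"` or `"OTHER"`.
#' @return Integer channel count.
#' @export
branch_channels <- function(branch) {
  switch(branch, COV = 483L, PLM = 482L, PRE = 484L, OTHER = 53L,
         stop("unknown branch: ", branch))
}

.pair_channel_names <- function(group) {
  ab <- aa_alphabet()
  paste0(group, ".", rep(ab, each = 21), rep(ab, 21))  # channel = (a-1)*21+b
}

.expand_names <- function(base, k) c(paste0(base, ".i", seq_len(k)),
                                     paste0(base, ".j", seq_len(k)))

#' Assemble the input tensor for one network branch
#'
#' Stacks the branch's feature blocks in a fixed manifest order into one
#' `L x L x C` tensor; see [branch_channels()] for the per-branch contracts.
#' All blocks must share the same L and be finite.
#'
#' @param branch `"COV"`, `"PLM"`, `"PRE"` or `"OTHER"`.
#' @param pair_tensor the branch's 441-channel [pair_block()] (COV/PLM/PRE;
#'   ignored for OTHER).
#' @param profile `L x 20` sequence profile.
#' @param stats list from [information_statistics()].
#' @param contact_score 1-channel [pair_block()] from
#'   [coupling_contact_score()] (COV branch only).
#' @param secondary_structure optional `L x 3` probabilities (OTHER branch);
#'   a flat (1/3, 1/3, 1/3) default is used when absent.
#' @param solvent_accessibility optional length-L vector (OTHER branch);
#'   defaults to 0.5.
#' @return A `branch_input` object: list of `branch`, `tensor` (L x L x C),
#'   `manifest` (channel names, length C).
#' @export
assemble_branch_input <- function(branch, pair_tensor = NULL, profile,
                                  stats, contact_score = NULL,
                                  secondary_structure = NULL,
                                  solvent_accessibility = NULL) {
  branch <- match.arg(branch, c("COV", "PLM", "PRE", "OTHER"))
  L <- nrow(profile)
  chk <- function(b, nm) {
    if (is.null(b)) stop("branch ", branch, " requires block ", nm)
    if (dim(b$values)[1] != L) stop("L mismatch in block ", nm, ": ",
                                    dim(b$values)[1], " vs ", L)
    b
  }
  prof2d <- pairwise_expand(profile)
  pieces <- list(); nm <- character(0)
  add3 <- function(arr, names) {
    pieces[[length(pieces) + 1L]] <<- arr
    nm <<- c(nm, names)
  }
  if (branch %in% c("COV", "PLM", "PRE")) {
    pt <- chk(pair_tensor, branch)
    add3(pt$values, .pair_channel_names(branch))
    add3(prof2d, .expand_names("profile", 20L))
    if (branch == "COV") {
      add3(chk(contact_score, "contact_score")$values, "contact_score")
      add3(chk(stats$pearson_correlation, "pearson")$values, "pearson_correlation")
    } else if (branch == "PLM") {
      add3(chk(stats$pearson_correlation, "pearson")$values, "pearson_correlation")
    } else {
      add3(chk(stats$joint_entropy, "joint_entropy")$values, "joint_entropy")
      ent <- -rowSums(ifelse(profile > 0, profile * log(profile), 0))
      add3(pairwise_expand(ent), .expand_names("column_entropy", 1L))
    }
  } else {
    if (is.null(secondary_structure))
      secondary_structure <- matrix(1 / 3, L, 3L)
    if (is.null(solvent_accessibility))
      solvent_accessibility <- rep(0.5, L)
    add3(prof2d, .expand_names("profile", 20L))
    add3(pairwise_expand(secondary_structure), .expand_names("ss3", 3L))
    add3(pairwise_expand(solvent_accessibility), .expand_names("acc", 1L))
    add3(chk(stats$mutual_information, "mi")$values, "mutual_information")
    add3(chk(stats$normalized_mi, "nmi")$values, "normalized_mi")
    add3(chk(stats$joint_entropy, "joint_entropy")$values, "joint_entropy")
    add3(chk(stats$shannon_entropy_sum, "entropy_sum")$values, "shannon_entropy_sum")
    add3(chk(stats$pearson_correlation, "pearson")$values, "pearson_correlation")
  }
  tensor <- array(0, dim = c(L, L, length(nm)))
  at <- 0L
  for (p in pieces) {
    k <- dim(p)[3]
    tensor[, , at + seq_len(k)] <- p
    at <- at + k
  }
  C <- branch_channels(branch)
  if (branch != "OTHER" && dim(tensor)[3] != C)
    stop("assembled ", branch, " tensor has ", dim(tensor)[3],
         " channels; contract requires ", C)
  if (length(nm) != dim(tensor)[3]) stop("manifest/channel-count mismatch")
  if (!all(is.finite(tensor))) stop("non-finite values in assembled tensor")
  structure(list(branch = branch, tensor = tensor, manifest = nm),
            class = "branch_input")
}

#' @export
print.branch_input <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("branch_input %s: %d x %d x %d channels\n", x$branch, d[1], d[2], d[3]))
  invisible(x)
}

#' Compute all feature blocks for one MSA
#'
#' Convenience driver: weights, frequencies, COV/PRE/PLM tensors, scalar
#' statistics, profile and contact score in one call.
#'
#' @param msa an `msa` object (weights computed if absent).
#' @param pseudocount passed to [column_frequencies()].
#' @param shrinkage passed to [precision_tensor()].
#' @param plm_budget iteration cap for [plm_tensor()].
#' @param branches which pair tensors to compute.
#' @return List with `msa`, `freqs`, `profile`, `stats`, and the requested
#'   blocks (`cov`, `pre`, `plm`, `contact_score`).
#' @export
compute_feature_set <- function(msa, pseudocount = 0.5, shrinkage = 0.1,
                                plm_budget = 100L,
                                branches = c("COV", "PLM", "PRE", "OTHER")) {
  if (is.null(msa$weights)) msa <- compute_weights(msa)
  freqs <- column_frequencies(msa, pseudocount)
  out <- list(msa = msa, freqs = freqs,
              profile = msa_profile(msa),
              stats = information_statistics(freqs))
  need_plm <- any(c("COV", "PLM") %in% branches)  # COV needs contact scores
  if (any(c("COV", "PRE") %in% branches)) {
    out$cov <- covariance_tensor(freqs)
    if ("PRE" %in% branches) out$pre <- precision_tensor(out$cov, shrinkage)
  }
  if (need_plm) {
    out$plm <- plm_tensor(msa, optimizer_budget = plm_budget)
    out$contact_score <- coupling_contact_score(out$plm)
  }
  out
}

#' Assemble every requested branch input from a feature set
#'
#' @param fs output of [compute_feature_set()].
#' @param branches branches to assemble.
#' @return Named list of `branch_input` objects.
#' @export
assemble_all_branches <- function(fs, branches = c("COV", "PLM", "PRE", "OTHER")) {
  out <- list()
  for (b in branches) {
    out[[b]] <- switch(b,
      COV = assemble_branch_input("COV", fs$cov, fs$profile, fs$stats,
                                  contact_score = fs$contact_score),
      PLM = assemble_branch_input("PLM", fs$plm, fs$profile, fs$stats),
      PRE = assemble_branch_input("PRE", fs$pre, fs$profile, fs$stats),
      OTHER = assemble_branch_input("OTHER", profile = fs$profile, stats = fs$stats))
  }
  out
}
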