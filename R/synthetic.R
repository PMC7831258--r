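# Synthetic world: toy self-avoiding backbones plus Potts-sampled MSAs
# whose column covariation is planted on spatially contacting pairs. This is
# what makes the whole pipeline — features, training, evaluation — testable
# without downloads. It deliberately omits real-protein energetics and
# phylogenetic correlation between sampled sequences.

#' Generate a toy protein backbone
#'
#' Seeded self-avoiding random chain with ~3.8 A virtual-bond steps:
#' consecutive residues are 3.0-4.5 A apart and non-adjacent residues at
#' least 3.0 A apart. A mild back-bias makes the chain compact enough to
#' form long-range contacts at realistic rates.
#'
#' @param L chain length (>= 5).
#' @param seed RNG seed; the same seed reproduces the same coordinates.
#' @param retry_budget restart budget for the placement loop; default 200.
#' @return A `toy_structure`: list with `L`, `coords` (L x 3, A), `distmap`
#'   (L x L), `contacts` (2-column matrix of pairs with distance <= 8 A).
#' @export
generate_structure <- function(L, seed = 1L, retry_budget = 200L) {
  stopifnot(L >= 5)
  set.seed(seed)
  step <- 3.8
  for (attempt in seq_len(retry_budget)) {
    coords <- matrix(NA_real_, L, 3)
    coords[1, ] <- 0
    dir <- c(1, 0, 0)
    coords[2, ] <- coords[1, ] + step * dir
    ok <- TRUE
    for (k in 3:L) {
      placed <- FALSE
      for (try in 1:60) {
        # propose a bend: previous direction plus noise, pulled toward the
        # centroid to keep the fold compact
        cen <- colMeans(coords[1:(k - 1), , drop = FALSE])
        pull <- cen - coords[k - 1, ]
        npull <- sqrt(sum(pull^2))
        if (npull > 0) pull <- pull / npull
        d <- dir + stats::rnorm(3, sd = 0.9) + 0.35 * pull
        d <- d / sqrt(sum(d^2))
        slen <- stats::runif(1, 3.3, 4.2)
        cand <- coords[k - 1, ] + slen * d
        dd <- sqrt(rowSums((coords[1:(k - 2), , drop = FALSE] -
                              matrix(cand, k - 2, 3, byrow = TRUE))^2))
        if (all(dd >= 3.0)) {
          coords[k, ] <- cand
          dir <- d
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      dm <- coords_to_distmap(coords)
      cp <- which(upper.tri(dm) & dm <= 8, arr.ind = TRUE)
      return(structure(list(L = L, coords = coords, distmap = dm,
                            contacts = unname(cp), seed = seed),
                       class = "toy_structure"))
    }
  }
  stop("chain placement failed after ", retry_budget,
       " restarts; increase retry_budget")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("toy_structure: L = %d, %d contacts at 8 A (seed %d)\n",
              x$L, nrow(x$contacts), x$seed))
  invisible(x)
}

#' Build a Potts model with couplings planted on structure contacts
#'
#' Fields are small random perturbations; couplings are nonzero only on
#' `n_planted` long-range (separation >= 6) contacts of the structure and
#' use a low-rank favored-pair pattern: two 4-residue symbol groups attract
#' within-group pairings with strength `coupling_strength`, so recovery by
#' coupling analysis is unambiguous.
#'
#' @param structure a [generate_structure()] result.
#' @param n_planted number of coupled pairs; default 10.
#' @param coupling_strength within-group coupling energy; default 1.5.
#' @param min_sep minimum separation of planted pairs; default 6.
#' @param seed RNG seed.
#' @return A `potts_model`: list of `L`, `h` (21 x L), `pairs` (n x 2),
#'   `J` (list of 21 x 21 coupling blocks, one per planted pair).
#' @export
plant_potts <- function(structure, n_planted = 10L, coupling_strength = 1.5,
                        min_sep = 6L, seed = 1L) {
  set.seed(seed + 1000L)
  L <- structure$L
  cp <- structure$contacts
  cand <- cp[cp[, 2] - cp[, 1] >= min_sep, , drop = FALSE]
  if (nrow(cand) == 0) {
    # short chains can lack well-separated contacts; fall back to the
    # longest separations available (never adjacent residues)
    cand <- cp[cp[, 2] - cp[, 1] >= 2, , drop = FALSE]
  }
  cp <- cand
  if (nrow(cp) == 0 && n_planted > 0)
    stop("structure has no contacts with separation >= 2; cannot plant couplings")
  # longest-range contacts first (where coupling analysis matters most),
  # greedily avoiding residue reuse so planted pairs are individually
  # identifiable
  ord <- order(-(cp[, 2] - cp[, 1]))
  used <- integer(0); sel <- integer(0)
  for (r in ord) {
    if (length(sel) >= n_planted) break
    if (!(cp[r, 1] %in% used) && !(cp[r, 2] %in% used)) {
      sel <- c(sel, r)
      used <- c(used, cp[r, ])
    }
  }
  for (r in ord) {            # fill up allowing reuse if needed
    if (length(sel) >= n_planted) break
    if (!(r %in% sel)) sel <- c(sel, r)
  }
  pairs <- cp[sel[seq_len(min(n_planted, length(sel)))], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  h <- matrix(stats::rnorm(21 * L, sd = 0.1), 21, L)
  h[21, ] <- -2                          # keep gaps rare
  g1 <- c(8, 10, 18, 5); g2 <- c(9, 15, 3, 4)   # I,L,V,F vs K,R,D,E states
  Jblk <- matrix(0, 21, 21)
  Jblk[g1, g1] <- coupling_strength
  Jblk[g2, g2] <- coupling_strength
  J <- replicate(nrow(pairs), Jblk, simplify = FALSE)
  base::structure(list(L = L, h = h, pairs = pairs, J = J,
                       coupling_strength = coupling_strength),
                  class = "potts_model")
}

#' Sample an MSA from a structure-coupled Potts model
#'
#' Runs `n_sequences` independent Gibbs chains (one per output sequence)
#' for `burn_in` full sweeps from independent field-only draws; with
#' independent chains the thinning interval is a no-op and kept only for
#' interface compatibility. `coupling_strength = 0` yields statistically
#' independent columns.
#'
#' @param structure a [generate_structure()] result.
#' @param n_sequences number of sequences (>= 2).
#' @param coupling_strength passed to [plant_potts()].
#' @param n_planted planted contact pairs; default 10.
#' @param seed RNG seed (also seeds the planted model).
#' @param burn_in Gibbs sweeps; default 200.
#' @param thin unused for independent chains; default 5.
#' @return An `msa` (weights unset) with attribute `"potts"` holding the
#'   generating model.
#' @export
simulate_msa <- function(structure, n_sequences = 500L,
                         coupling_strength = 1.5, n_planted = 10L,
                         seed = 1L, burn_in = 200L, thin = 5L) {
  stopifnot(n_sequences >= 2)
  pm <- plant_potts(structure, n_planted = n_planted,
                    coupling_strength = coupling_strength, seed = seed)
  set.seed(seed)
  L <- pm$L; n <- n_sequences; q <- 21L
  # neighbor lists from planted pairs
  nb <- vector("list", L)
  for (p in seq_along(pm$J)) {
    i <- pm$pairs[p, 1]; j <- pm$pairs[p, 2]
    nb[[i]] <- c(nb[[i]], list(list(j = j, J = pm$J[[p]])))
    nb[[j]] <- c(nb[[j]], list(list(j = i, J = t(pm$J[[p]]))))
  }
  Ucum <- upper.tri(diag(q), diag = TRUE)    # cumsum as a matmul
  softmax_sample <- function(logits) {
    # logits: n x q; one categorical draw per row (fully vectorized)
    m <- logits[, 1]
    for (a in 2:q) m <- pmax(m, logits[, a])
    P <- exp(logits - m)
    P <- P / rowSums(P)
    cum <- P %*% Ucum
    cum[, q] <- 1                        # guard against float undershoot
    u <- stats::runif(n)
    max.col(cum >= u, ties.method = "first")
  }
  # initialize from fields only
  X <- matrix(0L, n, L)
  for (i in seq_len(L))
    X[, i] <- softmax_sample(matrix(pm$h[, i], n, q, byrow = TRUE))
  for (sw in seq_len(burn_in)) {
    for (i in seq_len(L)) {
      logits <- matrix(pm$h[, i], n, q, byrow = TRUE)
      for (e in nb[[i]])
        logits <- logits + t(e$J[, X[, e$j]])
      X[, i] <- softmax_sample(logits)
    }
  }
  m <- new_msa(X, ids = sprintf("sim%04d", seq_len(n)))
  attr(m, "potts") <- pm
  m
}

#' Deterministic synthetic training dataset
#'
#' Generates `n_targets` toy structures with Potts-sampled MSAs, computes
#' features, assembles the requested branch inputs, and pairs them with
#' [training_target()]s. All randomness flows from `seed` via per-target
#' derived seeds (`seed * 1000 + t`), recorded in the manifest.
#'
#' @param n_targets number of targets.
#' @param L_range inclusive range for chain lengths; default c(28, 34).
#' @param n_sequences MSA depth per target; default 300.
#' @param coupling_strength Potts coupling strength; default 1.5.
#' @param n_planted planted pairs per target; default 10.
#' @param branches branch inputs to assemble; default "COV".
#' @param plm_budget PLM iteration cap while building features; default 50.
#' @param seed master seed.
#' @return List with `targets` (each: `structure`, `msa`, `inputs` (named by
#'   branch), `target`) and `manifest` (data.frame of per-target seeds/sizes).
#' @export
make_dataset <- function(n_targets, L_range = c(28, 34), n_sequences = 300L,
                         coupling_strength = 1.5, n_planted = 10L,
                         branches = "COV", plm_budget = 50L, seed = 7L) {
  targets <- vector("list", n_targets)
  man <- data.frame(target = integer(0), seed = integer(0), L = integer(0),
                    n_sequences = integer(0), n_contacts = integer(0))
  for (t in seq_len(n_targets)) {
    ts <- seed * 1000L + t
    set.seed(ts)
    L <- sample(seq(L_range[1], L_range[2]), 1)
    st <- generate_structure(L, seed = ts)
    msa <- simulate_msa(st, n_sequences = n_sequences,
                        coupling_strength = coupling_strength,
                        n_planted = n_planted, seed = ts)
    fs <- compute_feature_set(msa, plm_budget = plm_budget,
                              branches = branches)
    inputs <- assemble_all_branches(fs, branches)
    targets[[t]] <- list(structure = st, msa = msa, inputs = inputs,
                         target = training_target(st$distmap))
    man <- rbind(man, data.frame(target = t, seed = ts, L = L,
                                 n_sequences = n_sequences,
                                 n_contacts = nrow(st$contacts)))
  }
  list(targets = targets, manifest = man)
}

#' Write a synthetic fixture tree to disk
#'
#' One directory per target containing the MSA (aligned FASTA), the toy
#' coordinates (PDB), the true distance map (plain text) and a manifest.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(ds$targets)) {
    td <- file.path(dir, sprintf("target%03d", t))
    dir.create(td, showWarnings = FALSE)
    tg <- ds$targets[[t]]
    write_msa(tg$msa, file.path(td, "alignment.fasta"))
    write_pdb_cb(tg$structure$coords, file.path(td, "structure.pdb"))
    write_matrix_txt(tg$structure$distmap, file.path(td, "distmap.txt"))
  }
  utils::write.table(ds$manifest, file.path(dir, "manifest.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(dir)
}
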