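#' Generate Cb-Cb distance restraints from a predicted distance map
#'
#' Selects upper-triangle pairs with predicted distance <= `max_dist`
#' (default 15 A) and sequence separation >= `min_sep` (default 3); each
#' restraint targets the predicted distance with bounds `target +/- delta`
#' (default 0.1 A, i.e. a 0.2 A window) between Cb atoms (Ca for glycine).
#' `NA` predictions (pairs flagged unpredictable upstream) are skipped.
#'
#' @param D L x L symmetric predicted distance map (A).
#' @param max_dist maximum restrained distance; default 15 A.
#' @param min_sep minimum sequence separation; default 3.
#' @param delta half-width of the bound window; default 0.1 A.
#' @return A `restraint_set`: data.frame with columns `i`, `j` (1-based),
#'   `target`, `lower`, `upper`.
#' @export
make_restraints <- function(D, max_dist = 15, min_sep = 3, delta = 0.1) {
  L <- nrow(D)
  sel <- which(upper.tri(D) & (col(D) - row(D)) >= min_sep &
                 !is.na(D) & D <= max_dist)
  df <- data.frame(i = row(D)[sel], j = col(D)[sel], target = D[sel])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df$lower <- df$target - delta
  df$upper <- df$target + delta
  structure(df, class = c("restraint_set", "data.frame"),
            delta = delta, max_dist = max_dist, min_sep = min_sep)
}

#' Nested restraint subsets at the five folding cutoffs
#'
#' Filters the restraint pool at cutoffs 11, 12, 13, 14, 15 A (restraints
#' with target >= cutoff dropped), producing five nested sets — the subset
#' schedule fed to distance-geometry folding.
#'
#' @param D L x L predicted distance map.
#' @param cutoffs cutoff vector; default `c(11, 12, 13, 14, 15)`.
#' @param ... passed to [make_restraints()].
#' @return Named list of `restraint_set`s (`"11"` .. `"15"`).
#' @export
make_subsets <- function(D, cutoffs = c(11, 12, 13, 14, 15), ...) {
  full <- make_restraints(D, max_dist = max(cutoffs), ...)
  out <- lapply(cutoffs, function(x) {
    s <- full[full$target < x, , drop = FALSE]
    rownames(s) <- NULL
    structure(s, class = c("restraint_set", "data.frame"),
              delta = attr(full, "delta"), max_dist = x,
              min_sep = attr(full, "min_sep"))
  })
  names(out) <- as.character(cutoffs)
  out
}

#' Sum of restraint violations of a set of coordinates
#'
#' For each restraint, the realized Cb-Cb distance `d` contributes
#' `max(0, lower - d) + max(0, d - upper)`; the score is the sum — the
#' energy used to rank candidate models. Restraints touching residues with
#' missing coordinates are skipped and counted.
#'
#' @param coords L x 3 matrix of per-residue Cb coordinates (Ca for
#'   glycine); rows of `NA` mark missing residues.
#' @param restraints a `restraint_set`.
#' @return Nonnegative scalar with attribute `n_skipped`.
#' @export
violation_score <- function(coords, restraints) {
  have <- stats::complete.cases(coords)
  ok <- have[restraints$i] & have[restraints$j]
  if (any(!ok))
    warning(sum(!ok), " restraint(s) skipped: missing coordinates")
  r <- restraints[ok, , drop = FALSE]
  d <- sqrt(rowSums((coords[r$i, , drop = FALSE] -
                       coords[r$j, , drop = FALSE])^2))
  s <- sum(pmax(0, r$lower - d) + pmax(0, d - r$upper))
  attr(s, "n_skipped") <- sum(!ok)
  s
}

#' Write a restraint set to disk
#'
#' `cns_tbl` emits one CNS-dialect `assign` record per restraint with the
#' `(target, minus-delta, plus-delta)` convention:
#' `assign (resid I and name CB) (resid J and name CB) target delta delta`.
#' `tabular` writes a delimited table of the underlying data.frame.
#'
#' @param restraints a `restraint_set`.
#' @param path output file.
#' @param format `"cns_tbl"` or `"tabular"`.
#' @param atom_names optional character vector of per-residue atom names
#'   (`"CB"`/`"CA"`); defaults to `"CB"` everywhere.
#' @return The path, invisibly.
#' @export
write_restraints <- function(restraints, path,
                             format = c("cns_tbl", "tabular"),
                             atom_names = NULL) {
  format <- match.arg(format)
  if (format == "tabular") {
    utils::write.table(as.data.frame(restraints), path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
    return(invisible(path))
  }
  delta <- attr(restraints, "delta")
  if (is.null(delta)) delta <- 0.1
  an <- function(k) if (is.null(atom_names)) "CB" else atom_names[k]
  lines <- c("! distance restraints (CNS dialect: target dminus dplus)")
  if (nrow(restraints) > 0)
    lines <- c(lines, sprintf(
      "assign (resid %d and name %s) (resid %d and name %s) %.2f %.2f %.2f",
      restraints$i, vapply(restraints$i, an, ""),
      restraints$j, vapply(restraints$j, an, ""),
      restraints$target, delta, delta))
  writeLines(lines, path)
  invisible(path)
}

#' Write contacts in CASP RR format
#'
#' Header (`PFRMAT RR`, optional target/model lines) followed by
#' `i j 0 8 p` records sorted by descending score, 1-based indices.
#'
#' @param scores L x L contact score matrix (probabilities preferred).
#' @param path output file.
#' @param target target name for the header.
#' @param min_sep minimum separation of emitted pairs; default 1.
#' @param max_records cap on emitted records (NULL = all).
#' @return The path, invisibly.
#' @export
write_contacts_rr <- function(scores, path, target = "T0000", min_sep = 1,
                              max_records = NULL) {
  sel <- which(upper.tri(scores) & (col(scores) - row(scores)) >= min_sep)
  i <- row(scores)[sel]; j <- col(scores)[sel]; p <- scores[sel]
  ord <- order(-p, i, j)
  i <- i[ord]; j <- j[ord]; p <- p[ord]
  if (!is.null(max_records) && length(i) > max_records) {
    keep <- seq_len(max_records)
    i <- i[keep]; j <- j[keep]; p <- p[keep]
  }
  lines <- c("PFRMAT RR", paste("TARGET", target), "MODEL 1",
             sprintf("%d %d 0 8 %.6f", i, j, p), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file
#' @param path RR file written by [write_contacts_rr()] (or compatible).
#' @return data.frame with columns `i`, `j`, `lower`, `upper`, `score`.
#' @export
read_contacts_rr <- function(path) {
  lines <- .read_lines(path)
  rec <- grep("^\\s*\\d+\\s+\\d+\\s", lines, value = TRUE)
  if (length(rec) == 0)
    return(data.frame(i = integer(0), j = integer(0), lower = numeric(0),
                      upper = numeric(0), score = numeric(0)))
  parts <- do.call(rbind, lapply(strsplit(trimws(rec), "\\s+"), as.numeric))
  data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
             lower = parts[, 3], upper = parts[, 4], score = parts[, 5])
}

# ---- minimal PDB coordinate I/O -------------------------------------------
# No PDB parser exists in the supported R stack, so the few fields the
# restraint module needs are read here directly (first model, first altloc).

#' Read per-residue Cb coordinates from a PDB file
#'
#' Extracts one coordinate row per residue: the CB atom, or CA for glycine
#' (and as fallback when CB is absent). Only the first MODEL and the first
#' altloc are considered; residues are returned in order of residue number
#' of the requested chain.
#'
#' @param path PDB file.
#' @param chain chain identifier; default: first chain encountered.
#' @return List with `coords` (n x 3 matrix), `resno`, `resname`, `chain`.
#' @export
read_pdb_cb <- function(path, chain = NULL) {
  lines <- .read_lines(path)
  end1 <- grep("^ENDMDL", lines)
  if (length(end1)) lines <- lines[seq_len(end1[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(at) == 0) stop("no ATOM records in ", path)
  fld <- function(s, a, b) trimws(substr(s, a, b))
  name <- fld(at, 13, 16)
  alt <- fld(at, 17, 17)
  resn <- fld(at, 18, 20)
  ch <- fld(at, 22, 22)
  resno <- as.integer(fld(at, 23, 26))
  x <- as.numeric(fld(at, 31, 38)); y <- as.numeric(fld(at, 39, 46))
  z <- as.numeric(fld(at, 47, 54))
  keep <- alt %in% c("", "A")
  if (is.null(chain)) chain <- ch[1]
  keep <- keep & ch == chain & name %in% c("CA", "CB")
  name <- name[keep]; resn <- resn[keep]; resno <- resno[keep]
  xyz <- cbind(x[keep], y[keep], z[keep])
  ures <- unique(resno)
  coords <- matrix(NA_real_, length(ures), 3)
  rn <- character(length(ures))
  for (k in seq_along(ures)) {
    rows <- which(resno == ures[k])
    rn[k] <- resn[rows[1]]
    pick <- if (rn[k] == "GLY") rows[name[rows] == "CA"] else {
      cb <- rows[name[rows] == "CB"]
      if (length(cb)) cb else rows[name[rows] == "CA"]
    }
    if (length(pick)) coords[k, ] <- xyz[pick[1], ]
  }
  list(coords = coords, resno = ures, resname = rn, chain = chain)
}

#' Write a toy backbone as a PDB file (CA + CB pseudo-atoms)
#'
#' Serializer for synthetic structures: writes each residue's coordinate as
#' both CA and CB of an alanine (glycine gets CA only), which is all the
#' downstream distance machinery reads back.
#'
#' @param coords L x 3 coordinate matrix.
#' @param path output file.
#' @param resnames optional 3-letter residue names; default "ALA".
#' @return The path, invisibly.
#' @export
write_pdb_cb <- function(coords, path, resnames = NULL) {
  L <- nrow(coords)
  if (is.null(resnames)) resnames <- rep("ALA", L)
  serial <- 0L
  lines <- character(0)
  for (k in seq_len(L)) {
    atoms <- if (resnames[k] == "GLY") "CA" else c("CA", "CB")
    for (a in atoms) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, a, resnames[k], k, coords[k, 1], coords[k, 2], coords[k, 3]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Pairwise distance map from coordinates
#' @param coords L x 3 matrix.
#' @return L x L symmetric distance matrix (A), zero diagonal.
#' @export
coords_to_distmap <- function(coords) {
  m <- as.matrix(stats::dist(coords))
  dimnames(m) <- NULL
  m
}
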