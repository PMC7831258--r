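#' The 21-letter amino-acid alphabet used by all feature tensors
#'
#' Twenty standard amino acids in alphabetical one-letter order, followed by
#' the gap symbol `-` as the 21st state. Every pairwise tensor in the package
#' indexes its 441 = 21 x 21 amino-acid-pair channels by this order.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' @rdname aa_alphabet
#' @export
aa_gap_index <- function() 21L

# ambiguity / non-standard codes remapped during sanitization
.aa_wildcards <- c("B", "Z", "X", "U", "O", "J")

#' Map residue characters to integer states
#'
#' @param chars character vector of single residue letters.
#' @param wildcard policy for non-standard codes (B/Z/X/U/O/J): `"gap"` maps
#'   them to the gap state; `"error"` rejects them.
#' @return Integer states in 1..21.
#' @keywords internal
aa_encode <- function(chars, wildcard = c("gap", "error")) {
  wildcard <- match.arg(wildcard)
  chars <- toupper(chars)
  chars[chars %in% c(".", "*")] <- "-"
  bad <- chars %in% .aa_wildcards
  if (any(bad)) {
    if (wildcard == "error") stop("non-standard residue code(s): ",
                                  paste(unique(chars[bad]), collapse = ", "))
    chars[bad] <- "-"
  }
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) stop("unrecognized residue code(s): ",
                       paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}
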