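# IUPAC nucleotide alphabet: code -> set of concrete bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_SETS)

# base-set (sorted, collapsed) -> IUPAC code
IUPAC_FROM_SET <- setNames(
  names(IUPAC_SETS),
  vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), character(1))
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Validate an IUPAC nucleotide string
#'
#' Uppercases the input and checks every character against the 15-letter IUPAC
#' nucleotide alphabet (`A C G T` plus ambiguity codes and `N`).
#'
#' @param seq Character scalar.
#' @param what Label used in error messages (e.g. a record id).
#' @return The validated, uppercased sequence.
#' @keywords internal
validate_seq <- function(seq, what = "sequence") {
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("%s: non-IUPAC character '%s' at offset %d",
                  what, chars[bad[1]], bad[1]))
  }
  seq
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Complements every symbol under the IUPAC code table (`K` <-> `M`,
#' `R` <-> `Y`, `S`/`W`/`N` self-complementary, `B` <-> `V`, `D` <-> `H`)
#' and reverses the string, so that `reverse_complement()` is an involution.
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' reverse_complement("AAK")    # "MTT"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- validate_seq(s)
    chars <- IUPAC_COMPLEMENT[seq_chars(s)]
    paste(rev(chars), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Degeneracy of an IUPAC string
#'
#' The number of concrete (A/C/G/T-only) sequences an IUPAC string represents:
#' the product over positions of the size of each symbol's base set.
#'
#' @param iupac_seq Character scalar, IUPAC nucleotides.
#' @return Integer count (may overflow to `Inf`-like doubles for long N runs;
#'   returned as double).
#' @examples
#' degeneracy("ACGT") # 1
#' degeneracy("ACKGCTCAGTAACACGTG") # 2
#' degeneracy("NN") # 16
#' @export
degeneracy <- function(iupac_seq) {
  s <- validate_seq(iupac_seq)
  prod(vapply(IUPAC_SETS[seq_chars(s)], length, integer(1)))
}

#' Expand an IUPAC string into all concrete variants
#'
#' Enumerates, in lexicographic order, every A/C/G/T sequence compatible with
#' the IUPAC string. Refuses to expand beyond `cap` variants.
#'
#' @param iupac_seq Character scalar.
#' @param cap Maximum number of variants to enumerate (default 64).
#' @return Character vector of `degeneracy(iupac_seq)` sequences.
#' @export
expand_iupac <- function(iupac_seq, cap = 64) {
  s <- validate_seq(iupac_seq)
  d <- degeneracy(s)
  if (d > cap) {
    abort(sprintf("degeneracy %d exceeds cap %d for '%s'", d, cap, s))
  }
  sets <- lapply(IUPAC_SETS[seq_chars(s)], sort)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}
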