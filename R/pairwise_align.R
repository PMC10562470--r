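# Affine-gap local alignment core used by locus extraction, in-silico PCR
# evaluation and read classification.

#' Alignment scoring scheme
#'
#' Match reward, mismatch penalty and affine gap costs. A gap of length k
#' costs `gap_open + k * gap_extend`. Defaults (+2, -3, open 5, extend 2)
#' mirror blastn defaults. IUPAC ambiguity codes in either sequence score as a
#' match whenever their base sets intersect, which is what degenerate primers
#' require downstream.
#'
#' @param match Positive integer reward.
#' @param mismatch Negative integer penalty.
#' @param gap_open Non-negative gap opening cost.
#' @param gap_extend Non-negative per-base gap extension cost,
#'   `<= gap_open`.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0) abort("match reward must be positive")
  if (mismatch >= 0) abort("mismatch penalty must be negative")
  if (gap_extend < 0 || gap_open < gap_extend) {
    abort("need gap_open >= gap_extend >= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Local pairwise alignment (Smith-Waterman-Gotoh)
#'
#' Exact maximum-scoring local alignment under affine gaps, fully
#' deterministic: among equal-scoring end cells the smallest end on `a` wins,
#' then the smallest end on `b`; traceback prefers diagonal over up over left.
#' Coordinates are 0-based half-open. A pair with no positive-scoring cell
#' returns score 0 and an empty span.
#'
#' @param a,b Non-empty IUPAC nucleotide strings.
#' @param scoring A [scoring_scheme()].
#' @param traceback If `FALSE`, only the score and end coordinates are
#'   computed (faster; used to scan a reference panel before aligning the
#'   winner in full).
#' @return A `local_alignment` list: `score`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `matches`, `columns`, `gapped_a`, `gapped_b`.
#' @export
local_align <- function(a, b, scoring = scoring_scheme(), traceback = TRUE) {
  if (!nzchar(a) || !nzchar(b)) abort("local_align: empty sequence")
  a <- validate_seq(a); b <- validate_seq(b)
  if (!traceback) {
    score <- .swg_score_cpp(a, b, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)
    return(structure(list(score = score, a_start = NA_integer_,
                          a_end = NA_integer_, b_start = NA_integer_,
                          b_end = NA_integer_, matches = NA_integer_,
                          columns = NA_integer_, gapped_a = "", gapped_b = ""),
                     class = "local_alignment"))
  }
  res <- .swg_align_cpp(a, b, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend, TRUE)
  structure(res, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> score %d, a[%d,%d) b[%d,%d), %d/%d matched columns\n",
              x$score, x$a_start, x$a_end, x$b_start, x$b_end, x$matches, x$columns))
  invisible(x)
}

#' Identity and reference coverage of an alignment
#'
#' Identity is `matches / columns` with gap columns included in the
#' denominator; reference coverage is the aligned reference span divided by
#' the full reference length. These are the two quantities gating taxonomic
#' assignment (the classifier requires coverage > 0.6 and identity > 0.8).
#'
#' @param aln A `local_alignment` whose `b` sequence is the reference.
#' @param ref_len Full reference length (bases), `>=` the aligned span.
#' @return Named list `identity`, `ref_coverage`, both in `[0, 1]`.
#' @export
identity_and_coverage <- function(aln, ref_len) {
  if (ref_len <= 0) abort("ref_len must be positive")
  span <- aln$b_end - aln$b_start
  if (ref_len < span) abort("ref_len smaller than the aligned reference span")
  identity <- if (aln$columns == 0) 0 else aln$matches / aln$columns
  list(identity = identity, ref_coverage = span / ref_len)
}
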