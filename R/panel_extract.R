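# Locate the 16S locus in each genome by local alignment to a reference 16S
# gene, extract it, reorient minus-strand copies, and assemble the panel.

#' Locate the 16S locus in a genome
#'
#' Aligns the reference 16S gene against both strands of the genome and keeps
#' the better local alignment. Coordinates are always reported on the forward
#' strand of the genome (0-based half-open); `strand == "-"` marks a locus
#' whose gene lies on the reverse strand (genomes do embed the gene on either
#' strand). Returns `NULL` when the best hit fails the identity or
#' reference-coverage floor.
#'
#' @param genome,ref16s Single-row sequence tibbles (or lists with `id`,
#'   `seq`), as from [read_fasta()].
#' @param scoring A [scoring_scheme()].
#' @param min_identity Minimum identity (matches/columns) to accept, default 0.70.
#' @param min_cov Minimum reference coverage to accept, default 0.50.
#' @return One-row tibble `genome_id, start, end, strand, identity, score`,
#'   or `NULL` if no qualifying hit.
#' @export
find_16s_locus <- function(genome, ref16s, scoring = scoring_scheme(),
                           min_identity = 0.70, min_cov = 0.50) {
  gseq <- validate_seq(genome$seq[[1]], genome$id[[1]])
  rseq <- validate_seq(ref16s$seq[[1]], ref16s$id[[1]])
  glen <- nchar(gseq)
  fwd <- local_align(rseq, gseq, scoring)
  rev <- local_align(rseq, reverse_complement(gseq), scoring)
  if (fwd$score >= rev$score) {
    aln <- fwd; strand <- "+"
    start <- aln$b_start; end <- aln$b_end
  } else {
    aln <- rev; strand <- "-"
    start <- glen - aln$b_end; end <- glen - aln$b_start
  }
  met <- identity_and_coverage(aln, nchar(rseq))
  if (met$identity < min_identity || met$ref_coverage < min_cov) return(NULL)
  tibble(genome_id = genome$id[[1]], start = start, end = end,
         strand = strand, identity = met$identity, score = aln$score,
         ref_coverage = met$ref_coverage)
}

#' Extract the 16S sequence at a locus, reference-oriented
#'
#' Slices `[start - flank, end + flank)` (clamped to the genome) and reverse
#' complements minus-strand loci so every panel entry shares the reference
#' orientation.
#'
#' @param genome One-row sequence tibble.
#' @param hit One-row locus tibble from [find_16s_locus()].
#' @param flank Extra bases on each side (default 0), clamped at the ends.
#' @return One-row tibble `genome_id, seq, start, end, strand`.
#' @export
extract_oriented <- function(genome, hit, flank = 0) {
  gseq <- genome$seq[[1]]
  glen <- nchar(gseq)
  if (hit$start < 0 || hit$end > glen || hit$start >= hit$end) {
    abort(sprintf("locus [%d,%d) outside genome '%s' (length %d)",
                  hit$start, hit$end, genome$id[[1]], glen))
  }
  lo <- max(0, hit$start - flank)
  hi <- min(glen, hit$end + flank)
  s <- substr(gseq, lo + 1, hi)
  if (hit$strand == "-") s <- reverse_complement(s)
  tibble(genome_id = genome$id[[1]], seq = s,
         start = lo, end = hi, strand = hit$strand)
}

#' Build the 16S panel from a set of genomes
#'
#' One reference-oriented entry per genome with a qualifying 16S hit, in input
#' order; genomes with no qualifying hit are listed in the `skipped` report
#' with the failing criterion. Precomputed BLAST-style hits (reference as
#' query, genome as subject) can be supplied instead of aligning internally.
#'
#' @param genomes Sequence tibble, one row per genome.
#' @param ref16s One-row sequence tibble with the reference gene.
#' @param scoring A [scoring_scheme()].
#' @param min_identity,min_cov Acceptance floors (see [find_16s_locus()]).
#' @param flank Flank passed to [extract_oriented()].
#' @param hits Optional tibble from [read_tabular_hits()]; the best hit
#'   (highest bitscore) per genome is used in place of internal alignment.
#' @return List with `panel` (tibble `genome_id, seq, start, end, strand`)
#'   and `skipped` (tibble `genome_id, reason`).
#' @export
build_panel <- function(genomes, ref16s, scoring = scoring_scheme(),
                        min_identity = 0.70, min_cov = 0.50, flank = 0,
                        hits = NULL) {
  if (nrow(genomes) == 0) abort("no genomes supplied")
  ref_len <- nchar(ref16s$seq[[1]])
  entries <- list(); skipped <- list()
  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, ]
    if (is.null(hits)) {
      h <- find_16s_locus(g, ref16s, scoring, min_identity = 0, min_cov = 0)
      reason <- if (h$identity < min_identity) {
        "identity below threshold"
      } else if (h$ref_coverage < min_cov) {
        "reference coverage below threshold"
      } else NA_character_
      if (!is.na(reason)) {
        skipped[[length(skipped) + 1]] <- tibble(genome_id = g$id, reason = reason)
        next
      }
    } else {
      gh <- normalize_hits(hits[hits$subject_id == g$id, , drop = FALSE])
      if (nrow(gh) == 0) {
        skipped[[length(skipped) + 1]] <-
          tibble(genome_id = g$id, reason = "no hit")
        next
      }
      gh <- gh[order(-gh$bitscore, gh$s_lo), ][1, ]
      ident <- gh$pct_identity / 100
      cov <- (gh$q_hi - gh$q_lo) / ref_len
      if (ident < min_identity || cov < min_cov) {
        reason <- if (ident < min_identity) "identity below threshold"
                  else "reference coverage below threshold"
        skipped[[length(skipped) + 1]] <- tibble(genome_id = g$id, reason = reason)
        next
      }
      h <- tibble(genome_id = g$id, start = gh$s_lo, end = gh$s_hi,
                  strand = gh$strand, identity = ident,
                  score = gh$bitscore, ref_coverage = cov)
    }
    entries[[length(entries) + 1]] <- extract_oriented(g, h, flank)
  }
  if (length(entries) == 0) abort("empty panel: no genome had a qualifying 16S hit")
  list(
    panel = dplyr::bind_rows(entries),
    skipped = if (length(skipped)) dplyr::bind_rows(skipped)
              else tibble(genome_id = character(), reason = character())
  )
}
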