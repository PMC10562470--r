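# Long-read classification: length filter + best-reference OTU rule
# (coverage/identity thresholds) + rank summaries + classifier agreement.

#' Read classification parameters
#'
#' Reads between `len_lo` and `len_hi` (inclusive) are kept; a kept read is
#' classified when its best local alignment to the reference panel has
#' reference coverage strictly greater than `min_ref_cov` AND identity
#' strictly greater than `min_identity` ("more than 60% reference coverage and
#' 80% pairwise similarity" read as strict on both, so reads sitting exactly
#' on a boundary stay unclassified).
#'
#' @param len_lo,len_hi Inclusive read-length window (defaults 1250 and 1750
#'   bases, the full-length 16S amplicon window).
#' @param min_ref_cov Reference-coverage threshold (default 0.60).
#' @param min_identity Identity threshold, matches over alignment columns
#'   including gap columns (default 0.80).
#' @return A `classify_params` list.
#' @export
classify_params <- function(len_lo = 1250, len_hi = 1750,
                            min_ref_cov = 0.60, min_identity = 0.80) {
  if (len_lo > len_hi) abort("len_lo > len_hi")
  if (min_ref_cov <= 0 || min_ref_cov > 1 || min_identity <= 0 || min_identity > 1) {
    abort("thresholds must be in (0, 1]")
  }
  structure(list(len_lo = len_lo, len_hi = len_hi,
                 min_ref_cov = min_ref_cov, min_identity = min_identity),
            class = "classify_params")
}

#' Partition reads by the length filter
#'
#' @param reads Sequence tibble.
#' @param params A [classify_params()].
#' @return List `kept`, `removed`; an exact partition of the input.
#' @export
length_filter <- function(reads, params = classify_params()) {
  n <- nchar(reads$seq)
  keep <- n >= params$len_lo & n <= params$len_hi
  list(kept = reads[keep, , drop = FALSE], removed = reads[!keep, , drop = FALSE])
}

#' Assign one read to its best reference
#'
#' The best reference is the one with the highest local alignment score (ties
#' broken toward the lexicographically smallest reference id). The read is
#' `classified` only when both OTU thresholds are strictly exceeded; otherwise
#' it is `unclassified` with its metrics reported. Single best-hit assignment,
#' no LCA over near-ties.
#'
#' @param read One-row sequence tibble (assumed length-filtered).
#' @param refdb Sequence tibble of references.
#' @param taxonomy Tibble (`id`, `lineage`) covering at least the classified
#'   best reference.
#' @param params A [classify_params()].
#' @param scoring A [scoring_scheme()].
#' @return One-row tibble `read_id, status, best_ref, identity, ref_coverage,
#'   lineage`.
#' @export
assign_read <- function(read, refdb, taxonomy, params = classify_params(),
                        scoring = scoring_scheme()) {
  if (nrow(refdb) == 0) abort("empty reference database")
  scores <- vapply(refdb$seq, function(r) {
    local_align(read$seq[[1]], r, scoring, traceback = FALSE)$score
  }, double(1), USE.NAMES = FALSE)
  cand <- which(scores == max(scores))
  best <- cand[order(refdb$id[cand])][1]
  aln <- local_align(read$seq[[1]], refdb$seq[[best]], scoring)
  met <- identity_and_coverage(aln, nchar(refdb$seq[[best]]))
  ok <- met$ref_coverage > params$min_ref_cov && met$identity > params$min_identity
  lineage <- ""
  if (ok) {
    lin <- taxonomy$lineage[match(refdb$id[best], taxonomy$id)]
    if (is.na(lin)) {
      abort(sprintf("no lineage for best reference '%s'", refdb$id[best]))
    }
    lineage <- lin
  }
  tibble(read_id = read$id[[1]],
         status = if (ok) "classified" else "unclassified",
         best_ref = refdb$id[best],
         identity = met$identity, ref_coverage = met$ref_coverage,
         lineage = lineage)
}

#' Classify a read set against a reference panel
#'
#' Applies the length filter, then [assign_read()] to every kept read.
#'
#' @param reads Sequence tibble.
#' @inheritParams assign_read
#' @return Tibble with one row per input read (`status` is one of
#'   `classified`, `unclassified`, `length_filtered`), in input order.
#' @export
classify_reads <- function(reads, refdb, taxonomy, params = classify_params(),
                           scoring = scoring_scheme()) {
  parts <- length_filter(reads, params)
  assigned <- if (nrow(parts$kept) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(parts$kept)), function(i) {
      assign_read(parts$kept[i, ], refdb, taxonomy, params, scoring)
    }))
  } else NULL
  filtered <- if (nrow(parts$removed) > 0) {
    tibble(read_id = parts$removed$id, status = "length_filtered",
           best_ref = NA_character_, identity = NA_real_,
           ref_coverage = NA_real_, lineage = "")
  } else NULL
  out <- dplyr::bind_rows(assigned, filtered)
  out[match(reads$id, out$read_id), , drop = FALSE]
}

#' Rank-level abundance table from assignments
#'
#' Classified reads whose lineage does not reach `rank` are counted as
#' `"unranked"`. Total counts are conserved:
#' classified + unclassified + length_filtered = input reads.
#'
#' @param assignments Tibble from [classify_reads()].
#' @param rank One of [tax_ranks()].
#' @return An `abundance_table`: list with `rank`, `counts` (tibble
#'   `taxon, count`), `total_reads`, `n_unclassified`, `n_filtered`.
#' @export
abundance_table <- function(assignments, rank = "genus") {
  rank <- match.arg(rank, tax_ranks())
  cls <- assignments[assignments$status == "classified", , drop = FALSE]
  taxon <- dplyr::coalesce(lineage_at_rank(cls$lineage, rank), "unranked")
  counts <- dplyr::count(tibble(taxon = taxon), .data$taxon, name = "count")
  structure(list(rank = rank, counts = counts,
                 total_reads = nrow(assignments),
                 n_unclassified = sum(assignments$status == "unclassified"),
                 n_filtered = sum(assignments$status == "length_filtered")),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> rank %s: %d reads (%d unclassified, %d length-filtered)\n",
              x$rank, x$total_reads, x$n_unclassified, x$n_filtered))
  print(x$counts)
  invisible(x)
}

#' @rdname abundance_table
#' @param x An `abundance_table`.
#' @param ... Unused.
#' @export
tidy.abundance_table <- function(x, ...) x$counts

#' Krona-ready lineage abundance from assignments
#'
#' Aggregates classified reads by lineage truncated at `rank`; unclassified
#' and length-filtered reads contribute an empty lineage so the Krona export
#' conserves the total read count.
#'
#' @inheritParams abundance_table
#' @return Tibble `lineage, count` suitable for [write_krona_tsv()].
#' @export
krona_abundance <- function(assignments, rank = "species") {
  rank <- match.arg(rank, tax_ranks())
  k <- match(rank, tax_ranks())
  trunc <- vapply(assignments$lineage, function(x) {
    p <- parse_lineage(x)
    lineage_string(p[seq_len(min(length(p), k))])
  }, character(1), USE.NAMES = FALSE)
  trunc[assignments$status != "classified"] <- ""
  dplyr::count(tibble(lineage = trunc), .data$lineage, name = "count")
}

#' Compare two classifiers' assignments by taxonomic rank
#'
#' For each rank, over the reads classified by BOTH classifiers down to that
#' rank, agreement is the fraction assigned the identical taxon name. The L1
#' distance between the two rank-level relative-abundance vectors (over the
#' union of taxa, each vector over that classifier's own rank-classified
#' common reads) summarizes compositional disagreement. With one consistent
#' taxonomy, agreement can only fall (never rise) as the rank gets finer.
#'
#' @param assign_a,assign_b Assignment tibbles from [classify_reads()],
#'   indexed by `read_id`.
#' @param ranks Ranks to compare (default all of [tax_ranks()]).
#' @return An `agreement_report` tibble: `rank, n_both_classified, n_agree,
#'   agreement, l1_distance`.
#' @export
compare_classifiers <- function(assign_a, assign_b, ranks = tax_ranks()) {
  ranks <- match.arg(ranks, tax_ranks(), several.ok = TRUE)
  common <- intersect(assign_a$read_id, assign_b$read_id)
  if (length(common) == 0) abort("no common reads between the two assignment sets")
  a <- assign_a[match(common, assign_a$read_id), ]
  b <- assign_b[match(common, assign_b$read_id), ]
  rows <- lapply(ranks, function(rk) {
    ta <- ifelse(a$status == "classified", lineage_at_rank(a$lineage, rk), NA)
    tb <- ifelse(b$status == "classified", lineage_at_rank(b$lineage, rk), NA)
    both <- !is.na(ta) & !is.na(tb)
    n_both <- sum(both)
    n_agree <- sum(ta[both] == tb[both])
    rel <- function(x) { t <- table(x[!is.na(x)]); t / sum(t) }
    pa <- rel(ta); pb <- rel(tb)
    taxa <- union(names(pa), names(pb))
    l1 <- if (length(taxa) == 0) 0 else {
      va <- setNames(rep(0, length(taxa)), taxa); va[names(pa)] <- pa
      vb <- setNames(rep(0, length(taxa)), taxa); vb[names(pb)] <- pb
      sum(abs(va - vb))
    }
    tibble(rank = rk, n_both_classified = n_both, n_agree = n_agree,
           agreement = if (n_both > 0) n_agree / n_both else NA_real_,
           l1_distance = l1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agreement_report", class(out))
  out
}
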