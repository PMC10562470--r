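# Predict amplification of a primer pair across a labeled sequence database
# and quantify per-taxon coverage and cross-superkingdom specificity.

#' Primer binding model parameters
#'
#' A primer core binds where its IUPAC sets intersect the template position by
#' position, with at most `max_mismatch` mismatches overall and none within
#' the 3'-terminal `anchor3_len` bases (polymerase extension requires a
#' matched 3' end). Tails are never matched.
#'
#' @param max_mismatch Maximum tolerated mismatches outside the anchor
#'   (default 2).
#' @param anchor3_len 3'-terminal bases requiring an exact (set-intersection)
#'   match (default 3).
#' @param max_amplicon Longest reported product in bases (default 3000).
#' @return A `bind_params` list.
#' @export
bind_params <- function(max_mismatch = 2, anchor3_len = 3, max_amplicon = 3000) {
  if (max_mismatch < 0 || anchor3_len < 0) abort("negative binding parameter")
  structure(list(max_mismatch = as.integer(max_mismatch),
                 anchor3_len = as.integer(anchor3_len),
                 max_amplicon = as.integer(max_amplicon)),
            class = "bind_params")
}

#' Find primer binding sites on both strands of a template
#'
#' A `+` site means the core sequence itself matches the template top strand
#' over `[start, end)` (the primer anneals to the bottom strand and extends
#' rightward); a `-` site means the reverse complement of the core matches
#' there (extension leftward). The 3' anchor is enforced on the correct end
#' for each strand.
#'
#' @param template One-row sequence tibble (or list with `id`, `seq`).
#' @param primer_core IUPAC core string (tail excluded).
#' @param params A [bind_params()].
#' @return Tibble `template_id, start, end, strand, mismatches`, 0-based
#'   half-open, sorted by `start`.
#' @export
find_binding_sites <- function(template, primer_core, params = bind_params()) {
  tseq <- validate_seq(template$seq[[1]])
  core <- validate_seq(primer_core)
  n <- nchar(tseq); k <- nchar(core)
  anchor <- min(params$anchor3_len, k)
  plus <- .scan_sites_cpp(tseq, core, params$max_mismatch, anchor)
  minus <- .scan_sites_cpp(reverse_complement(tseq), core, params$max_mismatch, anchor)
  out <- tibble(
    template_id = template$id[[1]],
    start = c(plus[, 1], if (nrow(minus)) n - minus[, 1] - k else integer(0)),
    end = c(plus[, 1] + k, if (nrow(minus)) n - minus[, 1] else integer(0)),
    strand = c(rep("+", nrow(plus)), rep("-", nrow(minus))),
    mismatches = c(plus[, 2], minus[, 2])
  )
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' Every pairing of a forward-primer `+` site with a downstream
#' reverse-primer `-` site yields a product (and the strand-mirrored
#' arrangement: a reverse-primer `+` site with a downstream forward-primer
#' `-` site), provided `0 < length <= max_amplicon`.
#'
#' @param template One-row sequence tibble.
#' @param pair A `primer_pair`.
#' @param params A [bind_params()].
#' @return Tibble `template_id, start, end, length, orientation, f_mismatches,
#'   r_mismatches`, sorted by `start`; `orientation` is `"+"` when the forward
#'   primer sits on the top strand.
#' @export
predict_amplicons <- function(template, pair, params = bind_params()) {
  fs <- find_binding_sites(template, pair$forward$core, params)
  rs <- find_binding_sites(template, pair$reverse$core, params)
  empty <- tibble(template_id = character(), start = integer(), end = integer(),
                  length = integer(), orientation = character(),
                  f_mismatches = integer(), r_mismatches = integer())
  combos <- function(left, right, orient) {
    if (nrow(left) == 0 || nrow(right) == 0) return(empty)
    g <- tidyr::expand_grid(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
    len <- right$end[g$ri] - left$start[g$li]
    keep <- len > 0 & len <= params$max_amplicon
    if (!any(keep)) return(empty)
    tibble(
      template_id = left$template_id[g$li[keep]],
      start = left$start[g$li[keep]], end = right$end[g$ri[keep]],
      length = len[keep], orientation = orient,
      f_mismatches = if (orient == "+") left$mismatches[g$li[keep]]
                     else right$mismatches[g$ri[keep]],
      r_mismatches = if (orient == "+") right$mismatches[g$ri[keep]]
                     else left$mismatches[g$li[keep]]
    )
  }
  out <- dplyr::bind_rows(
    combos(fs[fs$strand == "+", ], rs[rs$strand == "-", ], "+"),
    combos(rs[rs$strand == "+", ], fs[fs$strand == "-", ], "-")
  )
  dplyr::arrange(out, .data$start, .data$end)
}

#' Per-taxon amplification coverage of a primer pair
#'
#' Runs [predict_amplicons()] over a labeled database; a sequence counts as
#' amplified when it yields at least one product within the length bound.
#' Reports coverage per taxon at the requested rank plus a superkingdom
#' rollup, which is what exposes cross-superkingdom (non-)specificity of a
#' primer set.
#'
#' @param db Sequence tibble (`id`, `seq`).
#' @param taxonomy Tibble (`id`, `lineage`) as from [read_taxonomy_table()];
#'   sequences without a name at `rank` are grouped as `"unassigned"`.
#' @param pair A `primer_pair`.
#' @param params A [bind_params()].
#' @param rank One of [tax_ranks()] (default `"genus"`).
#' @return A `coverage_report`: list with `per_taxon` and `per_superkingdom`
#'   tibbles (`taxon, n_sequences, n_amplified, coverage`) and `rank`.
#' @export
panel_coverage <- function(db, taxonomy, pair, params = bind_params(),
                           rank = "genus") {
  if (nrow(db) == 0) abort("empty sequence database")
  rank <- match.arg(rank, tax_ranks())
  lin <- setNames(taxonomy$lineage, taxonomy$id)[db$id]
  lin[is.na(lin)] <- ""
  amplified <- vapply(seq_len(nrow(db)), function(i) {
    nrow(predict_amplicons(db[i, ], pair, params)) > 0
  }, logical(1))
  base <- tibble(
    taxon = dplyr::coalesce(lineage_at_rank(lin, rank), "unassigned"),
    superkingdom = dplyr::coalesce(lineage_at_rank(lin, "superkingdom"), "unassigned"),
    amplified = amplified
  )
  summarize_by <- function(key) {
    dplyr::summarise(dplyr::group_by(base, taxon = .data[[key]]),
                     n_sequences = dplyr::n(),
                     n_amplified = sum(.data$amplified),
                     coverage = mean(.data$amplified), .groups = "drop")
  }
  structure(list(per_taxon = summarize_by("taxon"),
                 per_superkingdom = summarize_by("superkingdom"),
                 rank = rank),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> rank: %s\n", x$rank))
  print(x$per_taxon)
  cat("superkingdom rollup:\n")
  print(x$per_superkingdom)
  invisible(x)
}

#' @rdname panel_coverage
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @export
tidy.coverage_report <- function(x, ...) x$per_taxon

#' @rdname panel_coverage
#' @export
glance.coverage_report <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$per_superkingdom, "taxon", "coverage"),
    names_from = "taxon", values_from = "coverage", names_prefix = "coverage_"
  )
}
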