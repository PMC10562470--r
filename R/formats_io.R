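# Readers/writers for the external formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; the BLAST-style
# tabular dialect is converted to/from 1-based inclusive at this boundary only.

#' Taxonomic rank ladder
#'
#' The fixed, coarse-to-fine rank list used throughout: superkingdom, phylum,
#' class, order, family, genus, species. Lineages are prefix-closed over this
#' ladder: if a rank is absent, all finer ranks must be absent too.
#' @export
tax_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Read a FASTA (or FASTQ) file into a sequence tibble
#'
#' Sequences are uppercased, whitespace-stripped and validated against the
#' IUPAC nucleotide alphabet. FASTQ input is accepted by `read_seqs()`;
#' quality lines are ignored (downstream filtering is length-only).
#'
#' @param path File path.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (remainder of the header, possibly `""`), `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some desc", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !any(hdr)) abort(sprintf("%s: no records", path))
  if (!hdr[1]) abort(sprintf("%s: file does not start with '>'", path))
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), function(x) {
    gsub("\\s", "", paste(x, collapse = ""))
  }, character(1))
  seqs <- seqs[as.character(seq_along(id))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(id))) abort(sprintf("%s: empty record id", path))
  if (any(!nzchar(seqs))) {
    abort(sprintf("%s: record '%s' has an empty sequence", path, id[!nzchar(seqs)][1]))
  }
  seqs <- unname(mapply(validate_seq, seqs, paste0("record '", id, "'")))
  tibble(id = id, desc = unname(desc), seq = seqs)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("%s: no records", path))
  if (length(lines) %% 4 != 0 || !all(grepl("^@", lines[seq(1, length(lines), by = 4)]))) {
    abort(sprintf("%s: not 4-line FASTQ", path))
  }
  headers <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- lines[seq(2, length(lines), by = 4)]
  seqs <- unname(mapply(validate_seq, seqs, paste0("record '", id, "'")))
  tibble(id = id, desc = unname(desc), seq = seqs)
}

#' @rdname read_fasta
#' @export
read_seqs <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, "@")) read_fastq(path) else read_fasta(path)
}

#' Write a sequence tibble as FASTA
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(x, path))`
#' reproduces `x` exactly on valid input.
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate record ids: %s", paste(dup, collapse = ", ")))
  }
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read BLAST-style tabular hits ("tabular with comment lines")
#'
#' Parses the 12-column tab-separated dialect (`outfmt 7`): query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, q. start,
#' q. end, s. start, s. end, evalue, bit score. Lines starting `#` are skipped.
#' Coordinates are returned verbatim (1-based inclusive; `s_start > s_end`
#' encodes a minus-strand hit). Use [normalize_hits()] for internal 0-based
#' half-open coordinates with an explicit strand column.
#'
#' @param path File path.
#' @return Tibble with the 12 standard columns.
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
  if (!any(keep)) {
    return(tibble(
      query_id = character(), subject_id = character(), pct_identity = double(),
      aln_len = integer(), mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(), s_start = integer(),
      s_end = integer(), evalue = double(), bitscore = double()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    lineno <- which(keep)[which(nf != 12)[1]]
    abort(sprintf("%s: line %d has %d fields, expected 12", path, lineno, nf[nf != 12][1]))
  }
  m <- do.call(rbind, fields)
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.double(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.double(m[, 11]), bitscore = as.double(m[, 12])
  )
}

#' Normalize tabular hits to internal coordinates
#'
#' Converts 1-based inclusive spans to 0-based half-open and folds the
#' BLAST minus-strand convention (`s_start > s_end`) into a `strand` column
#' with `s_lo < s_hi` always.
#'
#' @param hits Tibble from [read_tabular_hits()].
#' @return The input with extra columns `q_lo`, `q_hi`, `s_lo`, `s_hi`, `strand`.
#' @export
normalize_hits <- function(hits) {
  minus <- hits$s_start > hits$s_end
  dplyr::mutate(
    hits,
    q_lo = .data$q_start - 1L, q_hi = .data$q_end,
    s_lo = ifelse(minus, hits$s_end, hits$s_start) - 1L,
    s_hi = ifelse(minus, hits$s_start, hits$s_end),
    strand = ifelse(minus, "-", "+")
  )
}

parse_lineage <- function(x, what = "lineage") {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  # trailing empties (e.g. "A;B;") are padding; internal empties break closure
  while (length(parts) > 0 && !nzchar(parts[length(parts)])) {
    parts <- parts[-length(parts)]
  }
  if (length(parts) > length(tax_ranks())) {
    abort(sprintf("%s: %d ranks exceed the %d-rank ladder", what,
                  length(parts), length(tax_ranks())))
  }
  if (any(!nzchar(parts))) {
    abort(sprintf("%s: empty rank at position %d violates prefix closure ('%s')",
                  what, which(!nzchar(parts))[1], x))
  }
  setNames(parts, tax_ranks()[seq_along(parts)])
}

lineage_string <- function(parts) paste(parts, collapse = ";")

#' Extract one rank's name from semicolon-joined lineages
#'
#' @param lineage Character vector of semicolon-joined, prefix-closed lineages
#'   (coarse to fine, starting at superkingdom).
#' @param rank One of [tax_ranks()].
#' @return Character vector; `NA` where the lineage does not reach the rank.
#' @export
lineage_at_rank <- function(lineage, rank) {
  rank <- match.arg(rank, tax_ranks())
  k <- match(rank, tax_ranks())
  vapply(lineage, function(x) {
    p <- parse_lineage(x)
    if (length(p) >= k) p[[k]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a taxonomy table (TSV: id, semicolon-joined lineage)
#'
#' Lineages are validated for prefix closure over [tax_ranks()] (no gaps);
#' an id repeated with a conflicting lineage is an error. An empty lineage
#' field means fully unclassified (zero ranks).
#'
#' @param path File path.
#' @return Tibble with columns `id`, `lineage` (normalized semicolon string).
#' @export
read_taxonomy_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) return(tibble(id = character(), lineage = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(fields, `[`, character(1), 1)
  lin <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  norm <- vapply(seq_along(id), function(i) {
    lineage_string(parse_lineage(lin[i], what = sprintf("%s: id '%s'", path, id[i])))
  }, character(1))
  tb <- tibble(id = id, lineage = norm)
  conflict <- dplyr::summarise(dplyr::group_by(tb, .data$id),
                               n = dplyr::n_distinct(.data$lineage))
  bad <- conflict$id[conflict$n > 1]
  if (length(bad) > 0) {
    abort(sprintf("%s: id '%s' repeated with conflicting lineages", path, bad[1]))
  }
  dplyr::distinct(tb)
}

#' Write (and read back) Krona text-import TSV
#'
#' One line per lineage: the read count, then the rank names root-to-leaf,
#' tab-separated. A fully unclassified lineage writes a count with no names.
#' `read_krona_tsv()` is the exact inverse on valid data and total counts are
#' conserved.
#'
#' @param abundance Tibble with columns `lineage` (semicolon-joined) and
#'   `count` (non-negative).
#' @param path File path.
#' @return `path` invisibly; for the reader, a tibble like `abundance`.
#' @export
write_krona_tsv <- function(abundance, path) {
  stopifnot(all(c("lineage", "count") %in% names(abundance)))
  if (any(abundance$count < 0)) abort("negative count in abundance table")
  lines <- vapply(seq_len(nrow(abundance)), function(i) {
    parts <- parse_lineage(abundance$lineage[i])
    paste(c(abundance$count[i], parts), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_krona_tsv
#' @export
read_krona_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(lineage = character(), count = double()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    lineage = vapply(fields, function(f) lineage_string(f[-1]), character(1)),
    count = vapply(fields, function(f) as.double(f[1]), double(1))
  )
}
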