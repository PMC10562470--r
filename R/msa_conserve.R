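# Desk-scale multiple alignment of the 16S panel and per-column conservation
# profiling to find primer-suitable conserved windows.

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  if (length(unique(nchar(rows))) > 1) abort("MSA rows differ in length")
  structure(list(ids = ids, rows = rows, n_cols = nchar(rows[1])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' @export
as_tibble.msa <- function(x, ...) tibble(id = x$ids, row = x$rows)

#' Center-star multiple sequence alignment
#'
#' Deterministic progressive alignment: the center is the sequence maximizing
#' the summed global pairwise alignment score against all others (ties go to
#' the earliest input sequence); every other sequence is aligned globally to
#' the center and merged under "once a gap, always a gap". Adequate at panel
#' scale (up to ~100 x 1.6 kb) and fully reproducible; an externally produced
#' alignment can be substituted via [read_msa()].
#'
#' @param seqs Sequence tibble (`id`, `seq`) with at least 2 rows.
#' @param scoring A [scoring_scheme()].
#' @return An `msa` object (`ids`, `rows`, `n_cols`); removing gaps from row
#'   i recovers input sequence i exactly.
#' @export
center_star_msa <- function(seqs, scoring = scoring_scheme()) {
  k <- nrow(seqs)
  if (k < 2) abort("center-star MSA needs at least 2 sequences")
  ss <- vapply(seqs$seq, validate_seq, character(1), USE.NAMES = FALSE)

  total <- numeric(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sc <- .nwg_align_cpp(ss[i], ss[j], scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend)$score
      total[i] <- total[i] + sc
      total[j] <- total[j] + sc
    }
  }
  center <- which.max(total) # ties -> earliest input row

  master <- seq_chars(ss[center])          # gapped center, grows as gaps merge in
  aligned <- list()                        # gapped rows, by original index
  aligned[[center]] <- master
  for (i in setdiff(seq_len(k), center)) {
    aln <- .nwg_align_cpp(ss[center], ss[i], scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
    gc <- seq_chars(aln$gapped_a)
    gs <- seq_chars(aln$gapped_b)
    # merge gc's gap pattern into master ("once a gap, always a gap")
    n <- length(master); m <- length(gc)
    from_old <- logical(0); new_chars <- character(0)
    ii <- 1; jj <- 1
    while (ii <= n || jj <= m) {
      if (ii <= n && master[ii] == "-") {
        from_old <- c(from_old, TRUE); new_chars <- c(new_chars, "-"); ii <- ii + 1
      } else if (jj <= m && gc[jj] == "-") {
        from_old <- c(from_old, FALSE); new_chars <- c(new_chars, gs[jj]); jj <- jj + 1
      } else {
        from_old <- c(from_old, TRUE); new_chars <- c(new_chars, gs[jj])
        ii <- ii + 1; jj <- jj + 1
      }
    }
    ncols <- length(from_old)
    expand <- function(row) {
      out <- character(ncols)
      out[from_old] <- row
      out[!from_old] <- "-"
      out
    }
    for (idx in seq_along(aligned)) {
      if (!is.null(aligned[[idx]])) aligned[[idx]] <- expand(aligned[[idx]])
    }
    master <- expand(master)
    aligned[[i]] <- new_chars
  }
  rows <- vapply(aligned, paste, character(1), collapse = "")
  new_msa(seqs$id, rows)
}

#' Read an alignment from aligned-FASTA or Clustal format
#'
#' Gap characters `-` and `.` are accepted (`.` is normalized to `-`), so an
#' alignment produced by an external program can replace [center_star_msa()].
#'
#' @param path File path.
#' @param format `"fasta"` (default; `>`-headed records possibly wrapped) or
#'   `"clustal"` (block format with a `CLUSTAL` header line).
#' @return An `msa` object.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "fasta") {
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grepl("^>", lines)
    if (!any(hdr)) abort(sprintf("%s: no records", path))
    rec <- cumsum(hdr)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    rows <- vapply(split(lines[!hdr], rec[!hdr]),
                   function(x) gsub("\\s", "", paste(x, collapse = "")),
                   character(1))
    rows <- unname(rows[as.character(seq_along(ids))])
  } else {
    if (!grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
      abort(sprintf("%s: missing CLUSTAL header", path))
    }
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    body <- body[grepl("^\\S+\\s+\\S", body) & !grepl("^[\\s.:*]+$", body, perl = TRUE)]
    ids <- sub("\\s.*$", "", body)
    chunks <- sub("\\s+\\d*$", "", sub("^\\S+\\s+", "", body))
    ord <- unique(ids)
    rows <- vapply(ord, function(nm) paste(chunks[ids == nm], collapse = ""),
                   character(1), USE.NAMES = FALSE)
    ids <- ord
  }
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  new_msa(ids, rows)
}

#' Write an MSA as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(msa$ids)) {
    writeLines(paste0(">", msa$ids[i]), con)
    s <- msa$rows[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Per-column conservation profiles of an alignment
#'
#' Counts A/C/G/T, gaps, and ambiguity symbols per column. Conservation is the
#' modal concrete-base count divided by the number of non-gap rows (ambiguity
#' symbols stay in the denominator but never in the numerator); gap pressure
#' is tracked separately as `gap_fraction` so indel-rich columns can be
#' excluded explicitly when choosing primer windows.
#'
#' @param msa An `msa` object.
#' @return Tibble with one row per column: `col` (0-based), `n_A`, `n_C`,
#'   `n_G`, `n_T`, `ambig_count`, `gap_count`, `conservation`, `gap_fraction`.
#' @export
column_profiles <- function(msa) {
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  n_rows <- nrow(mat)
  count_of <- function(b) colSums(mat == b)
  nA <- count_of("A"); nC <- count_of("C"); nG <- count_of("G"); nT <- count_of("T")
  gaps <- count_of("-")
  ambig <- n_rows - nA - nC - nG - nT - gaps
  nongap <- n_rows - gaps
  cons <- ifelse(nongap > 0, pmax(nA, nC, nG, nT) / nongap, 0)
  tibble(
    col = seq_len(msa$n_cols) - 1L,
    n_A = as.integer(nA), n_C = as.integer(nC),
    n_G = as.integer(nG), n_T = as.integer(nT),
    ambig_count = as.integer(ambig), gap_count = as.integer(gaps),
    conservation = cons, gap_fraction = gaps / n_rows
  )
}

#' Find conserved windows suitable for primers
#'
#' A window of alignment columns qualifies when it is at least `win_len`
#' columns long, every column's gap fraction is at most `max_gap_frac`, and
#' its mean conservation is at least `min_mean_cons`. The union of all
#' qualifying windows is reported as maximal non-overlapping runs, sorted by
#' start; every reported run therefore contains at least one qualifying
#' window of full length.
#'
#' @param profiles Tibble from [column_profiles()].
#' @param win_len Minimum window length in columns (default 18, a typical
#'   primer core length).
#' @param min_mean_cons Minimum mean conservation over the window (default 0.90).
#' @param max_gap_frac Maximum per-column gap fraction (default 0.10).
#' @return Tibble `start, end` (0-based half-open column spans),
#'   `mean_conservation`, `max_gap_fraction`; zero rows when nothing qualifies.
#' @export
find_conserved_windows <- function(profiles, win_len = 18,
                                   min_mean_cons = 0.90, max_gap_frac = 0.10) {
  L <- nrow(profiles)
  empty <- tibble(start = integer(), end = integer(),
                  mean_conservation = double(), max_gap_fraction = double())
  if (L < win_len) return(empty)
  ok <- profiles$gap_fraction <= max_gap_frac
  csum <- c(0, cumsum(profiles$conservation))
  in_union <- logical(L)
  # enumerate qualifying windows inside each gap-admissible run via prefix sums
  runs <- rle(ok)
  pos <- cumsum(c(1, runs$lengths))
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    lo <- pos[r]; hi <- pos[r + 1] - 1
    if (hi - lo + 1 < win_len) next
    for (i in lo:(hi - win_len + 1)) {
      js <- (i + win_len - 1):hi
      means <- (csum[js + 1] - csum[i]) / (js - i + 1)
      # small epsilon so windows sitting exactly on the threshold are kept
      # regardless of floating-point summation order
      q <- js[means >= min_mean_cons - 1e-9]
      # the union over all qualifying windows starting at i is [i, max(q)]
      if (length(q) > 0) in_union[i:max(q)] <- TRUE
    }
  }
  if (!any(in_union)) return(empty)
  rr <- rle(in_union)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1
  keep <- which(rr$values)
  dplyr::bind_rows(lapply(keep, function(r) {
    i <- starts[r]; j <- ends[r]
    tibble(start = i - 1L, end = j,
           mean_conservation = (csum[j + 1] - csum[i]) / (j - i + 1),
           max_gap_fraction = max(profiles$gap_fraction[i:j]))
  }))
}
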