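# Turn conserved alignment windows into tailed, degenerate, Tm-matched primer
# pairs. Melting temperatures are computed on the gene-specific core only; the
# constant 5' tails are universal tags absent from the template in the first
# PCR cycles.

# SantaLucia (1998) unified nearest-neighbor duplex parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are the 5'->3' top-strand dimers.
NN_UNIFIED <- list(
  AA = c(dH = -7.9, dS = -22.2), TT = c(dH = -7.9, dS = -22.2),
  AT = c(dH = -7.2, dS = -20.4), TA = c(dH = -7.2, dS = -21.3),
  CA = c(dH = -8.5, dS = -22.7), TG = c(dH = -8.5, dS = -22.7),
  GT = c(dH = -8.4, dS = -22.4), AC = c(dH = -8.4, dS = -22.4),
  CT = c(dH = -7.8, dS = -21.0), AG = c(dH = -7.8, dS = -21.0),
  GA = c(dH = -8.2, dS = -22.2), TC = c(dH = -8.2, dS = -22.2),
  CG = c(dH = -10.6, dS = -27.2), GC = c(dH = -9.8, dS = -24.4),
  GG = c(dH = -8.0, dS = -19.9), CC = c(dH = -8.0, dS = -19.9)
)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)  # duplex end pairing G or C
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)   # duplex end pairing A or T

#' Melting-temperature model parameters
#'
#' @param method `"nearest_neighbor"` (unified duplex parameters with a
#'   Schildkraut-Lifson salt correction `16.6 * log10([Na+])`) or `"wallace"`
#'   (the rule of thumb `2(A+T) + 4(G+C)`).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param primer_uM Oligo concentration in uM (default 0.25).
#' @return A `tm_params` list.
#' @export
tm_params <- function(method = c("nearest_neighbor", "wallace"),
                      na_mM = 50, primer_uM = 0.25) {
  method <- match.arg(method)
  if (na_mM <= 0 || primer_uM <= 0) abort("concentrations must be positive")
  structure(list(method = method, na_mM = na_mM, primer_uM = primer_uM),
            class = "tm_params")
}

tm_one <- function(seq, params) {
  chars <- seq_chars(seq)
  if (params$method == "wallace") {
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  }
  n <- length(chars)
  dimers <- paste0(chars[-n], chars[-1])
  dH <- sum(vapply(NN_UNIFIED[dimers], `[[`, double(1), "dH"))
  dS <- sum(vapply(NN_UNIFIED[dimers], `[[`, double(1), "dS"))
  ends <- chars[c(1, n)]
  for (e in ends) {
    init <- if (e %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  R <- 1.987               # cal / (mol K)
  ct <- params$primer_uM * 1e-6
  tm_K <- dH * 1000 / (dS + R * log(ct / 4))
  tm_K - 273.15 + 16.6 * log10(params$na_mM / 1000)
}

#' Melting temperature of a (possibly degenerate) primer core
#'
#' Degenerate cores are expanded to all concrete variants (at most `cap`) and
#' the Tm statistics are taken over the set; the mean is the headline value.
#' The nearest-neighbor method uses
#' `Tm = dH / (dS + R ln(Ct/4)) - 273.15 + 16.6 log10([Na+])`
#' over the unified duplex parameter table.
#'
#' @param core IUPAC string, length >= 6; the gene-specific part only
#'   (tails excluded).
#' @param params A [tm_params()].
#' @param cap Maximum degeneracy to expand (default 64).
#' @return A `tm_stats` list: `mean_C`, `min_C`, `max_C`, `n_variants`.
#' @examples
#' melt_tm("AAAATTTT", tm_params("wallace")) # 16 C exactly
#' @export
melt_tm <- function(core, params = tm_params(), cap = 64) {
  core <- validate_seq(core)
  if (nchar(core) < 6) abort("primer core shorter than 6 bases")
  variants <- expand_iupac(core, cap = cap)
  tms <- vapply(variants, tm_one, double(1), params = params)
  structure(list(mean_C = mean(tms), min_C = min(tms), max_C = max(tms),
                 n_variants = length(variants)),
            class = "tm_stats")
}

#' Trim a primer core from its 5' end to match a target Tm
#'
#' Bases are removed only from the 5' end -- the 3' end stays anchored on its
#' conserved, specificity-determining columns. Among all admissible suffixes
#' (length between `min_len` and the full core) the one whose mean Tm is
#' closest to `target_C` wins; ties go to the longer primer. This mirrors
#' matching a custom primer's annealing temperature to the partner primer set
#' by shortening.
#'
#' @param core IUPAC string, length > 6.
#' @param target_C Target Tm in degrees Celsius (typically the partner
#'   primer's Tm).
#' @param tol_C Acceptable |Tm - target| in degrees (default 2.5).
#' @param params A [tm_params()].
#' @param min_len Shortest admissible primer (default 15).
#' @param cap Degeneracy cap for Tm expansion.
#' @return The trimmed core (character scalar).
#' @export
trim_to_tm <- function(core, target_C, tol_C = 2.5, params = tm_params(),
                       min_len = 15, cap = 64) {
  core <- validate_seq(core)
  n <- nchar(core)
  if (n <= 6) abort("primer core must be longer than 6 bases")
  lens <- seq(min(n, max(min_len, 7)), n)
  suffixes <- substring(core, n - lens + 1, n)
  diffs <- vapply(suffixes, function(s) {
    abs(melt_tm(s, params, cap)$mean_C - target_C)
  }, double(1))
  best <- which(diffs == min(diffs))
  best <- best[length(best)] # ties -> longest suffix
  if (diffs[best] > tol_C) {
    abort(sprintf(
      "no 5'-trimmed suffix within %.2f C of target %.2f C; best achievable |dTm| = %.2f C at length %d",
      tol_C, target_C, diffs[best], lens[best]))
  }
  unname(suffixes[best])
}

#' Degenerate IUPAC consensus of an alignment window
#'
#' Per column, the IUPAC code of the set of bases whose frequency among
#' non-gap rows is at least `f_min`; minor alleles below the threshold are
#' suppressed. Ambiguity symbols in rows contribute fractionally to each base
#' of their set. Never emits a gap: a column whose gap fraction exceeds
#' `max_gap_frac` is an error (primers must avoid indel-rich columns).
#'
#' @param msa An `msa` object.
#' @param window Length-2 integer vector, 0-based half-open column span.
#' @param f_min Minimum base frequency to enter the code (default 0.10).
#' @param max_gap_frac Maximum tolerated per-column gap fraction (default 0.10).
#' @return IUPAC string of length `window[2] - window[1]`.
#' @export
degenerate_consensus <- function(msa, window, f_min = 0.10, max_gap_frac = 0.10) {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= msa$n_cols,
            window[1] < window[2])
  if (f_min <= 0 || f_min > 0.5) abort("f_min must be in (0, 0.5]")
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  out <- character(window[2] - window[1])
  for (k in seq_along(out)) {
    col <- window[1] + k # 1-based matrix column index of 0-based column window[1]+k-1
    chars <- mat[, col]
    gap_frac <- mean(chars == "-")
    if (gap_frac > max_gap_frac) {
      abort(sprintf("column %d has gap fraction %.2f > %.2f",
                    col - 1, gap_frac, max_gap_frac))
    }
    chars <- chars[chars != "-"]
    freq <- c(A = 0, C = 0, G = 0, T = 0)
    for (ch in chars) {
      set <- IUPAC_SETS[[ch]]
      freq[set] <- freq[set] + 1 / length(set)
    }
    freq <- freq / length(chars)
    keep <- names(freq)[freq >= f_min]
    if (length(keep) == 0) keep <- names(freq)[which.max(freq)]
    out[k] <- IUPAC_FROM_SET[[paste(sort(keep), collapse = "")]]
  }
  paste(out, collapse = "")
}

#' The published tailed 16S primer set
#'
#' The universal bacterial pair (Tailed-27For / Tailed-1492Rev) and the
#' custom archaea-targeted primers (For27, Rev621, Rev1413; the Rev1413 core
#' carries one degenerate K). Each oligo is a constant 22-base 5' tag followed
#' by the gene-specific core.
#'
#' @return Tibble: `name`, `set`, `orientation`, `tail`, `core`, `full_oligo`.
#' @export
published_primers <- function() {
  tag1 <- "TTTCTGTTGGTGCTGATATTGC"
  tag2 <- "ACTTGCCTGTCGCTCTATCTTC"
  tb <- tibble(
    name = c("Tailed-27For", "Tailed-1492Rev", "For27", "Rev621", "Rev1413"),
    set = c("universal", "universal", "archaeal", "archaeal", "archaeal"),
    orientation = c("forward", "reverse", "forward", "reverse", "reverse"),
    tail = c(tag1, tag2, tag2, tag1, tag1),
    core = c("AGAGTTTGATCMTGGCTCAG", "CGGTTACCTTGTTACGACTT",
             "TACGGCTACCTTGTTACGAC", "CTGAAACTTAAAGGAATTGGC",
             "ACKGCTCAGTAACACGTG")
  )
  dplyr::mutate(tb, full_oligo = paste0(.data$tail, .data$core))
}

new_primer_candidate <- function(name, orientation, core, tail, window, tm, deg) {
  structure(list(name = name, orientation = orientation, core = core,
                 tail = tail, full_oligo = paste0(tail, core),
                 window = window, tm = tm, degeneracy = deg),
            class = "primer_candidate")
}

#' @export
print.primer_candidate <- function(x, ...) {
  cat(sprintf("<primer %s (%s)> 5'-%s|%s-3'  cols [%d,%d)  deg %d  Tm %.1f C [%.1f, %.1f]\n",
              x$name, x$orientation, x$tail, x$core, x$window[1], x$window[2],
              x$degeneracy, x$tm$mean_C, x$tm$min_C, x$tm$max_C))
  invisible(x)
}

#' Assemble a Tm-matched, tailed primer pair from two conserved windows
#'
#' The forward core is the degenerate consensus of the forward window; the
#' reverse core is the reverse complement of the consensus of the reverse
#' window. Both are 5'-trimmed toward `target_tm` and prefixed with their
#' constant tails. The expected amplicon length (reverse span end minus
#' forward span start, on alignment columns, tails excluded) must fall inside
#' `amplicon_range`.
#'
#' @param msa An `msa` object.
#' @param fwd_window,rev_window 0-based half-open column spans;
#'   `fwd_window[2] < rev_window[1]`.
#' @param tails Character vector `c(forward = ..., reverse = ...)` of constant
#'   5' tags (default: the two published tags).
#' @param target_tm Target core Tm in Celsius (the partner set's Tm).
#' @param tol_C Tm tolerance for trimming.
#' @param amplicon_range Admissible amplicon length range (default
#'   `c(1250, 1750)`, the read-length filter window).
#' @param params A [tm_params()].
#' @param f_min,max_gap_frac,cap,min_len Passed through to consensus/trimming.
#' @return A `primer_pair` object (`forward`, `reverse`, `expected_len_range`).
#' @export
assemble_pair <- function(msa, fwd_window, rev_window,
                          tails = c(forward = "ACTTGCCTGTCGCTCTATCTTC",
                                    reverse = "TTTCTGTTGGTGCTGATATTGC"),
                          target_tm = 55, tol_C = 2.5,
                          amplicon_range = c(1250, 1750),
                          params = tm_params(), f_min = 0.10,
                          max_gap_frac = 0.10, cap = 64, min_len = 15) {
  if (fwd_window[2] >= rev_window[1]) {
    abort("forward window must precede the reverse window")
  }
  fwd_cons <- degenerate_consensus(msa, fwd_window, f_min, max_gap_frac)
  rev_cons <- degenerate_consensus(msa, rev_window, f_min, max_gap_frac)
  for (cons in c(fwd_cons, rev_cons)) {
    d <- degeneracy(cons)
    if (d > cap) abort(sprintf("window consensus degeneracy %d exceeds cap %d", d, cap))
  }
  fwd_core <- trim_to_tm(fwd_cons, target_tm, tol_C, params, min_len, cap)
  rev_core <- trim_to_tm(reverse_complement(rev_cons), target_tm, tol_C,
                         params, min_len, cap)
  # trimmed spans on alignment columns: forward keeps its 3' (right) edge,
  # reverse keeps its 3' edge, which is the left edge of rev_window
  fwd_span <- c(fwd_window[2] - nchar(fwd_core), fwd_window[2])
  rev_span <- c(rev_window[1], rev_window[1] + nchar(rev_core))
  expected_len <- rev_span[2] - fwd_span[1]
  if (expected_len < amplicon_range[1] || expected_len > amplicon_range[2]) {
    abort(sprintf("expected amplicon length %d outside [%d, %d]",
                  expected_len, amplicon_range[1], amplicon_range[2]))
  }
  fwd <- new_primer_candidate("fwd", "forward", fwd_core, unname(tails[["forward"]]),
                              fwd_span, melt_tm(fwd_core, params, cap),
                              degeneracy(fwd_core))
  rev <- new_primer_candidate("rev", "reverse", rev_core, unname(tails[["reverse"]]),
                              rev_span, melt_tm(rev_core, params, cap),
                              degeneracy(rev_core))
  structure(list(forward = fwd, reverse = rev,
                 expected_len_range = c(expected_len, expected_len)),
            class = "primer_pair")
}

#' Construct a primer pair directly from core sequences
#'
#' Convenience constructor used when the cores are already known (e.g. the
#' published set, or in-silico PCR of externally designed primers).
#'
#' @param fwd_core,rev_core IUPAC core strings (reverse core given 5'->3' as
#'   synthesized, i.e. reverse-complement of the template top strand).
#' @param tails Constant 5' tags, `c(forward = , reverse = )`.
#' @param names Primer names.
#' @param params A [tm_params()].
#' @param cap Degeneracy cap.
#' @return A `primer_pair`.
#' @export
primer_pair <- function(fwd_core, rev_core,
                        tails = c(forward = "", reverse = ""),
                        names = c("fwd", "rev"),
                        params = tm_params(), cap = 64) {
  fwd <- new_primer_candidate(names[1], "forward", validate_seq(fwd_core),
                              unname(tails[["forward"]]), c(NA_integer_, NA_integer_),
                              melt_tm(fwd_core, params, cap), degeneracy(fwd_core))
  rev <- new_primer_candidate(names[2], "reverse", validate_seq(rev_core),
                              unname(tails[["reverse"]]), c(NA_integer_, NA_integer_),
                              melt_tm(rev_core, params, cap), degeneracy(rev_core))
  structure(list(forward = fwd, reverse = rev,
                 expected_len_range = c(NA_integer_, NA_integer_)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  print(x$forward); print(x$reverse)
  cat(sprintf("expected amplicon length: %s\n",
              paste(x$expected_len_range, collapse = "-")))
  invisible(x)
}

#' @rdname assemble_pair
#' @param x A `primer_pair`.
#' @param ... Unused.
#' @export
tidy.primer_pair <- function(x, ...) {
  one <- function(p) tibble(
    name = p$name, orientation = p$orientation, tail = p$tail, core = p$core,
    full_oligo = p$full_oligo, degeneracy = p$degeneracy,
    tm_mean = p$tm$mean_C, tm_min = p$tm$min_C, tm_max = p$tm$max_C,
    ref_start = p$window[1], ref_end = p$window[2]
  )
  dplyr::bind_rows(one(x$forward), one(x$reverse))
}

#' @rdname assemble_pair
#' @export
glance.primer_pair <- function(x, ...) {
  tibble(
    expected_len_min = x$expected_len_range[1],
    expected_len_max = x$expected_len_range[2],
    tm_gap = abs(x$forward$tm$mean_C - x$reverse$tm$mean_C),
    total_degeneracy = x$forward$degeneracy * x$reverse$degeneracy
  )
}

#' Write / read a primer pair as TSV
#' @param pair A `primer_pair`.
#' @param path File path.
#' @return `path` invisibly; the reader returns a `primer_pair`.
#' @export
write_primers_tsv <- function(pair, path) {
  utils::write.table(tidy(pair), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_primers_tsv
#' @export
read_primers_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tb) == 2, all(c("forward", "reverse") %in% tb$orientation))
  f <- tb[tb$orientation == "forward", ][1, ]
  r <- tb[tb$orientation == "reverse", ][1, ]
  mk <- function(row) new_primer_candidate(
    row$name, row$orientation, row$core,
    ifelse(is.na(row$tail), "", row$tail),
    c(row$ref_start, row$ref_end),
    structure(list(mean_C = row$tm_mean, min_C = row$tm_min, max_C = row$tm_max,
                   n_variants = degeneracy(row$core)), class = "tm_stats"),
    degeneracy(row$core))
  structure(list(forward = mk(f), reverse = mk(r),
                 expected_len_range = c(r$ref_end - f$ref_start,
                                        r$ref_end - f$ref_start)),
            class = "primer_pair")
}
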