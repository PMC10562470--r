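# Independent, deliberately naive oracle implementations. These share no code
# with the package internals: full-matrix dynamic programming, direct looping,
# and a separately typed thermodynamic table.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# --- naive affine-gap local alignment score (full-matrix Gotoh) -------------
naive_local_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  oc <- gap_open + gap_extend
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - oc, E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - oc, F[i, j + 1] - gap_extend)
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H)
}

# --- hand-summed nearest-neighbor Tm ----------------------------------------
# Unified duplex parameters, typed independently from the package table.
oracle_nn_tm <- function(seq, na_mM = 50, primer_uM = 0.25) {
  dH_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
              GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
              CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  ch <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (k in 1:(length(ch) - 1)) {
    key <- paste0(ch[k], ch[k + 1])
    dH <- dH + dH_tab[[key]]
    dS <- dS + dS_tab[[key]]
  }
  for (e in ch[c(1, length(ch))]) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  ct <- primer_uM * 1e-6
  dH * 1000 / (dS + 1.987 * log(ct / 4)) - 273.15 + 16.6 * log10(na_mM / 1000)
}

# --- brute-force conserved-window enumeration -------------------------------
oracle_windows <- function(profiles, win_len, min_mean_cons, max_gap_frac) {
  L <- nrow(profiles)
  member <- rep(FALSE, L)
  if (L >= win_len) {
    for (i in 1:(L - win_len + 1)) {
      for (j in (i + win_len - 1):L) {
        cols <- i:j
        if (all(profiles$gap_fraction[cols] <= max_gap_frac) &&
            mean(profiles$conservation[cols]) >= min_mean_cons - 1e-9) {
          member[cols] <- TRUE
        }
      }
    }
  }
  r <- rle(member)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- data.frame(start = integer(), end = integer())
  for (k in seq_along(r$values)) {
    if (r$values[k]) out <- rbind(out, data.frame(start = starts[k] - 1L,
                                                  end = ends[k]))
  }
  out
}

# --- brute-force degenerate-aware site scan ---------------------------------
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

oracle_scan <- function(tmpl, core, max_mismatch, anchor3_len) {
  tc <- strsplit(tmpl, "")[[1]]; cc <- strsplit(core, "")[[1]]
  n <- length(tc); k <- length(cc)
  hits <- data.frame(start = integer(), mismatches = integer())
  if (n < k) return(hits)
  for (s in 0:(n - k)) {
    mm <- 0; ok <- TRUE
    for (p in 1:k) {
      inter <- length(intersect(oracle_iupac_sets[[tc[s + p]]],
                                oracle_iupac_sets[[cc[p]]])) > 0
      if (!inter) {
        if (p > k - anchor3_len) { ok <- FALSE; break }
        mm <- mm + 1
        if (mm > max_mismatch) { ok <- FALSE; break }
      }
    }
    if (ok) hits <- rbind(hits, data.frame(start = s, mismatches = mm))
  }
  hits
}

# small published-primer fixtures reused across tests
universal_pair_fixture <- function() {
  pp <- published_primers()
  primer_pair(pp$core[pp$name == "Tailed-27For"], pp$core[pp$name == "Tailed-1492Rev"],
              tails = c(forward = pp$tail[1], reverse = pp$tail[2]),
              names = c("Tailed-27For", "Tailed-1492Rev"))
}

archaeal_pair_fixture <- function() {
  pp <- published_primers()
  primer_pair(pp$core[pp$name == "For27"], pp$core[pp$name == "Rev1413"],
              tails = c(forward = pp$tail[pp$name == "For27"],
                        reverse = pp$tail[pp$name == "Rev1413"]),
              names = c("For27", "Rev1413"))
}
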