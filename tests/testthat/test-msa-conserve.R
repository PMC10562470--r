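test_that("center-star MSA of identical sequences has no gaps, full conservation", {
  set.seed(60)
  s <- rand_dna(200)
  seqs <- tibble::tibble(id = paste0("s", 1:5), seq = rep(s, 5))
  msa <- center_star_msa(seqs)
  expect_equal(msa$n_cols, 200)
  expect_true(all(msa$rows == s))
  prof <- column_profiles(msa)
  expect_true(all(prof$conservation == 1))
  expect_true(all(prof$gap_count == 0))
  expect_error(center_star_msa(seqs[1, ]), "at least 2")
})

test_that("substitution-only sets align gap-free with exact per-site counts", {
  set.seed(61)
  base <- strsplit(rand_dna(300), "")[[1]]
  seqs <- vapply(1:8, function(i) {
    x <- base
    idx <- which(runif(300) < 0.05)
    for (p in idx) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    paste(x, collapse = "")
  }, character(1))
  tb <- tibble::tibble(id = paste0("t", 1:8), seq = seqs)
  msa <- center_star_msa(tb)
  expect_equal(msa$n_cols, 300)
  expect_true(all(!grepl("-", msa$rows, fixed = TRUE)))
  # column base counts equal direct per-site frequencies of the unaligned set
  prof <- column_profiles(msa)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (b in c("A", "C", "G", "T")) {
    expect_equal(prof[[paste0("n_", b)]], unname(colSums(mat == b)))
  }
})

test_that("gap-free reconstruction: stripping gaps returns the inputs", {
  set.seed(62)
  # sequences with real indels
  base <- rand_dna(150)
  seqs <- vapply(1:6, function(i) {
    x <- strsplit(base, "")[[1]]
    cut <- sample(20:130, 1)
    x <- x[-(cut:(cut + sample(1:6, 1)))]
    paste(c(x, strsplit(rand_dna(sample(0:8, 1)), "")[[1]]), collapse = "")
  }, character(1))
  tb <- tibble::tibble(id = paste0("s", 1:6), seq = seqs)
  msa <- center_star_msa(tb)
  expect_equal(gsub("-", "", msa$rows, fixed = TRUE), seqs)
  # row-order invariance of conservation values (as a multiset per column)
  msa_rev <- center_star_msa(tb[6:1, ])
  expect_equal(gsub("-", "", msa_rev$rows, fixed = TRUE), rev(seqs))
})

test_that("two-sequence center-star equals the pairwise global merge", {
  set.seed(63)
  a <- rand_dna(80); b <- rand_dna(90)
  msa <- center_star_msa(tibble::tibble(id = c("a", "b"), seq = c(a, b)))
  nw <- taxprimer:::.nwg_align_cpp(a, b, 2L, -3L, 5L, 2L)
  expect_equal(msa$rows, c(nw$gapped_a, nw$gapped_b))
})

test_that("column profiles count bases, gaps and conserve row totals", {
  msa <- taxprimer:::new_msa(c("a", "b", "c", "d"),
                             c("AAG-", "AAC-", "A-GT", "ACGT"))
  prof <- column_profiles(msa)
  expect_equal(prof$conservation[1], 1.0)       # A,A,A,A
  expect_equal(prof$gap_fraction[2], 0.25)      # A,A,-,C
  expect_equal(prof$conservation[2], 2 / 3)
  expect_equal(prof$conservation[3], 0.75)      # G,C,G,G
  totals <- prof$n_A + prof$n_C + prof$n_G + prof$n_T +
    prof$gap_count + prof$ambig_count
  expect_true(all(totals == 4))
})

test_that("window finder equals brute-force enumeration on random profiles", {
  set.seed(64)
  for (rep in 1:20) {
    L <- sample(40:120, 1)
    prof <- tibble::tibble(
      col = seq_len(L) - 1L,
      conservation = sample(c(1, 1, 1, 0.9, 0.8, 0.5), L, replace = TRUE),
      gap_fraction = sample(c(0, 0, 0, 0.05, 0.2), L, replace = TRUE)
    )
    got <- find_conserved_windows(prof, win_len = 10, min_mean_cons = 0.9,
                                  max_gap_frac = 0.10)
    want <- oracle_windows(prof, 10, 0.9, 0.10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("a planted fully conserved block is recovered exactly", {
  L <- 120
  cons <- rep(0.25, L)
  cons[41:65] <- 1.0 # 25 columns, 0-based [40, 65)
  prof <- tibble::tibble(col = seq_len(L) - 1L, conservation = cons,
                         gap_fraction = 0)
  w <- find_conserved_windows(prof, win_len = 18, min_mean_cons = 0.98,
                              max_gap_frac = 0.1)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$end), c(40L, 65L))
  expect_equal(w$mean_conservation, 1.0)
  # all-variable profile yields nothing
  prof$conservation <- 0.5
  expect_equal(nrow(find_conserved_windows(prof)), 0)
})

test_that("aligned FASTA and Clustal readers reproduce an alignment", {
  msa <- taxprimer:::new_msa(c("x", "y"), c("AC-GT", "ACCGT"))
  tf <- withr::local_tempfile(fileext = ".afa")
  write_msa(msa, tf)
  back <- read_msa(tf)
  expect_equal(back$ids, msa$ids)
  expect_equal(back$rows, msa$rows)

  tc <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.0) multiple sequence alignment", "",
               "x   AC-GT", "y   ACCGT", "    ** **"), tc)
  cl <- read_msa(tc, format = "clustal")
  expect_equal(cl$ids, c("x", "y"))
  expect_equal(cl$rows, c("AC-GT", "ACCGT"))
})
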