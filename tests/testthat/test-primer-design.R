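test_that("degeneracy and expansion obey the product law", {
  expect_equal(degeneracy("ACGT"), 1)
  expect_equal(expand_iupac("ACGT"), "ACGT")
  expect_equal(degeneracy("NN"), 16)
  expect_length(expand_iupac("NN"), 16)

  # the published archaeal reverse core: one K -> exactly two variants
  core <- "ACKGCTCAGTAACACGTG"
  expect_equal(degeneracy(core), 2)
  vars <- expand_iupac(core)
  expect_equal(vars, c("ACGGCTCAGTAACACGTG", "ACTGCTCAGTAACACGTG"))
  diffs <- which(strsplit(vars[1], "")[[1]] != strsplit(vars[2], "")[[1]])
  expect_equal(diffs, 3) # only the K position differs

  set.seed(70)
  for (k in 1:40) {
    s <- paste(sample(names(taxprimer:::IUPAC_SETS), 12, replace = TRUE,
                      prob = c(rep(10, 4), rep(1, 11))), collapse = "")
    d <- degeneracy(s)
    if (d <= 64) {
      ex <- expand_iupac(s)
      expect_length(ex, d)
      expect_false(any(duplicated(ex)))
      expect_equal(ex, sort(ex)) # lexicographic
    } else {
      expect_error(expand_iupac(s), "exceeds cap")
    }
  }
})

test_that("Wallace and nearest-neighbor Tm match hand computation", {
  expect_equal(melt_tm("AAAATTTT", tm_params("wallace"))$mean_C, 16.0)
  oligos <- c("AGCGTAAGCTTCGCAT", "ACGTACGTACGTACGT", "GGGGCCCCAATT",
              "ATATATATATATATAT", "CGCGCGCGCGCG", "AAGGTTCCAAGGTTCC",
              "TTGACCTTGACC", "CAGTCAGTCAGTCAGT", "GCATGCATGCAT",
              "AAAAAACCCCCC")
  for (o in oligos) {
    expect_equal(melt_tm(o)$mean_C, oracle_nn_tm(o), tolerance = 0.01)
  }
  # degenerate core: stats over expanded variants
  st <- melt_tm("ACKGCT")
  both <- vapply(expand_iupac("ACKGCT"), oracle_nn_tm, numeric(1))
  expect_equal(st$n_variants, 2)
  expect_equal(st$mean_C, mean(both), tolerance = 1e-9)
  expect_equal(st$min_C, min(both), tolerance = 1e-9)
  expect_equal(st$max_C, max(both), tolerance = 1e-9)
  expect_error(melt_tm("ACGTA"), "shorter than 6")
})

test_that("5'-trimming finds the suffix closest to the target Tm", {
  set.seed(71)
  core <- rand_dna(30)
  target <- melt_tm(substring(core, 11, 30))$mean_C
  got <- trim_to_tm(core, target, tol_C = 3)
  # exhaustive check over all admissible suffixes
  lens <- 15:30
  suff <- substring(core, 30 - lens + 1, 30)
  diffs <- vapply(suff, function(s) abs(melt_tm(s)$mean_C - target), numeric(1))
  expect_equal(abs(melt_tm(got)$mean_C - target), min(diffs))
  # ties toward the longer primer, and suffix property
  expect_true(endsWith(core, got))

  # already within tolerance -> unchanged
  c2 <- rand_dna(18)
  expect_equal(trim_to_tm(c2, melt_tm(c2)$mean_C, tol_C = 1), c2)

  # GC-rich core with a target far below its Tm is strictly shortened
  gc30 <- "GCGGCCGCATGCGGCCGCATGCGGCCGCAT"
  target_low <- melt_tm(substring(gc30, 16, 30))$mean_C
  expect_lt(nchar(trim_to_tm(gc30, target_low, tol_C = 3)), 30)

  # unreachable target errors with the best achievable gap
  expect_error(trim_to_tm(rand_dna(20), 95, tol_C = 1), "best achievable")
})

test_that("degenerate consensus applies the frequency floor per column", {
  rows <- c("AGGA", "AGGA", "AGTA", "AGTC")
  msa <- taxprimer:::new_msa(paste0("s", 1:4), rows)
  # col1 100% A -> A; col2 100% G -> G; col3 50/50 G/T -> K; col4 75/25 A/C
  expect_equal(degenerate_consensus(msa, c(0, 4), f_min = 0.10), "AGKM")
  expect_equal(degenerate_consensus(msa, c(0, 4), f_min = 0.30), "AGKA")
  # minor allele below the floor is suppressed (96/4 pattern)
  rows25 <- c(rep("A", 24), "C")
  msa2 <- taxprimer:::new_msa(paste0("t", 1:25), rows25)
  expect_equal(degenerate_consensus(msa2, c(0, 1), f_min = 0.10), "A")
  # gappy columns are refused
  msa3 <- taxprimer:::new_msa(c("a", "b", "c"), c("A-G", "AAG", "A-G"))
  expect_error(degenerate_consensus(msa3, c(0, 3)), "column 1.*gap fraction")
  # consensus of identical rows is the row slice
  msa4 <- taxprimer:::new_msa(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  expect_equal(degenerate_consensus(msa4, c(2, 6)), "GTAC")
})

test_that("assemble_pair builds a tailed, Tm-matched, orientation-correct pair", {
  set.seed(72)
  base <- rand_dna(1500)
  msa <- taxprimer:::new_msa(paste0("s", 1:4), rep(base, 4))
  # pick a target both windows can reach: halfway between the two core Tms
  tm_f <- melt_tm(degenerate_consensus(msa, c(10, 30)))$mean_C
  tm_r <- melt_tm(reverse_complement(degenerate_consensus(msa, c(1430, 1450))))$mean_C
  target <- (tm_f + tm_r) / 2
  pair <- assemble_pair(msa, c(10, 30), c(1430, 1450), target_tm = target,
                        tol_C = 8)
  expect_s3_class(pair, "primer_pair")
  # reverse core = reverse complement of the window consensus; after the 5'
  # trim it maps back to a prefix of the consensus on the template strand
  rev_cons <- degenerate_consensus(msa, c(1430, 1450))
  expect_equal(reverse_complement(pair$reverse$core),
               substr(rev_cons, 1, nchar(pair$reverse$core)))
  expect_equal(pair$expected_len_range[1],
               pair$reverse$window[2] - pair$forward$window[1])
  expect_true(pair$expected_len_range[1] >= 1250 &&
                pair$expected_len_range[1] <= 1750)
  expect_equal(pair$forward$full_oligo,
               paste0(pair$forward$tail, pair$forward$core))
  td <- tidy(pair)
  expect_equal(nrow(td), 2)
  expect_equal(td$orientation, c("forward", "reverse"))
  expect_true(all(abs(td$tm_mean - target) <= 8))

  # windows too close -> amplicon below the floor
  expect_error(assemble_pair(msa, c(10, 30), c(200, 230), target_tm = target,
                             tol_C = 8),
               "outside")
  # misordered windows
  expect_error(assemble_pair(msa, c(400, 430), c(200, 230), target_tm = target),
               "precede")
})

test_that("primer TSV round-trips through write/read", {
  pair <- universal_pair_fixture()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_primers_tsv(pair, tf)
  back <- read_primers_tsv(tf)
  expect_equal(back$forward$core, pair$forward$core)
  expect_equal(back$reverse$core, pair$reverse$core)
  expect_equal(back$forward$tail, pair$forward$tail)
})

test_that("published primer set carries the expected architecture", {
  pp <- published_primers()
  expect_equal(nrow(pp), 5)
  expect_true(all(nchar(pp$tail) == 22))
  expect_equal(pp$full_oligo, paste0(pp$tail, pp$core))
  # one K in Rev1413, nothing else degenerate
  expect_equal(vapply(pp$core, degeneracy, numeric(1), USE.NAMES = FALSE),
               c(2, 1, 1, 1, 2))
})
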