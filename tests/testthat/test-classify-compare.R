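ref_fixture <- function(n = 4, len = 1500, seed = 90) {
  set.seed(seed)
  tibble::tibble(id = sprintf("ref%02d", 1:n),
                 seq = vapply(rep(len, n), rand_dna, character(1)))
}

tax_fixture <- function(refdb) {
  tibble::tibble(
    id = refdb$id,
    lineage = sprintf("Bacteria;Firmicutes;Clostridia;Clostridiales;fam_%d;genus_%d;species_%d",
                      seq_len(nrow(refdb)), seq_len(nrow(refdb)), seq_len(nrow(refdb)))
  )
}

test_that("length filter keeps the inclusive 1250-1750 window and partitions", {
  set.seed(91)
  reads <- tibble::tibble(
    id = paste0("r", 1:5),
    seq = vapply(c(1249, 1250, 1500, 1750, 1751), rand_dna, character(1))
  )
  parts <- length_filter(reads)
  expect_equal(parts$kept$id, c("r2", "r3", "r4"))
  expect_equal(parts$removed$id, c("r1", "r5"))
  expect_equal(nrow(parts$kept) + nrow(parts$removed), nrow(reads))
  empty <- length_filter(reads[0, ])
  expect_equal(nrow(empty$kept) + nrow(empty$removed), 0)
})

test_that("a read identical to a reference classifies with its full lineage", {
  refdb <- ref_fixture()
  tax <- tax_fixture(refdb)
  read <- tibble::tibble(id = "q", seq = refdb$seq[2])
  a <- assign_read(read, refdb, tax)
  expect_equal(a$status, "classified")
  expect_equal(a$best_ref, "ref02")
  expect_equal(a$identity, 1.0)
  expect_equal(a$ref_coverage, 1.0)
  expect_equal(a$lineage, tax$lineage[2])
})

test_that("coverage and identity gates are strict inequalities", {
  refdb <- ref_fixture(1, len = 1500)
  tax <- tax_fixture(refdb)
  params <- classify_params(len_lo = 100, len_hi = 2000)

  # truncated read: perfect identity but exactly 55% reference coverage
  read55 <- tibble::tibble(id = "short", seq = substr(refdb$seq[1], 1, 825))
  a <- assign_read(read55, refdb, tax, params)
  expect_equal(a$status, "unclassified")
  expect_equal(a$ref_coverage, 0.55)
  expect_equal(a$identity, 1.0)

  # boundary: exactly 60% coverage stays unclassified under strict '>'
  read60 <- tibble::tibble(id = "b60", seq = substr(refdb$seq[1], 1, 900))
  a60 <- assign_read(read60, refdb, tax, params)
  expect_equal(a60$ref_coverage, 0.60)
  expect_equal(a60$status, "unclassified")
  # nudge one base beyond the boundary -> classified
  read61 <- tibble::tibble(id = "b61", seq = substr(refdb$seq[1], 1, 901))
  expect_equal(assign_read(read61, refdb, tax, params)$status, "classified")

  # exact identity boundary 0.80: gap-free alignment, 20% mismatches
  set.seed(92)
  ref <- tibble::tibble(id = "refX", seq = "ACGTACGTACGTACGTACGT")
  taxX <- tibble::tibble(id = "refX", lineage = "Bacteria;Firmicutes")
  pX <- classify_params(len_lo = 1, len_hi = 100, min_ref_cov = 0.5,
                        min_identity = 0.80)
  # flip 4 of 20 bases in the middle (identity exactly 0.8, coverage 1.0)
  chars <- strsplit(ref$seq, "")[[1]]
  for (p in c(5, 9, 13, 17)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  read80 <- tibble::tibble(id = "q80", seq = paste(chars, collapse = ""))
  a80 <- assign_read(read80, ref, taxX, pX)
  expect_equal(a80$identity, 0.80)
  expect_equal(a80$ref_coverage, 1.0)
  expect_equal(a80$status, "unclassified")
  # unclassified reads need no lineage entry
  expect_no_error(assign_read(read55, refdb, tax_fixture(refdb)[0, ], params))
})

test_that("ties go to the lexicographically smallest reference id", {
  set.seed(93)
  s <- rand_dna(1300)
  refdb <- tibble::tibble(id = c("zeta", "alpha"), seq = c(s, s))
  tax <- tibble::tibble(id = c("zeta", "alpha"),
                        lineage = c("Bacteria;Zeta", "Bacteria;Alpha"))
  a <- assign_read(tibble::tibble(id = "q", seq = s), refdb, tax)
  expect_equal(a$best_ref, "alpha")
  # and is invariant to refdb row order
  a2 <- assign_read(tibble::tibble(id = "q", seq = s), refdb[2:1, ], tax)
  expect_equal(a2$best_ref, "alpha")
})

test_that("classify_reads partitions statuses and conserves counts", {
  refdb <- ref_fixture(3)
  tax <- tax_fixture(refdb)
  set.seed(94)
  reads <- tibble::tibble(
    id = c("good", "short", "junk"),
    seq = c(refdb$seq[1], rand_dna(100), rand_dna(1400))
  )
  out <- classify_reads(reads, refdb, tax)
  expect_equal(out$read_id, reads$id)
  expect_equal(out$status, c("classified", "length_filtered", "unclassified"))
  ab <- abundance_table(out, "genus")
  expect_equal(ab$total_reads, 3)
  expect_equal(ab$n_unclassified, 1)
  expect_equal(ab$n_filtered, 1)
  expect_equal(sum(ab$counts$count) + ab$n_unclassified + ab$n_filtered, 3)

  # krona round trip conserves counts
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_krona_tsv(krona_abundance(out), tf)
  expect_equal(sum(read_krona_tsv(tf)$count), 3)
})

test_that("simulated noisy reads recover their true genus", {
  spec <- community_spec(n_archaea = 2, n_bacteria = 4, seed = 95)
  comm <- evolve_community(spec)
  amps <- dplyr::mutate(comm$seqs, abundance = spec$taxa$abundance)
  sim <- simulate_reads(amps, read_sim_params(sub_rate = 0.02, ins_rate = 0,
                                              del_rate = 0, n_reads = 60,
                                              seed = 96))
  out <- classify_reads(sim$reads, comm$seqs, comm$taxonomy)
  cls <- out[out$status == "classified", ]
  expect_gt(nrow(cls), 50)
  truth_lineage <- comm$taxonomy$lineage[match(
    sim$truth$source_id[match(cls$read_id, sim$truth$read_id)], comm$taxonomy$id)]
  agree <- mean(lineage_at_rank(cls$lineage, "genus") ==
                  lineage_at_rank(truth_lineage, "genus"))
  expect_gte(agree, 0.95)
})

test_that("self-comparison gives agreement 1 and L1 0; disjoint sets error", {
  refdb <- ref_fixture(3)
  tax <- tax_fixture(refdb)
  assigns <- tibble::tibble(
    read_id = paste0("r", 1:6), status = "classified",
    best_ref = rep(refdb$id, 2), identity = 0.95, ref_coverage = 0.9,
    lineage = rep(tax$lineage, 2)
  )
  rep <- compare_classifiers(assigns, assigns)
  expect_true(all(rep$agreement == 1))
  expect_true(all(rep$l1_distance == 0))
  other <- dplyr::mutate(assigns, read_id = paste0("x", 1:6))
  expect_error(compare_classifiers(assigns, other), "no common reads")
})

test_that("genus-level agreement with species-level disagreement is scored per rank", {
  lin_a <- "Bacteria;Proteobacteria;Gamma;Oceanospirillales;F;Oleiphilus;Oleiphilus_sp"
  lin_b <- "Bacteria;Proteobacteria;Gamma;Oceanospirillales;F;Oleiphilus;Oleiphilus_other"
  a <- tibble::tibble(read_id = paste0("r", 1:10), status = "classified",
                      best_ref = "x", identity = 0.9, ref_coverage = 0.9,
                      lineage = lin_a)
  b <- dplyr::mutate(a, lineage = lin_b)
  rep <- compare_classifiers(a, b)
  expect_equal(rep$agreement[rep$rank == "genus"], 1.0)
  expect_equal(rep$agreement[rep$rank == "species"], 0.0)
  expect_equal(rep$l1_distance[rep$rank == "species"], 2.0)
})

test_that("agreement is rank-monotone for consistent prefix-closed lineages", {
  set.seed(97)
  ranks <- tax_ranks()
  for (trial in 1:25) {
    # one consistent taxonomy: each node has a unique parent chain
    n_taxa <- 6
    taxa <- vapply(1:n_taxa, function(i) {
      g <- sample(1:3, 1)
      sprintf("SK%d;P%d;C%d;O%d;F%d;G%d;S%d",
              g %% 2, g, g, g, g * 10 + sample(1:2, 1), i, i)
    }, character(1))
    n <- 40
    a <- tibble::tibble(read_id = paste0("r", 1:n), status = "classified",
                        best_ref = "x", identity = 1, ref_coverage = 1,
                        lineage = sample(taxa, n, replace = TRUE))
    b <- dplyr::mutate(a, lineage = sample(taxa, n, replace = TRUE))
    rep <- compare_classifiers(a, b, ranks)
    ag <- rep$agreement[match(ranks, rep$rank)]
    expect_true(all(diff(ag) <= 1e-12))
  }
})
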