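test_that("binding sites are found on both strands with anchored 3' ends", {
  set.seed(80)
  core <- "ACGTACGTACGTAC"
  bg <- rand_dna(400)
  tmpl <- tibble::tibble(
    id = "t1",
    seq = paste0(substr(bg, 1, 100), core, substr(bg, 101, 300),
                 reverse_complement(core), substr(bg, 301, 400))
  )
  sites <- find_binding_sites(tmpl, core)
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  expect_true(any(plus$start == 100 & plus$mismatches == 0))
  expect_true(any(minus$start == 314 & minus$mismatches == 0))
})

test_that("degenerate primer bases match by set intersection", {
  tmpl <- tibble::tibble(id = "t", seq = "GGGGGGACTGCTGGGGGG")
  sites <- find_binding_sites(tmpl, "ACKGCT", bind_params(max_mismatch = 0))
  expect_equal(sites$mismatches[sites$strand == "+"], 0)
  expect_equal(sites$start[sites$strand == "+"], 6)
  # primer base vs template N counts as a match
  tmplN <- tibble::tibble(id = "t", seq = "GGGGGGACNGCTGGGGGG")
  sN <- find_binding_sites(tmplN, "ACKGCT", bind_params(max_mismatch = 0))
  expect_true(any(sN$strand == "+" & sN$mismatches == 0))
})

test_that("site finder equals the brute-force scan oracle", {
  set.seed(81)
  for (k in 1:25) {
    tmpl <- rand_dna(150)
    core <- if (k %% 3 == 0) paste0(rand_dna(5), "K", rand_dna(4))
            else substr(tmpl, 60, 69) # guarantee some perfect hits
    mm <- sample(0:3, 1)
    got <- taxprimer:::.scan_sites_cpp(tmpl, core, mm, 3L)
    want <- oracle_scan(tmpl, core, mm, 3L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got[, 1], want$start)
      expect_equal(got[, 2], want$mismatches)
    }
  }
})

planted_template <- function(fwd_core, rev_core, gap = 1406, seed = 82) {
  set.seed(seed)
  lead <- rand_dna(25)
  mid <- rand_dna(gap)
  tail <- rand_dna(30)
  tibble::tibble(id = "planted",
                 seq = paste0(lead, fwd_core, mid,
                              reverse_complement(rev_core), tail))
}

test_that("amplicons are predicted from facing site pairs", {
  pair <- universal_pair_fixture()
  fl <- nchar(pair$forward$core); rl <- nchar(pair$reverse$core)
  gap <- 1440 - fl - rl
  tmpl <- planted_template(pair$forward$core, pair$reverse$core, gap = gap)
  amps <- predict_amplicons(tmpl, pair)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, 1440)
  expect_equal(amps$start, 25)
  expect_equal(amps$orientation, "+")

  # forward site only -> nothing
  t2 <- tibble::tibble(id = "fonly",
                       seq = paste0(rand_dna(20), pair$forward$core, rand_dna(500)))
  expect_equal(nrow(predict_amplicons(t2, pair)), 0)

  # two forward sites facing one reverse site -> two products
  t3 <- tibble::tibble(id = "ff", seq = paste0(
    rand_dna(10), pair$forward$core, rand_dna(100), pair$forward$core,
    rand_dna(300), reverse_complement(pair$reverse$core), rand_dna(10)))
  a3 <- predict_amplicons(t3, pair)
  expect_equal(nrow(a3), 2)
  expect_equal(length(unique(a3$end)), 1)
})

test_that("strand mirror: flipping the template mirrors amplicons exactly", {
  pair <- universal_pair_fixture()
  tmpl <- planted_template(pair$forward$core, pair$reverse$core, gap = 500,
                           seed = 83)
  flipped <- tibble::tibble(id = "flip", seq = reverse_complement(tmpl$seq))
  a1 <- predict_amplicons(tmpl, pair)
  a2 <- predict_amplicons(flipped, pair)
  n <- nchar(tmpl$seq)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(sort(a2$length), sort(a1$length))
  expect_equal(sort(n - a1$end), sort(a2$start))
  expect_setequal(a2$orientation, "-")
})

test_that("coverage is monotone in the mismatch tolerance and conserves counts", {
  pair <- universal_pair_fixture()
  set.seed(84)
  mk_template <- function(n_mut) {
    fc <- strsplit(pair$forward$core, "")[[1]]
    # mutate the 5' side of the forward site, keeping the 3' anchor intact
    for (p in seq_len(n_mut)) fc[p] <- setdiff(c("A", "C", "G", "T"), fc[p])[1]
    paste0(rand_dna(20), paste(fc, collapse = ""), rand_dna(800),
           reverse_complement(expand_iupac(pair$reverse$core)[1]), rand_dna(20))
  }
  db <- tibble::tibble(
    id = sprintf("s%d", 0:4),
    seq = vapply(0:4, mk_template, character(1))
  )
  tax <- tibble::tibble(id = db$id,
                        lineage = rep(c("Bacteria;Firmicutes", "Archaea;Euryarchaeota"),
                                      length.out = 5))
  covs <- vapply(0:4, function(mm) {
    rep <- panel_coverage(db, tax, pair, bind_params(max_mismatch = mm),
                          rank = "phylum")
    expect_equal(sum(rep$per_taxon$n_sequences), 5) # conservation
    sum(rep$per_taxon$n_amplified) / sum(rep$per_taxon$n_sequences)
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_equal(covs[1], 1 / 5) # only the unmutated template at 0 mismatches
  expect_error(panel_coverage(db[0, ], tax, pair), "empty")
})

test_that("group rollup separates superkingdoms", {
  pair <- archaeal_pair_fixture()
  set.seed(85)
  arch <- planted_template(pair$forward$core, pair$reverse$core, 500, seed = 86)
  bact <- tibble::tibble(id = "b1", seq = rand_dna(600))
  db <- dplyr::bind_rows(dplyr::mutate(arch, id = "a1"), bact)
  tax <- tibble::tibble(id = c("a1", "b1"),
                        lineage = c("Archaea;Euryarchaeota", "Bacteria;Firmicutes"))
  rep <- panel_coverage(db, tax, pair, rank = "phylum")
  sk <- rep$per_superkingdom
  expect_equal(sk$coverage[sk$taxon == "Archaea"], 1)
  expect_equal(sk$coverage[sk$taxon == "Bacteria"], 0)
  expect_equal(glance(rep)$coverage_Archaea, 1)
})
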