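# Deterministic generator of mock two-superkingdom communities, genomes with
# an embedded 16S on either strand, and noisy full-length amplicon reads, with
# complete ground truth. Every stage is seeded and reproducible, so the whole
# workflow is testable without downloads.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_positions <- function(chars, idx) {
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  chars
}

#' Alternating conserved/hypervariable block layout
#'
#' Emulates the 16S architecture of conserved stretches flanking hypervariable
#' regions (V1-V9): conserved blocks of `cons_len` alternate with variable
#' blocks of `var_len`, tiling `[0, template_len)` exactly (the final block is
#' clipped). The defaults (60/100 over 1500 bases) give ten conserved and nine
#' variable blocks.
#'
#' @param template_len Template length in bases (default 1500).
#' @param cons_len,var_len Block lengths (defaults 60 and 100).
#' @return Tibble `start, end, type` with 0-based half-open spans.
#' @export
block_layout <- function(template_len = 1500, cons_len = 60, var_len = 100) {
  start <- 0; rows <- list(); type <- "conserved"
  while (start < template_len) {
    w <- if (type == "conserved") cons_len else var_len
    end <- min(start + w, template_len)
    rows[[length(rows) + 1]] <- tibble(start = start, end = end, type = type)
    start <- end
    type <- if (type == "conserved") "variable" else "conserved"
  }
  dplyr::bind_rows(rows)
}

#' Specification of a synthetic two-superkingdom community
#'
#' Parameters and ground-truth scaffold for a mock archaea/bacteria community:
#' every taxon's 16S derives from one random template whose conserved blocks
#' mutate slowly and whose hypervariable blocks mutate fast, plus extra
#' substitutions shared within each superkingdom (a clade signature that makes
#' the two groups separable the way real archaeal and bacterial 16S are).
#'
#' @param n_archaea,n_bacteria Taxon counts (defaults 4 and 12, a minority of
#'   archaea among bacteria as in hot-spring communities).
#' @param archaea_fraction Total relative abundance of the archaeal taxa
#'   (default 0.10), split evenly; bacteria share the rest evenly.
#' @param template_len Template length (default 1500, full-length 16S scale).
#' @param layout Block layout tibble (default [block_layout()]).
#' @param cons_rate,var_rate Per-base substitution probabilities on
#'   conserved/variable blocks (defaults 0.01 and 0.20; conserved 16S blocks diverge little across a clade, hypervariable blocks a lot).
#' @param sig_rate Per-base probability of a superkingdom-signature
#'   substitution (default 0.04).
#' @param seed Integer seed driving all randomness.
#' @param taxa Optional explicit tibble `id, lineage, abundance` overriding
#'   the generated taxon list.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_archaea = 4, n_bacteria = 12,
                           archaea_fraction = 0.10, template_len = 1500,
                           layout = block_layout(template_len),
                           cons_rate = 0.01, var_rate = 0.20, sig_rate = 0.04,
                           seed = 1, taxa = NULL) {
  if (is.null(taxa)) {
    mk <- function(n, sk, phyla, frac) {
      if (n == 0) return(NULL)
      tibble(
        id = sprintf("%s_taxon_%02d", tolower(sk), seq_len(n)),
        lineage = sprintf("%s;%s;%s_class_%d;%s_order_%d;%s_family_%d;%s_genus_%d;%s_species_%d",
                          sk, phyla[(seq_len(n) - 1) %% length(phyla) + 1],
                          sk, (seq_len(n) - 1) %/% 2 + 1, sk, seq_len(n), sk, seq_len(n),
                          sk, seq_len(n), sk, seq_len(n)),
        abundance = frac / n
      )
    }
    taxa <- dplyr::bind_rows(
      mk(n_archaea, "Archaea", c("Euryarchaeota", "Crenarchaeota"), archaea_fraction),
      mk(n_bacteria, "Bacteria", c("Firmicutes", "Proteobacteria"), 1 - archaea_fraction)
    )
  }
  if (abs(sum(taxa$abundance) - 1) > 1e-8) abort("abundances must sum to 1")
  if (max(layout$end) != template_len || min(layout$start) != 0) {
    abort("block layout must tile [0, template_len)")
  }
  structure(list(taxa = taxa, template_len = template_len, layout = layout,
                 cons_rate = cons_rate, var_rate = var_rate,
                 sig_rate = sig_rate, seed = seed),
            class = "community_spec")
}

#' Evolve the per-taxon 16S sequences of a community
#'
#' Draws one random template, applies a shared signature to each
#' superkingdom's copy, then mutates each taxon independently: conserved
#' blocks at `cons_rate`, variable blocks at `var_rate`. Byte-identical under
#' a fixed seed.
#'
#' @param spec A [community_spec()].
#' @return List: `seqs` (tibble `id, seq`), `taxonomy` (tibble `id, lineage`),
#'   `truth` (list with `template`, `layout`, `taxa`).
#' @export
evolve_community <- function(spec) {
  with_seed(spec$seed, {
    template <- seq_chars(random_dna(spec$template_len))
    rate_at <- rep(spec$cons_rate, spec$template_len)
    for (i in seq_len(nrow(spec$layout))) {
      if (spec$layout$type[i] == "variable") {
        rate_at[(spec$layout$start[i] + 1):spec$layout$end[i]] <- spec$var_rate
      }
    }
    sks <- unique(lineage_at_rank(spec$taxa$lineage, "superkingdom"))
    sk_template <- lapply(sks, function(sk) {
      idx <- which(stats::runif(spec$template_len) < spec$sig_rate)
      mutate_positions(template, idx)
    })
    names(sk_template) <- sks
    seqs <- vapply(seq_len(nrow(spec$taxa)), function(i) {
      sk <- lineage_at_rank(spec$taxa$lineage[i], "superkingdom")
      chars <- sk_template[[sk]]
      idx <- which(stats::runif(spec$template_len) < rate_at)
      paste(mutate_positions(chars, idx), collapse = "")
    }, character(1))
    list(
      seqs = tibble(id = spec$taxa$id, seq = seqs),
      taxonomy = tibble(id = spec$taxa$id, lineage = spec$taxa$lineage),
      truth = list(template = paste(template, collapse = ""),
                   layout = spec$layout, taxa = spec$taxa)
    )
  })
}

#' Embed a 16S sequence in a random background genome
#'
#' Places the gene at a seeded position on a seeded strand (forward or
#' reverse complement, 50/50) inside a uniform-composition background, so
#' locus extraction can be tested against exact truth.
#'
#' @param seq16s The gene sequence (character scalar).
#' @param genome_len Total genome length, `> nchar(seq16s) + 200`.
#' @param seed Integer seed.
#' @param id Genome record id.
#' @return List: `genome` (one-row tibble `id, seq`), `locus` (tibble
#'   `genome_id, start, end, strand`).
#' @export
embed_in_genome <- function(seq16s, genome_len, seed = 1, id = "genome") {
  L <- nchar(seq16s)
  if (genome_len <= L + 200) abort("genome too short to embed the gene")
  with_seed(seed, {
    bg <- random_dna(genome_len - L)
    start <- sample.int(genome_len - L + 1, 1) - 1  # 0-based insert position
    strand <- sample(c("+", "-"), 1)
    insert <- if (strand == "+") seq16s else reverse_complement(seq16s)
    genome <- paste0(substr(bg, 1, start), insert,
                     substr(bg, start + 1, nchar(bg)))
    list(genome = tibble(id = id, seq = genome),
         locus = tibble(genome_id = id, start = start, end = start + L,
                        strand = strand))
  })
}

#' Long-read error model parameters
#'
#' Independent per-base substitutions, insertions and deletions, applied
#' substitutions-first then indels left to right (so truth alignments stay
#' computable). Defaults approximate modern long-read error rates.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities (defaults
#'   0.02, 0.015, 0.015; all must be below 0.2).
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.015,
                            n_reads = 300, seed = 1) {
  if (any(c(sub_rate, ins_rate, del_rate) < 0) ||
      any(c(sub_rate, ins_rate, del_rate) >= 0.2)) {
    abort("error rates must be in [0, 0.2)")
  }
  if (n_reads < 1) abort("n_reads must be >= 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, n_reads = n_reads, seed = seed),
            class = "read_sim_params")
}

mutate_read <- function(seq, p) {
  chars <- seq_chars(seq)
  L <- length(chars)
  sub_idx <- which(stats::runif(L) < p$sub_rate)
  chars <- mutate_positions(chars, sub_idx)
  keep <- stats::runif(L) >= p$del_rate
  ins <- stats::runif(L) < p$ins_rate
  out <- character(0)
  for (i in seq_len(L)) {
    if (ins[i]) out <- c(out, sample(c("A", "C", "G", "T"), 1))
    if (keep[i]) out <- c(out, chars[i])
  }
  paste(out, collapse = "")
}

#' Simulate noisy long reads from amplicons
#'
#' Reads are drawn from the amplicons proportional to `abundance` (multinomial
#' with replacement), then corrupted by the error model. Expected read length
#' is `amplicon length * (1 + ins_rate - del_rate)`.
#'
#' @param amplicons Tibble `id, seq, abundance` (abundances are normalized
#'   internally).
#' @param params A [read_sim_params()].
#' @return List: `reads` (tibble `id, seq`), `truth` (tibble `read_id,
#'   source_id, true_len`).
#' @export
simulate_reads <- function(amplicons, params = read_sim_params()) {
  if (nrow(amplicons) == 0) abort("no amplicons to sample from")
  p <- amplicons$abundance / sum(amplicons$abundance)
  with_seed(params$seed, {
    src <- sample.int(nrow(amplicons), params$n_reads, replace = TRUE, prob = p)
    seqs <- vapply(src, function(i) mutate_read(amplicons$seq[i], params),
                   character(1))
    ids <- sprintf("read_%05d", seq_len(params$n_reads))
    list(reads = tibble(id = ids, seq = seqs),
         truth = tibble(read_id = ids, source_id = amplicons$id[src],
                        true_len = nchar(seqs)))
  })
}

# Deterministically diverge a primer site beyond any mismatch tolerance:
# flip every 2nd base (cycled A->C->G->T->A), including the 3' anchor.
diverge_site <- function(core) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- seq_chars(expand_iupac(core)[1])
  idx <- seq(1, length(chars), by = 2)
  chars[idx] <- nxt[chars[idx]]
  paste(chars, collapse = "")
}

plant <- function(seq, at, site) {
  paste0(substr(seq, 1, at), site, substr(seq, at + nchar(site) + 1, nchar(seq)))
}

#' Primer-bias scenario: universal vs archaea-targeted pair
#'
#' Builds a mixed community in which every taxon carries binding sites for the
#' archaea-targeted pair, but the universal forward site is planted intact
#' only in bacteria -- in archaea it is diverged far beyond any mismatch
#' tolerance. In-silico PCR, read simulation and classification are then run
#' under each pair and the archaeal read fraction is reported: the universal
#' pair sees no archaea at all, while the targeted pair recovers the
#' community's archaeal abundance (and still amplifies the bacteria, which is
#' exactly the cross-superkingdom behaviour such primers show).
#'
#' @param spec A [community_spec()] containing both superkingdoms.
#' @param universal_pair,archaeal_pair `primer_pair` objects.
#' @param bind A [bind_params()].
#' @param read_params A [read_sim_params()]; one read set of `n_reads` is
#'   drawn per pair.
#' @param cls_params A [classify_params()].
#' @param scoring A [scoring_scheme()].
#' @return A list with `report` (tibble: `pair, n_reads, n_classified,
#'   n_filtered, n_archaeal, archaeal_fraction`), `community` (the planted
#'   sequences + taxonomy) and `amplicons` (per pair).
#' @export
scenario_primer_bias <- function(spec, universal_pair, archaeal_pair,
                                 bind = bind_params(),
                                 read_params = read_sim_params(),
                                 cls_params = classify_params(),
                                 scoring = scoring_scheme()) {
  comm <- evolve_community(spec)
  sk <- lineage_at_rank(comm$taxonomy$lineage, "superkingdom")
  if (!all(c("Archaea", "Bacteria") %in% sk)) {
    abort("scenario needs both superkingdoms in the community")
  }
  u_f <- expand_iupac(universal_pair$forward$core)[1]
  a_f <- expand_iupac(archaeal_pair$forward$core)[1]
  u_r <- reverse_complement(expand_iupac(universal_pair$reverse$core)[1])
  a_r <- reverse_complement(expand_iupac(archaeal_pair$reverse$core)[1])
  L <- spec$template_len
  # site positions: forward sites near the 5' end, reverse sites near 3'
  pos_uf <- 10
  pos_af <- pos_uf + nchar(u_f) + 10
  pos_ar <- L - nchar(a_r) - 10
  pos_ur <- pos_ar - nchar(u_r) - 10
  seqs <- comm$seqs
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$seq[i]
    fwd_site <- if (sk[i] == "Archaea") diverge_site(u_f) else u_f
    s <- plant(s, pos_uf, fwd_site)
    s <- plant(s, pos_af, a_f)
    s <- plant(s, pos_ur, u_r)
    s <- plant(s, pos_ar, a_r)
    seqs$seq[i] <- s
  }
  run_pair <- function(pair, label, seed_offset) {
    amps <- dplyr::bind_rows(lapply(seq_len(nrow(seqs)), function(i) {
      a <- predict_amplicons(seqs[i, ], pair, bind)
      if (nrow(a) == 0) return(NULL)
      a <- a[1, ] # longest-outer product: first by start, last end kept below
      a <- tibble(id = seqs$id[i],
                  seq = substr(seqs$seq[i], a$start + 1, a$end),
                  abundance = spec$taxa$abundance[i])
      a
    }))
    if (is.null(amps) || nrow(amps) == 0) {
      return(list(report = tibble(pair = label, n_reads = 0L, n_classified = 0L,
                                  n_filtered = 0L, n_archaeal = 0L,
                                  archaeal_fraction = NA_real_),
                  amplicons = tibble()))
    }
    rp <- read_params
    rp$seed <- read_params$seed + seed_offset
    sim <- simulate_reads(amps, rp)
    assigns <- classify_reads(sim$reads, seqs, comm$taxonomy, cls_params, scoring)
    cls <- assigns[assigns$status == "classified", ]
    n_arch <- sum(lineage_at_rank(cls$lineage, "superkingdom") == "Archaea",
                  na.rm = TRUE)
    list(report = tibble(
      pair = label, n_reads = nrow(assigns), n_classified = nrow(cls),
      n_filtered = sum(assigns$status == "length_filtered"),
      n_archaeal = n_arch,
      archaeal_fraction = if (nrow(cls) > 0) n_arch / nrow(cls) else NA_real_
    ), amplicons = amps)
  }
  uni <- run_pair(universal_pair, "universal", 0)
  arc <- run_pair(archaeal_pair, "archaeal", 1)
  list(report = dplyr::bind_rows(uni$report, arc$report),
       community = list(seqs = seqs, taxonomy = comm$taxonomy),
       amplicons = list(universal = uni$amplicons, archaeal = arc$amplicons))
}
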