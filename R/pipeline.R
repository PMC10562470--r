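# End-to-end workflow: synthesize (or load) a community, extract the 16S
# panel from genomes, align it, design a tailed Tm-matched primer pair,
# evaluate it by in-silico PCR, simulate reads, classify them and compare
# against the ground-truth labeling. One config, one seed, deterministic
# outputs.

#' Default pipeline configuration
#'
#' Every tunable of [run_pipeline()] with its default. Values loaded from a
#' YAML file or passed as a list override these field by field.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_archaea = 6, n_bacteria = 10, archaea_fraction = 0.10,
    template_len = 1500, cons_rate = 0.01, var_rate = 0.20, sig_rate = 0.04,
    genome_len = 5000,
    min_identity = 0.70, min_cov = 0.50,
    win_len = 18, min_mean_cons = 0.96, max_gap_frac = 0.10,
    target_tm = 46, tol_C = 3, f_min = 0.10, degeneracy_cap = 64,
    amplicon_min = 1250, amplicon_max = 1750, primer_max_cols = 26,
    max_mismatch = 2, anchor3_len = 3, max_amplicon = 3000,
    n_reads = 120, sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.015,
    len_lo = 1250, len_hi = 1750, min_ref_cov = 0.60, otu_min_identity = 0.80,
    rank = "genus"
  )
}

load_config <- function(config = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(config)] <- config
  }
  cfg
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-column IUPAC set size the consensus would emit under f_min
consensus_set_sizes <- function(msa, f_min) {
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  apply(mat, 2, function(chars) {
    chars <- chars[chars != "-"]
    if (length(chars) == 0) return(4L)
    freq <- c(A = 0, C = 0, G = 0, T = 0)
    for (ch in chars) {
      set <- IUPAC_SETS[[ch]]
      freq[set] <- freq[set] + 1 / length(set)
    }
    max(1L, sum(freq / length(chars) >= f_min))
  })
}

# Pick the earliest forward and latest reverse primer site whose trimmed pair
# assembles inside the amplicon constraints. Candidate sites are maximal runs
# of primer-suitable columns (gap-poor, consensus at most 2-fold degenerate)
# inside the reported conserved windows; runs wider than `primer_max_cols`
# are cut at the 3'-anchored edge.
select_and_assemble <- function(msa, windows, cfg, params = tm_params()) {
  if (nrow(windows) < 2) abort("need at least two conserved windows to design a pair")
  rng <- c(cfg$amplicon_min, cfg$amplicon_max)
  in_window <- logical(msa$n_cols)
  for (i in seq_len(nrow(windows))) {
    in_window[(windows$start[i] + 1):windows$end[i]] <- TRUE
  }
  prof <- column_profiles(msa)
  suitable <- in_window & prof$gap_fraction <= cfg$max_gap_frac &
    consensus_set_sizes(msa, cfg$f_min) <= 2
  rr <- rle(suitable)
  run_end <- cumsum(rr$lengths)
  run_start <- run_end - rr$lengths + 1
  keep <- rr$values & rr$lengths >= cfg$win_len
  runs <- tibble(start = run_start[keep] - 1L, end = run_end[keep]) # 0-based half-open
  if (nrow(runs) < 2) abort("fewer than two primer-suitable conserved runs")
  sizes <- consensus_set_sizes(msa, cfg$f_min)
  # longest anchored cut whose consensus degeneracy stays within the cap
  cut_len <- function(cols) { # cols ordered outward from the 3' anchor
    lens <- seq_along(cols)
    admissible <- cumprod(sizes[cols]) <= cfg$degeneracy_cap &
      lens <= cfg$primer_max_cols
    if (!any(admissible[seq_len(min(cfg$win_len, length(cols)))])) return(0L)
    max(lens[admissible])
  }
  # if no pair matches the target Tm within tol_C, take the closest achievable
  # match before giving up: a slightly worse Tm pairing beats having no primer
  for (tol in c(cfg$tol_C, cfg$tol_C + 2, cfg$tol_C + 4)) {
    for (i in seq_len(nrow(runs) - 1)) {
      for (j in rev(seq_len(nrow(runs)))) {
        if (j <= i) next
        # forward primer anchors its 3' end at the run's right edge
        lf <- cut_len(rev((runs$start[i] + 1):runs$end[i]))
        # reverse primer anchors its 3' end at the run's left edge
        lr <- cut_len((runs$start[j] + 1):runs$end[j])
        if (lf < cfg$win_len || lr < cfg$win_len) next
        fw <- c(runs$end[i] - lf, runs$end[i])
        rw <- c(runs$start[j], runs$start[j] + lr)
        pair <- tryCatch(
          assemble_pair(msa, fw, rw, target_tm = cfg$target_tm, tol_C = tol,
                        amplicon_range = rng, params = params, f_min = cfg$f_min,
                        max_gap_frac = cfg$max_gap_frac, cap = cfg$degeneracy_cap),
          error = function(e) NULL)
        if (!is.null(pair)) return(pair)
      }
    }
  }
  abort(sprintf("no primer-site pair yields an amplicon inside [%d, %d]", rng[1], rng[2]))
}

#' Run the whole design-evaluate-classify workflow on a synthetic community
#'
#' Stages: (1) evolve a two-superkingdom community and embed each taxon's 16S
#' in a random genome on a random strand; (2) extract and reorient the 16S
#' panel from the archaeal genomes by alignment to the ancestral template;
#' (3) center-star align the panel, profile conservation, pick conserved
#' windows; (4) assemble a tailed, degenerate, Tm-matched primer pair;
#' (5) in-silico PCR over the full community with per-taxon coverage;
#' (6) simulate noisy long reads from the predicted amplicons; (7) classify
#' them against the community references; (8) compare the classification
#' against the ground-truth labeling per rank. All outputs are plain
#' TSV/FASTA under `outdir` and byte-identical under a fixed seed.
#'
#' @param config `NULL` (all defaults), a named list, or the path of a YAML
#'   file; see [default_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every intermediate object (`community`,
#'   `genomes`, `panel`, `msa`, `profiles`, `windows`, `pair`, `coverage`,
#'   `reads`, `assignments`, `agreement`, `config`).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL, quiet = FALSE) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("resolved config: %s", paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), file.path(outdir, "run_config.yaml"))

  spec <- community_spec(
    n_archaea = cfg$n_archaea, n_bacteria = cfg$n_bacteria,
    archaea_fraction = cfg$archaea_fraction, template_len = cfg$template_len,
    cons_rate = cfg$cons_rate, var_rate = cfg$var_rate, sig_rate = cfg$sig_rate,
    seed = cfg$seed
  )
  comm <- evolve_community(spec)
  write_fasta(comm$seqs, file.path(outdir, "taxa_16s.fasta"))
  write_tsv_plain(comm$taxonomy, file.path(outdir, "taxonomy.tsv"))

  say("embedding 16S genes in %d genomes", nrow(comm$seqs))
  genomes <- list(); loci <- list()
  for (i in seq_len(nrow(comm$seqs))) {
    emb <- embed_in_genome(comm$seqs$seq[i], cfg$genome_len,
                           seed = cfg$seed * 1000 + i, id = comm$seqs$id[i])
    genomes[[i]] <- emb$genome
    loci[[i]] <- emb$locus
  }
  genomes <- dplyr::bind_rows(genomes)
  loci <- dplyr::bind_rows(loci)
  write_fasta(genomes, file.path(outdir, "genomes.fasta"))
  write_tsv_plain(loci, file.path(outdir, "loci_truth.tsv"))

  sk <- lineage_at_rank(comm$taxonomy$lineage, "superkingdom")
  design_ids <- comm$seqs$id[sk == "Archaea"]
  if (length(design_ids) < 2) design_ids <- comm$seqs$id
  ref16s <- tibble(id = "template_16s", seq = comm$truth$template)
  say("extracting the 16S panel from %d design genomes", length(design_ids))
  bp <- build_panel(genomes[genomes$id %in% design_ids, ], ref16s,
                    min_identity = cfg$min_identity, min_cov = cfg$min_cov)
  write_fasta(dplyr::transmute(bp$panel, id = .data$genome_id, seq = .data$seq),
              file.path(outdir, "panel.fasta"))
  write_tsv_plain(bp$skipped, file.path(outdir, "skipped.tsv"))

  say("aligning the panel (center-star)")
  msa <- center_star_msa(tibble(id = bp$panel$genome_id, seq = bp$panel$seq))
  write_msa(msa, file.path(outdir, "msa.afa"))
  profiles <- column_profiles(msa)
  windows <- find_conserved_windows(profiles, cfg$win_len, cfg$min_mean_cons,
                                    cfg$max_gap_frac)
  write_tsv_plain(windows, file.path(outdir, "windows.tsv"))

  say("designing a Tm-matched pair from %d conserved windows", nrow(windows))
  pair <- select_and_assemble(msa, windows, cfg)
  write_primers_tsv(pair, file.path(outdir, "primers.tsv"))

  bind <- bind_params(cfg$max_mismatch, cfg$anchor3_len, cfg$max_amplicon)
  cov <- panel_coverage(comm$seqs, comm$taxonomy, pair, bind, rank = cfg$rank)
  write_tsv_plain(cov$per_taxon, file.path(outdir, "coverage.tsv"))
  write_tsv_plain(cov$per_superkingdom, file.path(outdir, "coverage_superkingdom.tsv"))

  say("simulating %d reads from predicted amplicons", cfg$n_reads)
  amps <- dplyr::bind_rows(lapply(seq_len(nrow(comm$seqs)), function(i) {
    a <- predict_amplicons(comm$seqs[i, ], pair, bind)
    if (nrow(a) == 0) return(NULL)
    tibble(id = comm$seqs$id[i],
           seq = substr(comm$seqs$seq[i], a$start[1] + 1, a$end[1]),
           abundance = spec$taxa$abundance[i])
  }))
  if (nrow(amps) == 0) abort("designed pair amplifies nothing in the community")
  rp <- read_sim_params(cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
                        n_reads = cfg$n_reads, seed = cfg$seed + 7)
  sim <- simulate_reads(amps, rp)
  write_fasta(sim$reads, file.path(outdir, "reads.fasta"))
  write_tsv_plain(sim$truth, file.path(outdir, "reads_truth.tsv"))

  say("classifying reads against the community panel")
  cls <- classify_params(cfg$len_lo, cfg$len_hi, cfg$min_ref_cov, cfg$otu_min_identity)
  assigns <- classify_reads(sim$reads, comm$seqs, comm$taxonomy, cls)
  write_tsv_plain(assigns, file.path(outdir, "assignments.tsv"))
  ab <- krona_abundance(assigns, rank = "species")
  write_krona_tsv(ab, file.path(outdir, "abundance_krona.tsv"))

  truth_assign <- tibble(
    read_id = sim$truth$read_id, status = "classified",
    best_ref = sim$truth$source_id, identity = 1, ref_coverage = 1,
    lineage = comm$taxonomy$lineage[match(sim$truth$source_id, comm$taxonomy$id)]
  )
  agreement <- compare_classifiers(assigns, truth_assign)
  write_tsv_plain(agreement, file.path(outdir, "agreement.tsv"))
  say("done: genus-level agreement with truth = %.3f",
      agreement$agreement[agreement$rank == "genus"])

  invisible(list(community = comm, genomes = genomes, loci = loci,
                 panel = bp, msa = msa, profiles = profiles, windows = windows,
                 pair = pair, coverage = cov, reads = sim$reads,
                 reads_truth = sim$truth, assignments = assigns,
                 agreement = agreement, config = cfg))
}
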