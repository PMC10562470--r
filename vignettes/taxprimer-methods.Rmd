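---
title: "Methods: taxon-targeted 16S primer design and in-silico evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-targeted 16S primer design and in-silico evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxprimer)
```

# The problem

Universal bacterial 16S primers (27F/1492R style) can miss entire
superkingdoms: a community rich in archaea may show no archaeal reads at all
simply because the primers never anneal to archaeal templates. The remedy is
to design primers on the conserved blocks of the *target clade's* 16S genes:
collect whole genomes, extract and reorient the 16S locus from each, align
the panel, find conserved windows, and derive degenerate, tailed,
Tm-matched primer pairs whose amplicons span enough hypervariable sequence to
classify long reads to genus or species. `taxprimer` implements that workflow
end to end, together with the evaluation half: in-silico PCR over a labeled
sequence database, length/coverage/identity-gated read classification, and
per-rank comparison of classifiers.

# Models and procedures

## Local alignment core

Every stage that compares sequences uses one affine-gap local aligner
(Smith–Waterman–Gotoh, compiled): a gap of length $k$ costs
$g_{open} + k \cdot g_{ext}$, defaults $(+2, -3, 5, 2)$ mirroring blastn.
Determinism is guaranteed by fixed tie-breaking: among equal-scoring cells the
smallest end on the first sequence wins, then the smallest end on the second;
traceback prefers diagonal over up over left. IUPAC ambiguity codes score as a
match whenever their base sets intersect, which is what lets degenerate
primers and `N` bases behave sensibly. **Pairwise similarity** is defined as
matches over alignment columns *including gap columns* (the stricter of the
plausible denominators); **reference coverage** is the aligned reference span
over the full reference length.

## Locus extraction

The reference 16S gene is aligned to both strands of each genome; the better
strand wins and coordinates are always reported on the forward strand
(0-based, half-open — the single coordinate convention used internally;
the BLAST-style tabular dialect converts at the file boundary only). Minus-
strand loci are reverse complemented so the panel shares one orientation.
Because the gene is the query and the genome the subject, extraction uses
*subject* coordinates — query coordinates cannot address genome positions.
One locus per genome (the best hit); acceptance floors default to identity
≥ 0.70 and reference coverage ≥ 0.50, deliberately liberal so divergent
archaea are admitted. A genome with no 16S-like region typically fails the
*coverage* floor, not identity: the best local hit on a random background is
a short, near-perfect spurious match.

## Multiple alignment and conservation

The panel is aligned by deterministic center-star: the center maximizes the
summed global pairwise score; every other sequence is merged under "once a
gap, always a gap". This is adequate and exactly reproducible at panel scale
(≤ ~100 × 1.6 kb); `read_msa()` accepts aligned FASTA or Clustal files when
an external aligner is preferred. Conservation per column is the modal base
count over non-gap rows; gap pressure is a separate per-column
`gap_fraction`, because primers must avoid indel-rich columns explicitly
rather than have gaps dilute the conservation score.

`find_conserved_windows()` reports the union of all column windows of length
≥ `win_len` (default 18) whose per-column gap fraction stays ≤ `max_gap_frac`
(default 0.10) and whose mean conservation is ≥ `min_mean_cons` (default
0.90), merged into maximal runs. Two consequences are worth knowing: a
reported run is guaranteed to *contain* a qualifying window, but the run's
own mean can sit marginally below the threshold; and a fully conserved block
is recovered exactly only when the threshold is strict enough that the block
plus one flanking column fails it. Window means are compared with a $10^{-9}$
epsilon so floating-point summation order cannot flip windows sitting exactly
on the threshold.

## Primer assembly

Within a window, the degenerate consensus takes, per column, the IUPAC code
of all bases whose frequency among non-gap rows is at least `f_min` (default
0.10) — minor alleles below the floor are suppressed, and a gappy column is
an error rather than a silent gap in a primer. Degeneracy is the product of
per-symbol set sizes, capped (default 64) before expansion.

Melting temperature is computed on the gene-specific core only; the constant
5' tails are universal tags absent from the template in the first cycles.
The nearest-neighbor model uses the unified duplex parameter table with

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C_T/4)} - 273.15
        + 16.6\,\log_{10}[\mathrm{Na}^+]$$

at defaults 50 mM Na⁺ and 0.25 µM oligo; the classic
Schildkraut–Lifson salt term was chosen for implementability from the formula
alone (divalent corrections are out of scope). A degenerate core reports
mean/min/max over all expanded variants, the mean being the headline value.
The Wallace rule ($2(A{+}T) + 4(G{+}C)$) is available for sanity checks.

Tm matching to the partner set is done by **5'-only trimming**: the 3' end
stays anchored on its conserved, specificity-determining columns, and among
all suffixes down to a floor of 15 bases the one closest to the target wins,
ties toward the longer primer. The reverse core is the reverse complement of
its window consensus, so its 5' trim removes template columns at the
window's far edge. The expected amplicon length (reverse span end minus
forward span start, on alignment columns) must land inside the configured
range, default [1250, 1750] — the same window the read-length filter uses, so
designed amplicons survive filtering.

## In-silico PCR

A primer core binds where its IUPAC sets intersect the template position by
position with at most `max_mismatch` mismatches (default 2) and none within
the 3'-terminal `anchor3_len` bases (default 3) — polymerase extension needs
a matched 3' end. Binding is evaluated on both strands; every facing
forward/reverse site pair with $0 < \text{length} \le$ `max_amplicon`
(default 3000) is reported, and "amplified" for coverage means at least one
product. Coverage is reported per taxon at a chosen rank plus a superkingdom
rollup; it is monotone non-decreasing in the mismatch tolerance by
construction. The mismatch defaults are declared assumptions — the underlying
study reports amplification outcomes, not a binding model.

## Read classification and classifier comparison

Reads are first filtered to the inclusive 1250–1750 base window. A kept read
is assigned to the reference with the highest local alignment score (ties to
the lexicographically smallest id) and is **classified** only when reference
coverage > 0.60 AND identity > 0.80 — "more than" is read as strict on both
thresholds, so boundary reads (exactly 0.60 or 0.80) stay unclassified; the
tests assert the boundary explicitly so the choice is auditable. Assignment
is best-hit only (no LCA over near-ties). Abundance tables conserve counts
exactly: classified + unclassified + length-filtered = input reads, with
lineages truncated at the reporting rank and a Krona-format text export that
round-trips.

`compare_classifiers()` scores, per rank, the fraction of reads classified by
both assignments that received the identical taxon name, plus the L1 distance
between the two rank-level relative-abundance vectors. With prefix-closed
lineages drawn from one consistent taxonomy, agreement can only fall as the
rank gets finer — the "agree at genus, diverge at species" pattern falls out
of the arithmetic.

# The synthetic world

The generator states a mock 16S universe rather than emulating any dataset:

* one random 1500-base template, tiled by ten 60-base conserved blocks
  alternating with nine 100-base hypervariable blocks (the V1–V9
  architecture);
* per-taxon substitutions at 0.01/site in conserved blocks and 0.20/site in
  hypervariable blocks — roughly what conserved 16S stretches versus
  hypervariable loops show across a clade — plus a superkingdom "signature"
  at 0.04/site shared within each group, which is what makes archaea and
  bacteria separable and archaea-specific primers possible;
* a default community of 4 archaea and 12 bacteria with 10% total archaeal
  abundance (archaea as a minority, as in hot-spring communities);
* genomes of uniform base composition with the gene embedded at a seeded
  position on a seeded strand (50/50), because real assemblies carry the gene
  on either strand;
* long reads drawn from amplicons proportional to abundance with independent
  substitutions/insertions/deletions at 0.02/0.015/0.015 per base,
  substitutions first, then indels left to right, so truth alignments remain
  computable.

Everything is seeded; identical seeds give byte-identical FASTA/TSV outputs.

What the generator does **not** model: nanopore signal-level artifacts,
homopolymer-specific errors, chimeras, quality scores, multiple 16S copies
per genome, GC bias, and real phylogenetic covariance between sites. A green
test therefore establishes that the *algorithms* behave as specified on a
world with known truth — not that any particular wet-lab community would
yield the same numbers.

# Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; the tabular
  hit dialect (1-based inclusive, minus strand as start > end) converts at
  the parser/writer boundary only.
* **Strict thresholds**: the classification gates use strict `>`; the window
  finder uses `≥` with a 1e-9 epsilon against summation-order effects.
* **Substitution-only data can still align with gaps**: at hypervariable
  divergence (~20%/site, ~32% pairwise) a maximum-score affine aligner
  sometimes buys a shifted stretch for the price of two gaps. The package
  asserts the "no spurious gaps" property in a low-divergence regime
  (3%/site), where no shift can pay for its gaps; at higher divergence gapped
  optima are correct behaviour, not artifacts.
* **Pipeline primer-site selection** intersects the conserved windows with
  runs of "primer-suitable" columns — gap-poor and at most 2-fold degenerate
  under `f_min` — then cuts each run at its 3'-anchored edge to the longest
  stretch whose consensus degeneracy stays within the cap. On small panels
  this matters: with six rows, every singleton allele clears `f_min` = 0.10,
  and an unconstrained 26-column window can exceed a 64-fold cap. If no pair
  meets the Tm tolerance, the tolerance is relaxed in two +2 °C steps before
  failing: the closest achievable Tm match beats having no primer.
* **Demo target Tm = 46 °C**: the published universal cores melt at ~45–46 °C
  under this package's nearest-neighbor model, and the procedure matches the
  custom cores to the partner set's Tm. The target is a required user input,
  since no printed value exists for it.
* **Degenerate-core Tm** reports statistics over expanded variants rather
  than a single approximation, preserving min/max for the user.
* **Primer names** in the published set (For27, Rev621, Rev1413) are treated
  as opaque labels; their numbers are not used as coordinates.

# Known limitations

* Center-star alignment is a 2-approximation; for panels with heavy indel
  structure an external MSA via `read_msa()` is the better input.
* The binding model is combinatorial (mismatch counts + 3' anchor), not
  thermodynamic; it cannot rank two sites with equal mismatch counts.
* Best-hit classification without LCA can flip between near-tied references;
  the documented tie-break keeps it deterministic but an LCA mode would be
  the principled extension.
* The aligner is exact and quadratic: a read set is classified in
  O(reads × references × length²). Fine at desk scale (hundreds of reads,
  tens of references), not a metagenome-scale classifier.
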