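---
title: "Methods: designing and quantifying base-editing stop-codon knockouts"
author: "bestop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and quantifying base-editing stop-codon knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestop)
```

## The problem

Third-generation cytidine base editors (BE3: a cytidine deaminase fused to a
Cas9 nickase and a uracil-glycosylase inhibitor) convert C:G base pairs to
T:A inside a window of the 20-nt protospacer, without double-strand breaks.
Used as a knockout reagent, a single deamination can turn one of four codons
into a premature stop:

| codon | edit (strand) | stop |
|-------|----------------|------|
| CAA | C1→T (sense) | TAA |
| CAG | C1→T (sense) | TAG |
| CGA | C1→T (sense) | TGA |
| TGG | G2→A, G3→A or both (antisense C→T) | TAG, TGA, TAA |

`bestop` implements the two computational halves of this workflow: a
genome-scale **design scan** over coding sequences, and a **quantification
pipeline** for targeted amplicon deep-sequencing readouts, plus a seeded
simulator that generates both kinds of input with known ground truth.

Protospacer positions are numbered 1–20 from the PAM-distal end, so "C5"
is a cytosine five bases from the distal end. Internally all arithmetic is
0/1-based-consistent on the sense strand of the supplied sequence; every
user-facing coordinate is 1-based inclusive.

## Design scan

`scan_cds()` enumerates every NGG protospacer on both strands
(`find_protospacers()`), every in-frame CAA/CAG/CGA/TGG codon, and every
conversion route (`stop_codon_conversions()`), and reports a knockout site
whenever all codon positions that must be edited fall — as Cs on the
protospacer strand — inside the editing window.

Decisions taken where the procedure was genuinely open:

* **Window membership.** "Motif at positions 1–13" can mean (a) the whole
  codon inside the window or (b) the editable C(s) inside the window. The
  default is (b), the functional requirement for the edit;
  `strict_window = TRUE` gives reading (a).
* **Editing window default** `c(1, 13)`: the window observed for BE3 in
  the silkworm system this package models. The canonical in-vitro window
  `c(4, 8)` is selectable. Widening the window can only add sites (a
  tested invariant).
* **Multi-route codons.** A TGG codon reachable by one protospacer yields
  up to three routes (TAG, TGA, TAA); each is reported as its own row, but
  `summarize_genome()` counts unique (gene, codon, protospacer) pairs once —
  a site is a place you can target, not a route.
* **Stop codons are not targets.** TGA→TAA and TAG→TAA G→A conversions
  exist formally, but a codon that already terminates translation admits no
  *premature* stop; such codons yield no routes. This is what makes the
  four-codon rule exact over all 64 codons (a tested property). It only
  matters for frame-broken input: a valid CDS has no internal stops.
* **Median sites per gene** is computed over targetable genes only (genes
  with at least one site); the targetability percentage is over all genes.
* **Scan domain.** Only the supplied CDS sequence is scanned; protospacers
  or PAMs extending past its ends are not searched, so sites spanning
  splice junctions are missed. Protospacers containing N are discarded and
  codons containing N are untargetable.

The scan is validated against an exhaustive brute-force oracle (every
offset × strand × codon × edit subset) on randomized CDSs, on their reverse
complements, and in both window-membership modes.

## Quantification pipeline

* **Trimming** (`trim_reads()`) reproduces the classic
  LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15 MINLEN:50 rule: end bases below
  Q3 are removed, the read is cut at the start of the first 4-base window
  with mean quality < 15, and reads shorter than 50 nt are discarded.
  Qualities are fixed Phred+33 (modern Illumina); there is no
  auto-detection. Paired-end reads are expected pre-merged.
* **Demultiplexing** (`demultiplex()`) assigns reads by exact joint match
  of a left-prefix/right-suffix barcode pair (0 mismatches — conservative
  and deterministic), counts unassigned reads, and strips barcodes.
  Trimming runs before demultiplexing, matching the original processing
  order; per-sample "raw" counts are therefore post-trim counts, and
  pool-level raw/discarded totals are recorded in the run manifest.
* **Alignment.** Each read is aligned to its known amplicon reference
  (global over the read, local over the reference) with affine gap costs:
  match +2, mismatch −3, gap open 5, gap extend 2. With a single known
  reference, read mapping would add nothing. Tie-breaking among equal-score
  alignments follows the dynamic-programming engine
  (`Biostrings::pairwiseAlignment`). Identical reads are deduplicated
  before alignment, which changes nothing numerically.
* **Classification** (`classify_reads()`): a read is `not_covering` if its
  alignment does not span the full 20-bp protospacer (excluded from that
  site's tallies), `edited` if at least one targeted C shows the C→T
  conversion in protospacer-strand orientation (T at a plus-strand C; A at
  a minus-strand G), otherwise `unedited`. Substitutions other than the
  targeted C→T never make a read edited. Efficiency is the edited fraction
  of clean reads, as a percentage to one decimal.
* **Editing-window profile** (`window_profile()`): per position n, the
  number of designed gRNAs carrying Cn and the number whose measured
  per-position fraction exceeds a detection threshold; the ratio estimates
  the substitution probability at Cn. The threshold defaults to 0.5% and
  rises to 3× the control rate per position when a no-gRNA control sample
  is provided — the data themselves do not fix a threshold, so both
  components are configurable.
* **Multiplex counting** (`multiplex_histogram()`): per read, the number
  of distinct targeted positions (union over all sites; shared positions
  count once) showing the conversion; reads not spanning all targeted
  positions are excluded and reported.
* **Indels** (`indel_frequency()`): a read is an indel read iff its best
  alignment contains at least one internal gap. Terminal gaps reflect read
  length, not editing, and are ignored. On substitution-only input with no
  sequencing error the caller returns exactly 0% (a tested invariant).
  Because the original indel figures depended on a short-read mapper's
  conventions (soft-clipping etc.), this definition is not expected to
  reproduce published control-rate values exactly.

### Per-position denominators

Whether per-position efficiencies should be divided by all clean reads or
only by reads covering that position is not determinable from the source
material; `per_position_matrix()` divides by clean reads, and partial reads
are pushed into `not_covering` so they cannot silently deflate a site's
numerator while staying in its denominator.

### Rounding conventions

Percentages are reported to one decimal, round-half-up — with one
deliberate exception: `clone_efficiency()` truncates, because published
clone-level figures (7/12 = 58.3, 3/11 = 27.2, 2/5 = 40.0, 21/41 = 51.2)
are uniformly consistent with truncation and 3/11 is not consistent with
rounding. Genome-level percentages round (14,106/14,623 = 96.46 → 96.5).

## The simulator

`generate_cds_set()` emits frame-valid CDSs (ATG start, single terminal
stop, no internal stops) with knockout sites planted at recorded codon and
protospacer positions by locking the codon and its PAM bases and
resampling any background codon the locks corrupt. Incidental sites arise
naturally and are expected; tests therefore compare the scanner against
full enumeration, not against the truth table alone.

`simulate_sample_reads()` emits amplicon reads: per targeted C an
independent conversion with its stated probability, at most one contiguous
indel per read (lengths 1–10 by default), uniform substitution error, and
constant Q35 qualities with an optional linear 3'-degradation mode to
exercise trimming. Default depth is 100,000 reads per sample, the order of
magnitude of a typical targeted amplicon run; tests scale down.

What the simulator deliberately does **not** model: linkage between
editing events (edits are independent across positions and reads — the
"more simultaneous substitutions, fewer reads" pattern emerges from
independence alone), PCR duplicates and chimeras, learned error profiles,
multi-indel reads, and barcode sequencing errors (exact-match
demultiplexing would misbin them). Passing tests therefore demonstrate
correctness of the bookkeeping and estimators under these idealized
conditions, not robustness to every artifact of real libraries.

## Problem sizes and numerical checks

The test suite runs the scanner-vs-oracle comparison on 100 random 300-nt
CDSs (plus reverse-complement fixtures and both window modes), recovers
planted parameters at depth 10,000 (efficiency 0.20, per-position rate
0.25 at C5, indel fraction 0.05, each within three binomial standard
errors), verifies estimator unbiasedness over 200 replicate simulations at
depth 400, and checks the multiplex histogram against its Binomial law by
a χ² goodness-of-fit test at α = 0.01. Determinism is asserted byte-for-byte:
identical seeds give identical FASTA/FASTQ/TSV output, and pipeline re-runs
reproduce identical manifest checksums.

## Known limitations

* Genome-scale totals depend on the exact CDS release scanned; the scan on
  a different annotation will count differently. No published genome-wide
  totals are asserted by the tests.
* No off-target scoring, gRNA activity prediction, PAM variants beyond
  NGG, or intron-aware scanning.
* Amplicon quantification assumes one known reference per sample; this is
  not a read mapper.

## A worked example

```{r example}
sim <- generate_cds_set(n_genes = 3, length_codons = c(80, 120),
                        planted = data.frame(gene = 1, codon = "CAG",
                                             proto_pos = 5),
                        seed = 42)
sites <- scan_cds_set(sim$cds)
summarize_genome(sites, sim$cds$gene_id)

amp <- local({set.seed(1); make_amplicon(random_spacer(c_at = c(5, 7)))})
reads <- simulate_sample_reads(amp$reference,
                               site_edits(amp$site, c("5" = 0.25, "7" = 0.1)),
                               depth = 2000, subst_error = 0.001, seed = 2)
stats <- quantify_sample(reads$reads, amp$reference, amp$site)
compute_efficiency(stats)
window_profile(per_position_matrix(list(stats)))
```
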