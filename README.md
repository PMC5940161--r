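# bestop

Design and quantification of cytidine base-editing stop-codon knockouts.

BE3-style base editors (cytidine deaminase + Cas9 nickase + uracil-glycosylase
inhibitor) convert C:G base pairs to T:A inside an editing window of the 20-nt
protospacer, without double-strand breaks. A single such edit can turn one of
four codons into a premature stop codon:

```
CAA --C1>T--> TAA      CAG --C1>T--> TAG      CGA --C1>T--> TGA
TGG --G2>A--> TAG      TGG --G3>A--> TGA      TGG --G2,3>A--> TAA   (antisense C>T)
```

`bestop` is for people using base editors as knockout reagents: it answers
*where can I install a premature stop in this gene set* (design), and *what
did my editor actually do* (quantification from targeted amplicon deep
sequencing). Protospacer positions are numbered 1–20 from the PAM-distal
end, so C5 means a cytosine at position 5.

**Design.** `find_protospacers()` enumerates every NGG-PAM 20-mer on both
strands; `stop_codon_conversions()` enumerates the edit routes of a codon;
`scan_cds()` combines them over in-frame codons of a CDS, keeping sites
whose required edits fall inside the editing window (default C1–C13;
canonical C4–C8 selectable); `summarize_genome()` reports per-gene site
counts, targetability percentage, and positional distributions.

**Quantification.** `trim_reads()` (LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15
MINLEN:50 semantics), `demultiplex()` (exact paired-barcode match),
`classify_reads()`/`quantify_sample()` (reads aligned to the amplicon
reference with affine gaps — match +2, mismatch −3, gap open 5, extend 2 —
and called edited iff a targeted C shows the C→T conversion),
`per_position_matrix()`, `window_profile()` (designed-vs-substituted gRNA
ratio per position), `multiplex_histogram()` (distinct substituted
positions per molecule in pooled-guide runs), `indel_frequency()` (internal
alignment gaps), `clone_efficiency()` (Sanger clone counts).

**Simulation.** `generate_cds_set()` plants knockout sites at known codon
and protospacer positions in frame-valid CDSs; `simulate_sample_reads()` /
`simulate_panel()` emit barcoded amplicon reads with chosen per-position
editing probabilities, indel rates, and sequencing error — every stage is
testable with known ground truth, no downloads required.

File-level runs (`run_scan`, `run_quant`, `run_multiplex`, `run_simulate`)
write TSV tables, BED, figures with TSV twins, and a JSON manifest with
content checksums; a thin CLI lives at `inst/cli/bestop.R`.

## Worked example

```r
library(bestop)

# design: 3 synthetic genes, one CAG site planted with its C at position 5
sim   <- generate_cds_set(n_genes = 3, length_codons = c(80, 120),
                          planted = data.frame(gene = 1, codon = "CAG",
                                               proto_pos = 5),
                          seed = 42)
sites <- scan_cds_set(sim$cds)
summarize_genome(sites, sim$cds$gene_id)
#> Genome-wide knockout-site summary
#>   targetable sites : 9
#>   targetable genes : 3 of 3 (100.0%)
#>   median sites per targetable gene: 3
```

Nine unique (gene, codon, protospacer) sites exist across the three genes —
the planted one plus incidental sites from the random background; a TGG
codon reachable by one protospacer shows up as three rows (stops TAG, TGA,
TAA) but counts once.

```r
# quantification: one guide with Cs at positions 5 and 7,
# edited in 25% / 10% of molecules
amp   <- local({set.seed(1); make_amplicon(random_spacer(c_at = c(5, 7)))})
reads <- simulate_sample_reads(amp$reference,
                               site_edits(amp$site, c("5" = 0.25, "7" = 0.1)),
                               depth = 2000, subst_error = 0.001, seed = 2)
stats <- quantify_sample(reads$reads, amp$reference, amp$site)
compute_efficiency(stats)
#> [1] 32.4
clone_efficiency(7, 12)
#> [1] 58.3
```

32.4% of clean reads carry at least one targeted C→T conversion, matching
1 − (1 − 0.25)(1 − 0.1) = 32.5% up to sampling noise; the clone-level
helper reproduces conventional clone-count reporting (7 of 12 → 58.3%).

See `vignettes/bestop-methods.Rmd` for the model, parameter defaults, and
the design decisions behind the window rule, thresholds, and rounding.

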