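---
title: "Chromosome-scale phasing from strand-specific single-cell long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-scale phasing from strand-specific single-cell long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandhap)
```

# The measurement model

Strand-seq style libraries sequence only the parental *template* strand of
each chromosome in a single cell: after BrdU labelling and removal of the
nascent strand, every read from a given homolog maps to one fixed strand of
the reference. Per cell and chromosome there are three inheritance
patterns — WW (both homologs' templates on the Watson/minus strand), CC
(both on Crick/plus) and WC (one each). WC chromosomes are the phasing
substrate: there, strand identity *is* haplotype identity, so a single cell
separates the two homologs across the entire chromosome, regardless of the
distance between heterozygous sites.

`strandhap` implements the full computational path from multiplexed,
barcoded long reads to chromosome-scale haplotypes:

1. **demux** — assign reads to cells by combinatorial barcodes
   (Levenshtein distance), orient them to the template strand, trim
   linkers, reject chimeras;
2. **alnproc** — filter alignments, mark PCR duplicates with edge
   tolerance, annotate reads with a haplotype via phased hetSNPs;
3. **cellqc** — per-chromosome strand counts, the background-noise metric
   and library retention rules;
4. **inversion** — a directional composite across cells, scanned for
   strand-flipped intervals;
5. **phasing** — two-round haplotype reconstruction with consensus SNP
   calling;
6. **svphase** — genotyping and phasing of deletions/insertions
   (≥ 50 bp) from haplotype read sets;
7. **asmcluster** — strand-signal clustering of de novo assembly contigs
   into chromosome-scale, orientation-resolved groups.

A truth-annotated simulator (`simulate_diploid_genome()`,
`simulate_strand_run()`, `emit_multiplexed_fastq()`) generates every input
the pipeline consumes, so each stage is testable without external data.

# Key quantities and thresholds

* **Crick fraction** $P_c = N_\mathrm{crick}/(N_\mathrm{crick} +
  N_\mathrm{watson})$ per (cell, chromosome). Strand states are called as
  CC when $P_c > 0.8$, WW when $P_c < 0.2$, WC when
  $0.35 \le P_c \le 0.65$. The CC/WW cutoffs are the ones the composite
  construction uses; the WC band is a package choice (no published
  threshold exists) — symmetric about 0.5 and well clear of the CC/WW
  cutoffs, configurable in `call_strand_state()`. Chromosomes with fewer
  than 50 unique reads (configurable) stay `unknown` and are excluded from
  phasing; at lower counts a binomial fluctuation alone can cross the band
  boundaries.
* **Background** per chromosome:
  $\min(N_\mathrm{crick}, N_\mathrm{watson}) / (N_\mathrm{crick} +
  N_\mathrm{watson})$, and per cell: the mean of the four smallest
  autosomal values. It estimates the fraction of reads on the wrong strand
  (incomplete nascent-strand removal). Libraries are retained with
  ≥ 80,000 unique reads and background strictly below 5% (the mouse
  preset lowers the read floor to 70,000). Note the four-minimum rule
  presumes enough single-strand (WW/CC) autosomes; on genomes with very
  few chromosomes WC chromosomes (background ≈ 0.5) would contaminate the
  minima, so simulated QC runs here use 12 chromosomes.
* **Duplicates**: same cell, chromosome and strand, with both start and
  end differing by *less than* 20 bp; groups are the transitive closure of
  that relation (chained near-identical molecules collapse), computed with
  a sorted sweep + union-find in O(n log n). The kept representative is
  the highest-MAPQ read (ties: longest, then leftmost) — unspecified
  upstream, chosen so the best evidence survives.
* **Haplotype annotation**: a read is tagged HP1/HP2 only when *all* of
  its informative alleles at phased hetSNPs agree; mixed or empty evidence
  leaves it untagged. Base quality is not consulted (no threshold is
  defined for it in this protocol); the ≥ 2-read consensus rule below
  absorbs individual miscalls.

# Two-round haplotype reconstruction

**Anchors.** Pseudobulk allele observations (duplicates included — they
are independent observations of the same molecule's bases and raise
per-site depth at 0.2–0.3× per-cell coverage) are piled up per site; a
site becomes an anchor hetSNP when depth ≥ 10, the minor-allele fraction
lies in [0.25, 0.75], and the minor count is incompatible with a 5% error
rate (binomial tail < 0.01). Sites in a high-coverage blacklist — 10-kb
bins whose read count exceeds mean + 5 SD, a proxy for collapsed repeats —
are excluded. The anchor stage stands in for an external deep-learning
caller; an externally produced VCF can be substituted at the same
interface.

**Orientation clustering.** For each chromosome, every WC cell's Crick and
Watson reads get a majority-vote consensus allele per anchor. For two
cells $i, j$ the score
$\log_2\frac{\mathrm{agree}_{\parallel} + 1}{\mathrm{agree}_{\nparallel} + 1}$
(Crick–Crick + Watson–Watson matches vs the crossed matches; the
pseudocount 1 avoids division by zero without moving the sign) is positive
when the cells sequence the same haplotype on the same strand. Cells are
bipartitioned greedily in input order by weighted majority over
already-assigned cells — deterministic by construction. Cells whose
pairwise score signs agree with the bipartition less than 70% of the time,
or whose mean |score| is below 0.25 (no usable signal, e.g. a cell
misclassified as WC), are excluded. Before scoring, each WC cell is
restricted to its largest strand-consistent run of 1-Mb bins, so a
sister-chromatid exchange (SCE) inside the chromosome contributes only its
clean segment.

**Consensus calling.** HP1 pools Crick reads of cluster 1 with Watson
reads of cluster 2 (HP2 the reverse). Per site and haplotype the consensus
allele needs ≥ 2 supporting reads and ≥ 80% within-haplotype agreement;
a variant is emitted when both haplotypes pass and at least one differs
from the reference. The 2-read floor is the published support rule; the
80% agreement is this package's operationalisation of "stringent
filtering" — at the error rates involved (~1% per base) a true allele at
depth ≥ 2 essentially always clears it, while a lone miscall cannot.

**Round 2.** All reads of all cells (any strand state) are re-annotated
against the round-1 phased variants; unambiguously tagged reads form
enlarged haplotype read sets and consensus calling repeats. Because WW/CC
cells and ambiguous-orientation WC cells now contribute, round-2 recall is
never lower than round-1 on clean data, and phasing errors average out
over more cells.

**Inversion corrections.** Within putative homozygous inversions both
haplotypes' reads map flipped, so phases inferred there are
systematically inverted: variant phases are swapped. Within heterozygous
inversions only one haplotype flips and strand no longer separates
haplotypes cleanly: variants there are excluded. The same rule applies to
SV phases (`switch_phase_in_inversions()`), uniformly — the source
protocol states the switch for SVs and the exclusion for SNPs; applying
the exclusion to SVs as well is the conservative uniform choice, and such
records are dropped rather than silently re-labelled.

**Evaluation.** The Hamming error rate is computed per chromosome as the
mismatch fraction against truth minimized over the two global labelings
(chromosome-scale phasing has exactly this one degree of freedom per
chromosome), then aggregated across chromosomes weighted by compared
counts; per-chromosome values are also returned since the aggregation
convention is not standardised.

# Inversion detection

Cells with CC ($P_c > 0.8$) or WW ($P_c < 0.2$) chromosomes form a
composite: WW cells' read directions are switched, chromosomes are binned
at 1 Mb, and each cell keeps only maximal runs of bins whose Crick
fraction matches the expected profile within 0.1 (bins need ≥ 10 reads).
The expected profile is the per-bin median over cells grouped by profile
similarity (average-linkage clustering with a fixed height cutoff);
singleton groups are held to the global median instead — a profile of one
cell cannot justify itself, which is exactly the SCE case that must be
excluded. Reads overlapping these pure regions merge into the composite,
where inversions appear as runs of Watson reads.

Candidates are seeded as chains of Watson reads with midpoint gaps
≤ 5 kb. A second pass re-joins adjacent Watson-*enriched* fragments
($P_w \ge 0.3$) across gaps up to 50 kb and re-counts the merged span:
at realistic composite depths (below one Watson read per kb) a single
100-kb event is otherwise fragmented by coverage dips, while sparse
background Watson noise ($P_w \approx$ background) never participates in
merging and so cannot chain across a clean region. Classification uses
composite reads counted by midpoint: < 20 reads → filtered;
$P_w > 0.9$ → homozygous; $0.4 < P_w < 0.6$ → heterozygous;
$P_w < 0.1$ → filtered; the remaining bands stay *ungenotyped* — the gaps
between classes are preserved deliberately rather than smoothed, because
intermediate Watson fractions are exactly the signature of partial
artefacts.

# SV genotyping and phasing

Candidate deletions/insertions come from CIGAR operations ≥ 50 bp, merged
across reads when breakpoints lie within 500 bp and lengths agree within
25% (the same signature tolerance is used when matching reads to a
candidate). Blacklist rules remove: SVs within 1 kb of another SV (both
members), SVs longer than 10 kb, SVs in regions below 10× or above 80×
coverage *in every provided track*, and SVs overlapping annotated
difficult or tandem regions longer than 200 bp; missing inputs skip the
corresponding rule with a warning rather than failing. Genotyping counts,
per haplotype read set, reads carrying the signature (support) and reads
spanning the locus with 50 bp flanks without it (oppose): support on both
haplotypes (≥ 2 reads each) is homozygous; support on one plus opposition
on the other is heterozygous on the supporting haplotype; anything else is
unresolved. Distances to the nearest phased hetSNP are reported bucketed
at ≤ 2 kb / 2–10 kb / > 10 kb — the long-distance bucket is where
strand-based phasing is the only option, since read-length linkage cannot
reach the nearest informative site.

# Contig clustering for assembly phasing

Reads are assigned to assembly contigs (≥ 100 kb; shorter contigs carry
too little strand signal) and each (contig, cell) entry is
$(C - W)/(C + W)$. Chromosome grouping clusters the *absolute* matrix —
|value| is ~1 for WW/CC cells and ~0 for WC cells regardless of contig
orientation, so contigs of one chromosome share a cell-pattern fingerprint
— with complete-linkage agglomerative clustering on Euclidean distances
(`stats::hclust` + `cutree`; 30 clusters for a human-scale assembly,
simulations use the true chromosome count). Orientation is resolved inside
each cluster on the *signed* rows: each contig joins the sub-cluster given
by the sign of its inner product with the cluster's strongest row, so
anti-correlated (reverse-oriented) contigs separate and a uniformly
oriented cluster stays whole. One sub-cluster is reverse-complemented and
all contigs are concatenated with 1-kb N gaps; the coordinate map supports
exact lifting of cluster-based variant calls back to contig and reference
coordinates, with allele complementing when the net orientation is
reverse.

# The simulator: what it emulates and what it does not

The generator produces a random diploid genome with hetSNPs (default rate
10⁻³/bp), DEL/INS SVs of 50–300 bp, and HOM/HET inversions at requested
positions; per cell it draws an inheritance pattern per chromosome
(WW/CC/WC at 1/4, 1/4, 1/2 — each homolog independent), places SCE
breakpoints (Poisson, default 0.2 expected per chromosome — no empirical
per-cell rate is published, so this default is explicitly arbitrary and
documented as such), flips strands within carried inversions, emits a
`background_rate` fraction of reads on the wrong strand, and observes
alleles at polymorphic sites with substitution errors at
`base_error_rate`. Read lengths are lognormal with mean 2794 bp and SD
1500 bp, matching the reported mean/N50 scale of this library type.
Reads are emitted directly in aligned representation (coordinates, CIGAR,
observed alleles), with truth labels carried in read names; full sequences
are materialised only for the FASTQ/demultiplexing path.

Deliberately not modelled: homopolymer-biased Nanopore error profiles
(substitution-only by default), chimera formation (tested with constructed
reads), mapping ambiguity in repeats, GC bias, aneuploidy and polyploid
genomes. Passing tests therefore demonstrate the *logic* of every stage —
formulas, thresholds, orientation handling, corrections, coordinate
arithmetic — under controlled noise, not robustness to real-world mapping
artefacts; on real data the MAPQ ≥ 30 filter and the coverage blacklist
carry that burden.

# Numerical and degenerate-input choices

* Fixed seeds everywhere; a fixed configuration reproduces byte-identical
  FASTQ output. All internal RNG use restores the caller's RNG state.
* Barcode matching uses semi-global (infix) Levenshtein alignment
  (Rcpp kernels; `utils::adist` is global-only). Ties between *different*
  barcodes at the minimal distance make a read ambiguous — single-cell
  identity must be unambiguous; a forward/reverse tie of one barcode
  resolves to forward. Windows are `min(200, len/2)` bp.
* Zero-read chromosomes yield NA fractions and are flagged, never silently
  0; `cell_background()` refuses cells with fewer than 4 usable autosomes;
  empty barcode sets, missing inheritance patterns, overlapping requested
  inversions and `n_clusters` larger than the contig count are errors.
* Consensus ties (equal top allele counts) produce no call at that site
  for that haplotype.
* In `mark_duplicates`, the strict `< 20 bp` inequality is applied on both
  edges exactly as printed; coordinates are alignment reference
  coordinates.

# Problem sizes

Module tests run on 0.2–4 Mb genomes with 4–50 cells; the end-to-end
phasing checks use 2 chromosomes × 2 Mb, hetSNP rate 10⁻³, 40 cells at
~900 reads each (≈ 25× pseudobulk depth, matching the real regime of a
few hundred 0.2–0.3× cells); inversion recovery uses 20 events of 100 kb
on 4 × 2 Mb chromosomes with 50 cells. These sizes were chosen so the
complete suite exercises every code path at depths where the statistical
thresholds are meaningful.

# Known limitations

* The anchor and consensus callers handle SNPs only; short indels are out
  of scope (SVs ≥ 50 bp are handled by the dedicated path).
* Heterozygous inversions remove their interior variants from the phased
  set; no attempt is made to phase across them.
* The SCE guard keeps only each cell-chromosome's largest consistent
  segment rather than amending the switch.
* Aneuploidy is not modelled or corrected; contigs placed in a wrong
  cluster are not rescued (no corrective step is defined upstream).
* Haplotype labels are per-chromosome arbitrary (one phase set per
  chromosome); joining chromosomes into a genome-wide parental assignment
  requires external information (e.g. pedigree).
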