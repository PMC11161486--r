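---
title: "Methods: PIF/Harbinger insertion analytics with piftools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PIF/Harbinger insertion analytics with piftools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piftools)
```

# Scope

`piftools` is a desk-scale, fully tested re-implementation of the analytics
used to characterize an active *PIF/Harbinger* DNA transposon family in
melon: calling non-reference insertion loci from transposon-display
sequencing (TED-seq) alignments, describing the target-site and chromatin
context of those insertions, annotating full-length and degenerate element
copies, comparing insertion landscapes across germplasm panels, and mapping
a causal locus in bulked segregants. Read mapping, peak calling, RNA-seq
and bisulfite processing are deliberately out of scope: every module's
contract starts at standard file formats (SAM, BED, GFF3, bedGraph, VCF,
TSV).

Because real TED-seq, DAP-seq and resequencing libraries are not
desk-scale inputs, the
package ships a first-class synthetic-data module that generates every
input the pipeline consumes, with truth tables, so that each analytical
claim is validated by construction rather than by fixture.

All internal coordinates are 0-based half-open; conversion happens only at
format boundaries (SAM, GFF3 and VCF are 1-based on disk). An insertion
breakpoint is the 0-based genomic position of the junction: the element
inserts between `breakpoint - 1` and `breakpoint`.

# Insertion calling from junction evidence

A TE insertion that is absent from the reference genome leaves two
signatures in aligned short reads:

* **soft-clipped reads** whose terminal clipped bases reproduce a terminus
  of the TE consensus. A leading clip places the breakpoint at the
  alignment start, a trailing clip at the alignment end, so error-free
  junction reads agree on the breakpoint to the base.
* **discordant pairs** with one mate on the genome and the other on the TE
  consensus (carried as an extra contig). These localize the insertion
  only to a window of one insert size downstream of the genomic mate, so
  they corroborate but never define a breakpoint.

Evidence is clustered per contig by single linkage within `cluster_window`
(default 50 bp, wide enough to absorb alignment jitter, narrow enough to
separate neighboring loci); the cluster breakpoint is the modal soft-clip
breakpoint with ties resolved to the smallest coordinate, which makes the
caller invariant to read order. A candidate becomes a call when, in at
least one replicate, it has at least `min_softclip` unique soft-clip reads
**and** `min_discordant` unique discordant reads (defaults 3 and 3). The
rule is deliberately the most conservative conjunction of the two
evidence classes; both floors and the replicate policy (`any`/`all`) are
parameters, so laxer conventions (e.g. a summed-evidence floor) are one
flag away.

Calls within `match_window` (default 50 bp) of a known reference insertion
are `common`; others are `sample_specific`, and a sample-specific call
with parental-line evidence (default 3 or more reads of either class) is
reclassified `ancestral_reclassified` — it predates the sample rather than
being a new transposition.

Soft-clip matching accepts a clip when its mismatch fraction against the
best of the four TE terminus candidates (either end, either orientation)
is at most `max_clip_mismatch_frac` (default 0.1: a 150-bp read yields
clips of 25+ bases, where 10% tolerates sequencing error without admitting
random matches; `min_clip_len` defaults to 20).

# Target-site and chromatin context

*PIF/Harbinger* elements duplicate a short target site (TSD, canonically
`TAA`) on insertion. The site window is the 3-bp TSD starting at the
breakpoint plus 3 bp of flank on each side — 9 nt in total, six of them
flanking the duplication, matching the canonical width of published
PIF-family insertion-site consensi; both `tsd_len` and `flank` are
parameters. Windows are tallied into a position frequency matrix, and each
column maps to the IUPAC code of the bases reaching frequency
`min_freq = 0.25`; a column where no base qualifies reports `N`. On sites
drawn from the package's default PWM the recovered consensus is the
PIF-type string `MWYTWARWK`.

Breakpoints are assigned a single genomic feature class with priority
`exon > intron > promoter > intergenic`. The promoter is 2000 bp upstream
of the strand-aware gene start; there is no universal promoter length
for cucurbit genomes, so 2000 bp is a documented, flag-exposed
convention. Class proportions between groups are compared with a
pooled-variance two-proportion Z-test, applied only when both groups
have a non-zero count; a class absent from either group is reported
not-applicable rather than tested.

Chromatin signal (e.g. H3K9ac or ATAC coverage as bedGraph) is profiled in
100-bp bins across ±3 kb of each site: 60 bins, each the length-weighted
mean of the piecewise-constant track, averaged over sites; bins truncated
by contig ends are missing, not zero. Methylation profiles aggregate
per-cytosine counts of one context (CG/CHG/CHH) as
`sum(meth)/sum(total)` per bin with a coverage floor. Group profiles
(common vs new vs random sites) are compared with a two-sided Wilcoxon
rank-sum test over the 60 per-bin values; exact enumeration is used for
8 or fewer bins without ties, otherwise the normal approximation with tie
and continuity correction. Random control sites are genome-wide uniform,
not feature-matched — a documented limitation, since insertion sites are
gene-biased while controls are not.

# Element annotation with TIR and double-peak support

The element's terminal inverted repeat (`GGGCCCGTTTG`) is searched
genome-wide allowing up to 2 mismatches (Hamming distance; the forward
pattern on the + strand, its reverse complement on the −). Matches pair
into candidate elements by walking the − strand matches left to right and
pairing each with the nearest upstream unused + match whose outer span is
200–20000 bp. This innermost-first greedy rule is deterministic, cannot
nest pairs, and at desk scale matches how intact elements actually sit in
a genome; the length bounds span the known *PIF/Harbinger* size range,
since individual family members vary widely.

A DNA-affinity (DAP-seq) peak supports a TIR when a summit lies within
`summit_window` (default 500 bp, a typical DAP-seq peak half-width; the
tolerance is configuration, not an assumption about the binding data).
A paired-TIR candidate with both TIRs supported ("double peak") is
`full_length`; one-sided support, or a lone TIR with a nearby peak, is
`degenerate`; a paired candidate with no support is reported
`unsupported` rather than silently upgraded; a peak with no TIR-like
sequence near its summit is a `solo_peak`. Summit-centered windows (±15 bp)
feed the same PFM/consensus machinery used for target sites.

# Population presence/absence analysis

Insertion genotypes across accessions are coded exactly as the germplasm
convention dictates: at a reference-class locus the insertion is part of
the assembly, so presence is `0/0` and its deletion `1/1`; at a
non-reference locus absence is `0/0` and the insertion `1/1`. The VCF
carries the class in `INFO/CLASS`, and decode∘encode is bit-exact.
Heterozygous insertion states are out of scope; any other genotype is an
error.

Distances are Euclidean on the raw carrier bits — the square root of the
Hamming count for binary rows. Distances could equally be computed on the
class-polarized genotype codes; since the two codings differ only by
complementing reference-class columns, and complementing a binary column
leaves Euclidean distance unchanged, the choice is immaterial to the
tree. Carrier bits are the default.

Neighbor joining is implemented in-package because the package pins
platform-independent determinism that generic implementations do not
guarantee: the Q-criterion minimum resolves ties to the smallest (i, j)
pair in current matrix order, and a negative branch length is clamped to
zero with the deficit moved to its sister edge. The algorithm is exact on
additive distances (verified against random trees up to 16 taxa at 1e-9,
with `ape`/`phangorn` as independent oracles); trees are emitted unrooted.

A non-reference locus carried by exactly one accession is a
**new** insertion (recent transposition). Per-accession new-insertion
burden is compared between groups (wild vs cultivated) with the shared
Wilcoxon implementation.

# Bulk-segregant delta SNP-index mapping

For each SNP with per-bulk depth at least `min_depth` (default 10), the
SNP-index is the alternate-allele read fraction and

\[
\Delta \text{SNP-index} \;=\; \text{SNP-index}_{\text{mutant}} -
\text{SNP-index}_{\text{WT}},
\]

in exactly that order. Under a single-locus recessive model with F2
bulks, the mutant (homozygous) bulk's expected index at the causal locus
is 1 and the phenotypically wild-type bulk's (1 AA : 2 Aa) is 1/3, so the
expected Δ peaks at 2/3 and decays toward 0 with recombination distance.
Windows of 1 Mb — the standard QTL-seq reporting scale — slide at 100-kb
steps; the 10× overlap resolves the peak below window width and the step
is a flag. A window with fewer than `min_snps = 5` informative SNPs is
undefined — never zero. Candidate regions are maximal runs of defined
windows with mean Δ at or above `threshold = 0.5`, a default chosen well
above unlinked noise yet below the causal-locus expectation of 2/3;
tighter or looser association calls are a flag away.

# The synthetic-data generators

The generators are pure functions of a `sim_config()` plus seed —
byte-identical on repeated calls — and their defaults mirror the melon
system they emulate: 12 chromosomes, 150-bp reads, TIR `GGGCCCGTTTG`,
282 reference + 50 new insertion loci with ~34 evidence reads per locus
over two replicates, an 81 wild / 480 cultivated accession panel with
182 reference and 894 non-reference loci whose singleton rates
(2.0/accession wild, 0.8 cultivated) give ~560 singleton loci in
expectation, and a recessive F2 design with 10 plants per bulk. Where
the system fixes no value, a field-realistic choice is made
once and documented here: 200-kb contigs (melon chromosomes are not a
desk-scale input; what matters to every test is insertions-per-base, not
chromosome length), GC 0.38 (cucurbit-like), base error 0.001
(Illumina-like substitutions only), a 430-bp element (the size of the
best-studied family member), Haldane mapping at 4 cM/Mb, and a target-site
PWM placing probability 0.9 on each consensus column's base set.

What the generators emulate: junction reads whose clip boundaries sit
exactly on truth breakpoints, discordant mates on the TE contig,
PWM-biased insertion sites, additive chromatin enrichment and CHG/CHH
hypomethylation confined to ±3 kb of new sites, two-group carrier-
frequency structure with per-accession singletons, and Mendelian F2 pools
sampled through a genetic map. What they do not emulate: indel and
quality-score error models, PCR duplicates, repetitive-sequence
mismapping, linkage disequilibrium between BSA markers (each SNP's
marginal distribution is correct but inter-SNP correlation is not
modeled), and heterozygous insertion genotypes. Passing tests therefore
demonstrate correctness of the analytics under clean, well-specified
signal structure — not robustness to every artifact of real libraries.

Two generator details worth noting. Non-singleton population loci are
guaranteed at least two carriers so that the singleton classification
recovers the generated truth exactly rather than probabilistically. The
BSA simulator realizes pool allele frequencies from individual simulated
plants (finite-bulk overdispersion) by default; `pool_model = "expected"`
switches to the zero-overdispersion limit used in closed-form checks.

# Numerical choices and degenerate inputs

* Breakpoint ties in clustering resolve to the smallest coordinate; NJ
  Q-ties to the smallest index pair — both for platform determinism.
* A window/bin with no data is `NA` and is excluded from tests; it is
  never silently zero.
* The two-proportion test returns not-applicable (`NA`) on zero cells
  instead of ±Inf statistics.
* Zero-coverage cytosines, reads without CIGAR, unpaired or
  mate-unmapped reads are skipped with counts reported, not errors.
* Profile extraction treats bedGraph gaps as signal 0 (coverage
  semantics) but contig-end truncation as missing.
* Newick branch lengths are serialized at 17 significant digits so
  tree round trips preserve additive exactness.

# Problem sizes used by the test suite

The validation suite runs the full stack at reduced scale, chosen so the
whole suite completes in minutes while every statistical check retains
power: caller exactness and precision/recall on 50 insertions over
12 × 100-kb contigs; motif recovery from 200 sites; TIR search against a
brute-force scan of 100 kb; NJ exactness to 16 taxa; population round
trips at 50 × 200 with 50 seeded replicates of a 20-accession two-group
panel; BSA recovery over 20 seeded runs at depth 100 with 500 SNPs on a
20-Mb contig; and 200 null replicates for type-I control of the profile
comparison. The acceptance script simulates 1000 F2 populations of 200
plants. Full-scale runs (the `sim_config()` defaults) remain
single-command reproducible via the bundled CLI.

# Known limitations

* The caller does not genotype zygosity, assemble inserted sequence, or
  detect excisions.
* Random profile controls are not feature-matched.
* TIR pairing is greedy and will not resolve nested elements.
* The permutation behaviour of the Z-test is approximated by the pooled
  normal formula; for small counts the test is skipped by the zero-cell
  rule rather than replaced by an exact test.
* SAM support covers the text format with mandatory `@SQ` headers (the
  formats the simulator emits and desk-scale fixtures need); BAM/CRAM and
  indexed access are out of scope.

# A compact end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_contigs = 4, contig_length = 60000,
                  n_genes = 40, n_reference_insertions = 6,
                  n_new_insertions = 6, junction_reads = 4,
                  discordant_pairs = 4, background_pairs = 50)
g <- simulate_genome(cfg)
te <- simulate_te(cfg)
sites <- draw_insertion_sites(g$genome, 12, cfg$site_pwm, seed = 2)
truth <- transform(sites, category = rep(c("reference", "new"), each = 6))
reps <- simulate_junction_alignments(g$genome, te, truth, cfg)
ref_bed <- with(subset(truth, category == "reference"),
                data.frame(contig = contig, start = breakpoint,
                           end = breakpoint + 1))
calls <- call_insertions(reps, te, reference_insertions = ref_bed)
table(calls$category)
pfm_consensus(build_pfm(extract_site_windows(g$genome, calls)))
```
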