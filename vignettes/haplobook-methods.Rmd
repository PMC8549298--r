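---
title: "haplobook: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplobook: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

haplobook reconstructs the two haplotypes of a diploid genome de novo from
long reads (PacBio HiFi, PacBio CLR, Oxford Nanopore). This vignette explains
the method, its assumptions, the tunable parameters, the numerical choices
made where the design was genuinely open, and what the bundled simulator does
and does not emulate.

## The divide-and-conquer model

The central difficulty of haplotype-aware assembly is that the two haplotypes
of a diploid genome are nearly identical (typically around 0.1-1%
heterozygosity), while long reads carry sequencing error rates between under
1% (HiFi) and 10-15% (CLR/ONT). A consensus assembler collapses the
haplotypes; a naive haplotype-splitting approach drowns in errors.

haplobook works in two stages:

**Divide.** Reads are grouped into local clusters: reads are sorted by length
descending, the longest unprocessed read becomes a seed, its cluster is the
set of unprocessed reads having a retained overlap with it, and all members
are removed from the pool. Clusters therefore partition the read set, and the
number of clusters grows roughly linearly with genome size. Each cluster is a
local phasing problem: the cluster's reads are assembled into an *ad hoc
reference* (overlap graph, transitive reduction, longest path, overlap-aware
concatenation, two rounds of pileup polishing), which exists only to give the
cluster a local coordinate system. Candidate heterozygous SNPs are called
from the pileup of cluster reads against this reference, an allele matrix
(reads x sites over {0, 1, missing} with phred-scaled weights) is built, and
the *weighted minimum error correction* (wMEC) problem is solved exactly: the
bipartition of the reads minimising the total weight of entries that must be
flipped to make each side consistent with a single haplotype. Each side,
optionally error-corrected by group-local consensus projection, is assembled
into a *super read* — a long, haplotype-specific, near error-free local
sequence.

**Conquer.** The (far fewer) super reads are assembled through a second,
stricter overlap graph. Because super reads are haplotype specific, this
graph decomposes essentially into two haplotype components connected by a few
spurious cross-haplotype edges; an optional SNP-based edge filter removes
those by genotyping each overlap region with the groups' reads. After
transitive reduction and tip removal, every maximal simple path is merged
into one haplotig.

### Assumptions

* The genome is diploid; wMEC bipartitions reads into exactly two groups.
* Substitution heterozygosity carries the phasing signal; indel variants are
  not used as phasing markers.
* Reads are long enough to bridge neighbouring heterozygous sites; at 1%
  heterozygosity and 10 kb reads each read covers ~100 sites.
* Coverage suffices for pileup SNP calling (at least ~10x combined over a
  site; see below).

## The wMEC solver

`solve_wmec()` is an exact column-sweep dynamic program. Sites are processed
left to right; the state space of a column is the set of bipartitions (as
bitmasks) of its *active* reads — every read whose entry span covers the
column, so that each read is one decision variable end-to-end. The cost of a
column under a bipartition is, for each side, the cheaper of the two allele
assignments (summed weights of disagreeing entries; both sides may choose the
same allele, which handles homozygous-looking columns). Transitions between
consecutive columns force agreement on shared reads via projection onto the
intersection of the active sets. The runtime is linear in the number of
variants and exponential in the per-column coverage, which is why coverage is
capped.

Numerical/design choices:

* **Coverage cap** (`max_phasing_coverage`, default 20): columns above the
  cap are downsampled by truncating the shortest-spanning reads from the
  offending column onwards (keeping each read's active span contiguous —
  otherwise a read would decompose into independent fragments and the DP
  would solve a relaxation rather than the exact problem). Ties are broken
  by a ranking drawn once per matrix from `rng_seed`. Reads removed from the
  DP are assigned afterwards to the side whose inferred column alleles they
  disagree with least.
* **Label canonicalisation**: H1 is the group containing the
  lexicographically smallest assigned read id, so results are stable under
  side swaps.
* **Backtrace memory**: forward cost arrays are checkpointed (every 16
  columns when the full set would exceed ~80 MB) and recomputed per window
  during backtrace.

The solver is verified against exhaustive bipartition enumeration on random
instances (up to 10 reads x 8 sites, random weights and missingness) in the
test suite.

## SNP calling and the allele matrix

The het-site discovery role that a pair-HMM variant caller plays in
large-scale pipelines is filled here by a pileup caller with explicit
thresholds: a site is emitted iff base depth >= 10, both the reference and
the strongest alternative allele are seen >= 3 times, and the alternative
allele fraction lies in [0.2, 0.8]. Substitutions only. These thresholds are
deliberately conservative: at 40x combined coverage a true het site shows
roughly a 50:50 split and passes easily, while i.i.d. sequencing errors at
10% (split three ways per alternative base) essentially never reach count 3
with allele fraction >= 0.2. The cost of the conservatism is that clusters
with combined depth below ~10 cannot be phased; they produce a single
unphased super read (exactly as a homozygous cluster does).

A read's entry at a site is 0/1 if its aligned base equals the
reference/alternative allele; a third allele, a deletion, or no coverage is
missing. Weights are per-base phred qualities when the input was FASTQ, else
a constant 10.

## Overlap detection and alignment

All-vs-all overlapping uses a minimizer sketch (k = 15; window w = 10 for
HiFi, 5 for CLR/ONT), candidate pairs sharing >= 3 minimizers, colinear
chaining by longest increasing subsequence, and a banded edit-distance
alignment over the chained span. Two numerical choices matter:

* **The band follows the chain.** The band centre is the piecewise-linear
  diagonal through the chained anchors, with half-width
  `max(48, band_frac x largest inter-anchor gap)` (`band_frac` 0.05 HiFi,
  0.15 CLR/ONT). A fixed-fraction band around a single diagonal is quadratic
  in the span and, for long reads, either wastefully wide where anchors are
  dense or too narrow where indel drift accumulates; anchoring the band to
  the chain is both faster and tighter.
* **End extension.** When a chain's total overhang is at most 1000 bp the
  overlap coordinates are extended to the read ends before alignment, so
  proper dovetails carry exact end-to-end coordinates and concatenation along
  a path is base-exact on clean data. Internal (repeat-like) matches have
  large overhangs, are never extended, and are classified and removed by the
  standard overhang rule: internal iff
  `min(qs', ts) + min(qlen - qe', tlen - te) > min(1000, 0.8 x block_len)`
  (query coordinates flipped for `-` strand).

Filtering order: self-overlaps, exact duplicates, classification, then the
length (>= 1000 bp) and identity (>= 0.95 HiFi / 0.75 CLR+ONT) thresholds.
Containments are recorded; contained reads stay cluster members (they carry
phasing signal) but add no extension and are excluded from graph building.

Reverse-strand overlaps are resolved per component by a breadth-first
orientation assignment over the overlap adjacency; overlaps inconsistent with
the assignment (odd cycles) are dropped. The overlap graphs are held as
igraph objects; the longest path maximises assembled bases (first node length
plus summed edge extensions) by topological-order DP, after back-edges found
by depth-first search (rare cycles from repeats/palindromes) are deleted,
lowest extension first.

## Polishing and correction

Polishing is a full-pileup consensus (clusters are small enough that
windowing would buy nothing): reads are mapped to the working sequence by the
same seed-chain-align machinery in fitting mode, each column is replaced by
its quality-weighted majority symbol (deletion included), and an insertion is
applied when more than half of the reads covering a junction carry the same
inserted string. Two rounds by default. Group-local error correction (the
default for CLR/ONT) assembles each phase group's own longest-path backbone,
polishes it, and projects the polished consensus back onto each read's
aligned span, leaving unaligned read ends untouched; because the group is
haplotype-pure, true variation is not erased. Polishing the backbone before
projection matters: a single-pass consensus against the raw backbone leaves
the same residual errors in every corrected read, and correlated errors
cannot be removed by any later consensus step.

Super reads are polished against their group's *raw* reads and then trimmed
to the longest interval with read coverage >= 2 (discarded if shorter than
the minimum overlap length): single-read overhangs at super-read ends carry
most of the residual errors. The raw reads — not the corrected ones — are the
polishing evidence on purpose: consensus-projected corrected reads share
correlated errors and add no independent votes, whereas raw-read errors are
independent and vanish under a 20x majority. The same applies to the SNP
edge filter and the final contig polish, which genotype and vote with the
groups' raw reads. Super reads built from a single read skip trimming —
their profile is identically 1 and the read is legitimate output of a
singleton cluster.

## The super-read graph and final contigs

Super-read overlaps use stricter thresholds (>= 3000 bp; identity >= 0.98
for HiFi and >= 0.95 for CLR/ONT, configurable): super reads are long and
near error-free, so near-perfect identity is a necessary condition for an
edge. The noisy-platform default is looser because super-read *ends* — where
the inter-cluster overlaps live — retain 1.5-2% residual error after
consensus, which puts true same-haplotype overlaps at 0.96-0.98; at that
noise level identity cannot separate same- from cross-haplotype overlaps at
all, and the separation is left entirely to the SNP-based edge filter.
Three further choices:

* **Containment absorption is stricter than edge identity** (default 0.998).
  At 1% heterozygosity a super read's cross-haplotype counterpart is ~99%
  identical; absorbing into it (as the edge bar would allow) deletes a
  haplotype block. A super read is also absorbed when a single overlap covers
  >= 95% of its length at the absorption identity (*near-containment*): its
  possible extension is below the overlap scale, and the main source of such
  nodes — leftover clusters too thin for SNP calling, whose unphased super
  read duplicates already-assembled sequence — would otherwise emit redundant
  mixed-haplotype contigs. When the SNP edge filter is on, containment is
  additionally decided by *genotype*: an unphased contained super read is
  absorbed outright, and a phased one is absorbed iff genotyping the
  containment region with both groups' raw reads finds no heterozygous site
  — a noisy same-haplotype duplicate genotypes clean, a genuine
  cross-haplotype containment does not. Genotyping here means
  *group-consensus discordance*: a site is heterozygous iff each group's own
  pileup (at least three reads with 80% internal agreement) supports a
  different base. Within-group sequencing errors are independent and almost
  never produce an 80%-consistent wrong base, while true heterozygous sites
  split exactly along group lines; an allele-fraction caller on the pooled
  pileup, by contrast, hits error-pileup coincidences a few times per 10 kb
  at CLR error rates, which a `k = 0` filter cannot tolerate. The absorption
  runs once more on the merged contigs (with an overhang slack of
  `max_hang`): an unphasable leftover super read that straddles a junction
  of the merged chain is contained in no single super read but is contained
  in the contig, and would otherwise survive as a redundant mixed-haplotype
  contig.
* **The SNP-based edge filter** (optional, `snp_edge_filter`; recommended for
  small genomes and highly polymorphic regions) maps the corrected reads of
  both endpoint groups onto the concatenation of the two super reads along
  their overlap, genotypes the overlap region with the pileup caller, and
  removes the edge iff more than `snp_filter_k` heterozygous sites are found
  (default 0 — a perfect overlap is required). At 1% heterozygosity a
  cross-haplotype overlap of >= 3 kb contains ~30 het sites and is reliably
  removed, while a within-haplotype overlap genotypes clean.
* **Simplification order**: SNP edge filter, then transitive reduction, then
  tip removal, then simple-path merging. Tip removal must run on the reduced
  graph: a transitive skip edge makes a chain-end's predecessor look like a
  branch point, and the true chain end would be deleted as a "tip". (On a
  desk-scale diploid this ordering difference alone decided between ~67% and
  ~97% haplotype coverage.) Tips are dead-end branches of at most
  `tip_max_nodes` (default 2) nodes hanging off a branching node, removed
  iteratively on both the source and sink side. A dead-end branch is only a
  tip relative to its siblings: it is deleted when the branch point has a
  longer or continuing alternative (if every competing branch dead-ends
  within the limit, the longest survives), so a path's own short tail is
  never mistaken for a tip; a plain path component has no branch point and
  is never touched.

Merging uses the standard unitig rule (an edge `u -> v` joins contigs iff
out-degree(u) = in-degree(v) = 1), so contigs partition the surviving nodes.
Final contigs below 1000 bp are dropped. Final polishing from the groups'
raw reads is on by default: super-read end regions — assembled from the thin
coverage at the edges of their cluster's span — carry elevated error and end
up in the contig *interior* at junctions after merging, where only a
full-coverage consensus can repair them. The step matters most below about
20x per haplotype, but the measured junction errors persist at 25x, and the
cost of the polish is small at these scales.

## The simulator and what passing tests mean

`simulate_diploid()` draws haplotype 1 uniformly at random, derives haplotype
2 by Bernoulli substitutions (default 1% — the study condition used
throughout the end-to-end tests) and optional 1-10 bp indels (default rate
0), and records every het site and the read-level ground truth.
`simulate_reads()` draws lognormal read lengths (default mean 10 kb, sd 2 kb,
clamped to >= 500 bp), uniform start positions and random strands until a
per-haplotype coverage target is met, then applies i.i.d. per-base
substitutions, single-base insertions and deletions. The CLR-like test
condition uses 10% total error split as 4% substitutions, 4% insertions, 2%
deletions at 25x per haplotype; the error-free condition uses 20x per
haplotype.

The simulator deliberately does *not* emulate: repeats or segmental
duplications (hap1 is uniform random, so the overlap graph sees essentially
no repeat-induced internal matches), platform-specific error profiles
(homopolymer-length errors, chimeric reads, quality-correlated errors),
structural variation between haplotypes, or coverage biases. Passing the
end-to-end tests therefore demonstrates that the divide/phase/conquer
machinery is correct and exact on its own model assumptions — not that the
assembler handles repeat-rich real genomes, where the overlap classifier and
tip/SNP filters would face repeat-induced spurious overlaps far more often.

Problem sizes in the test suite were chosen so each stage is exercised at a
meaningful scale: the end-to-end conditions use two 100 kb haplotypes (~400
reads error-free, ~500 noisy); unit fixtures use 3-20 kb templates; oracle
comparisons use >= 100 random instances each.

## Degenerate inputs and tie-breaks

* Empty read set: `assemble_reads()` refuses with an error; an empty overlap
  set yields singleton clusters, whose reads become unphased super reads if
  at least `min_ovlp_len` long.
* Clusters with no callable site, or with one empty wMEC side, emit a single
  unphased super read whose constituent reads are all labelled `both`.
* Length ties in clustering and seed selection break lexicographically by
  read id; equal-cost wMEC bipartitions resolve to the canonical labelling;
  consensus ties prefer the current reference base, then alphabetical order;
  contigs are emitted ordered by their first super read id. Given
  `rng_seed`, the whole pipeline is deterministic and independent of the
  worker count (`threads`), because per-cluster results are combined in
  cluster-id order and per-cluster seeds are derived as `rng_seed +
  cluster_id`.

## Known limitations

* Diploid only; the wMEC state space is a bipartition.
* No bubble popping, scaffolding, or primary/alternate contig
  classification; branching that survives simplification fragments contigs
  rather than mis-joining them.
* Homozygous stretches longer than a read produce a single unphased super
  read; phase is not propagated across them, so haplotigs break there.
* The evaluator assigns each contig to its single best haplotype; sequence
  shared identically by both haplotypes is credited to one of them.
* Runtime is dominated by all-vs-all overlapping and by wMEC columns at the
  coverage cap; the cap (20) keeps the DP around one million states per
  column.
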