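# haplobook

Haplotype-aware de novo assembly of diploid genomes from long reads, in R.

Most long-read assemblers collapse the two haplotypes of a diploid genome
into one consensus sequence; reference-guided phasing tools avoid that but
inherit the biases of the reference they patch. haplobook reconstructs both
haplotypes directly from PacBio HiFi, PacBio CLR, or Oxford Nanopore reads,
with no reference genome, by a divide-and-conquer strategy:

1. **Divide.** Reads are grouped into clusters around seed reads (longest
   first; a cluster is the seed plus everything overlapping it). Each
   cluster is assembled into an *ad hoc reference* — a local coordinate
   system only — against which heterozygous SNPs are called from the read
   pileup. The cluster's reads are then split into the two local haplotypes
   by solving the **weighted minimum error correction (wMEC)** problem
   exactly: over bipartitions *(S, S̄)* of the reads and per-column allele
   assignments, minimise the total phred-weighted number of allele-matrix
   entries that must be flipped so that each side is consistent with a
   single haplotype. The solver is a column-sweep dynamic program, linear in
   the number of variants and exponential only in the (capped) per-column
   coverage. Each phase group, optionally error-corrected against its own
   polished backbone, becomes a haplotype-specific **super read**.
2. **Conquer.** Super reads are assembled through a stricter overlap graph
   (minimum overlap 3 kb, identity ≥ 0.98). An optional SNP-based filter
   genotypes every overlap with the groups' reads and removes edges whose
   overlap contains any heterozygous site — cross-haplotype overlaps look
   clean by identity alone but never genotype clean. After transitive
   reduction, tip removal and simple-path merging, every maximal
   non-branching path becomes a **haplotig**.

The package also ships an internal minimizer-based all-vs-all overlapper
(PAF import/export lets an external overlapper stand in), a synthetic
diploid genome and long-read simulator with ground-truth haplotype labels,
and evaluators for haplotype coverage, switch error rate, N50/NG50/NGA50,
duplication ratio and assembly QV.

## A worked example

```r
library(haplobook)

# a diploid toy genome: two 20 kb haplotypes differing at ~1% of positions
truth <- simulate_diploid(20000, snp_rate = 0.01, seed = 501)
sim   <- simulate_reads(truth, coverage_per_hap = 12, mean_len = 8000,
                        len_sd = 1500, seed = 502)

params <- assembly_params("hifi", snp_edge_filter = TRUE, rng_seed = 77)
asm    <- assemble_reads(sim$reads, params)
asm
#> <hb_assembly>
#>   reads: 61   overlaps kept: 1557   clusters: 1
#>   super reads: 2   contigs: 2 (total 36179 bp, N50 18526)

evaluate_assembly(asm$contigs, truth)
#> <hb_eval>
#>   haplotype coverage: 90.4%   switch error: 0.00%
#>   N50 18526  NG50 17653  NGA50 17653  dup 1.00  QV 60.0  (2 contigs, 36179 bp)
```

Two contigs, one per haplotype: 90% of the diploid truth is covered (the
rest is the thin-coverage genome ends that trimming removes), no adjacent
pair of heterozygous sites switches phase within a contig, every contig base
matches its haplotype (QV capped at 60 when no error is seen), and each
truth base is covered exactly once (duplication ratio 1.0).
`tidy()` on the evaluation gives the per-contig detail (assigned haplotype,
identity, covered het sites, switches); `tidy()`/`glance()`/`autoplot()`
methods exist for assemblies, phasings and evaluations.

A thin command-line wrapper with `overlap`, `assemble`, `simulate` and
`evaluate` subcommands is installed at `inst/cli/haplobook.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/haplobook.R", package="haplobook"))')" \
    assemble --platform clr --seed 1 -o out reads.fastq.gz
```

## Scope

Diploid genomes only. No bubble popping, scaffolding or primary/alternate
contig classification; the simulator does not model repeats or
platform-specific error profiles (see the methods vignette,
`vignettes/haplobook-methods.Rmd`, for what that implies about the tests).
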