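---
title: "Discovering and ranking tandem repeat families from survey reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and ranking tandem repeat families from survey reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satseeker)
options(satseeker.quiet = TRUE)
```

## The model behind the pipeline

Satellite DNA — centromeric repeats, subtelomeric repeats, knob repeats —
consists of a short monomer repeated head-to-tail in long arrays. Because a
high-abundance family contributes a fixed fraction of the genome, the number
of shotgun reads it recruits is binomially distributed around that fraction
regardless of sequencing depth. That is the statistical core of the method:
**the proportion of reads recruited by a repeat family estimates its genomic
fraction**, and survey-depth data suffice because the estimator's standard
error, $\sqrt{p(1-p)/n}$, depends on the number of reads, not on genome
coverage. Everything else in the package exists to build a usable reference
for that recruitment step out of the reads themselves: a repeat-tolerant
assembly, a tandem detector to isolate the satellite-bearing contigs, and a
homology clustering step so that rotated, diverged or reverse-complemented
copies of one monomer are counted as one family.

## Assembly of tandem arrays at survey depth

The assembler is a canonical-k-mer de Bruijn graph (default $k = 31$, odd so
no k-mer is its own reverse complement) with a multiplicity noise filter.
The default threshold of 2 removes singleton k-mers, which at survey depth
are overwhelmingly sequencing-error artifacts; at higher coverage the
threshold scales as mean multiplicity / 10, so it stays monotone in read
count for a fixed genome.

A tandem array is, to this graph, a cycle: every copy of the monomer
traverses the same $p$ k-mers. Two consequences drive the design:

* **Cycle recovery comes first.** Maximal non-branching-path extraction
  alone cannot reconstruct an array, because the array/background junctions
  attach in- and out-edges to the cycle and chop it into short arcs that
  fall below the 200 bp contig floor. A dedicated pass therefore walks the
  graph from high-multiplicity k-mers following the highest-count successor
  (ties: smallest encoded k-mer, for determinism) and extracts any directed
  cycle it closes. The cyclic sequence is emitted unrolled to **three
  monomer periods**, so the downstream detector sees multiple copies and a
  copy number of 3.
* **Unitigs are conservative.** Outside cycles, paths are extended only
  through edges that are the unique out-edge of their source and unique
  in-edge of their target; at any branch the path simply stops. At the
  benchmark's depth the unique background assembles into a handful of long
  unitigs, all of which the tandem filter later discards.

The practical consequence: arrays assemble when their k-mers are sampled at
multiplicity $\ge 2$, i.e. when array coverage reaches about 2X — which for
a high-copy family happens far below 0.1X genome coverage on real genomes.
On the package's 1 Mb benchmark genomes the same regime is reproduced with
7.5X read depth, because a desk-scale genome holds hundreds rather than
hundreds of thousands of copies per family. The choice of problem size
(1 Mb, 50,000 reads, 20 seeds for the stochastic properties) keeps the full
test suite in the minutes range while leaving every binomial test with
enough resolution to detect real bias.

## Tandem detection and scoring

Candidate periods are generated deterministically: for each distance
$d \le 2000$, the support is the number of positions whose probe k-mer
(default 4 bp) recurs exactly at distance $d$; a candidate must reach
$\lceil p_m (L - d - k) \rceil$ support with $p_m = 0.80$. This replaces a
probabilistic k-tuple model with a reproducible filter parameterised by the
same intended match probability; the companion indel probability
$p_i = 0.10$ is carried in `scoring_params()` but unused, since the error
model is substitution-only. A 4 bp probe keeps the filter sensitive to
monomers carrying a few percent of per-copy divergence (the expected support
fraction is $(1-\mu)^{2k}$ at per-base divergence $\mu$, comfortably above
0.80 at $\mu = 2\%$ for $k = 4$ but not for much longer probes). Random
sequence cannot reach the threshold: the expected support is
$(L-d)/4^k \ll 0.8 (L-d-k)$.

Each candidate span is then scored by wraparound dynamic programming against
its consensus monomer, with the classic weights match $+2$, mismatch $-7$,
indel $-7$ (per indel base, no affine gaps — the simplest reading of a
single indel weight). The recurrence allows the monomer column index to wrap
cyclically; the within-row cyclic dependency is resolved with two sweeps per
row, which reach the fixpoint because deleting a full monomer turn costs
$7p$ and is never optimal. Free start and end phase mean a perfect $c$-copy
array of a $p$-bp monomer scores exactly $2cp$; with the minimum reported
score of 50, no perfect array shorter than 25 bp can ever be annotated. The
test suite pins this implementation, on more than a thousand random
instances, to an independent brute-force formulation (global-in-sequence /
local-in-reference alignment against a long linear concatenation of the
monomer) — the two are provably the same optimisation when enough linear
copies are laid out.

The consensus monomer is a per-phase majority vote refined once along the
wraparound alignment; voting ties break to the alphabetically first base.
The reported period is the smallest that passes (perfect multiples of an
accepted period are suppressed), and overlapping annotations resolve to the
highest score, ties to the smaller period. Monomers are compared across
contigs, rotations and strands through `canonical_monomer()`: the
lexicographically least rotation of the monomer or its reverse complement.

## Read recruitment

A read hits a contig when a shared 15-mer (either strand) lies on a diagonal
whose maximal ungapped segment covers at least 80% of the read at identity
at least 0.85. Segment finding uses a linear scan with match $+1$ and an
internal extension penalty of $-3$ per mismatch: scattered sequencing errors
are bridged, but the segment cannot drift into unrelated flanking sequence
(expected score per base in random sequence is negative). Gapless extension
is coherent with the substitution-only simulator; with indel-rich real data
the identity threshold would effectively tighten, which errs conservative.
The defaults (seed 15, identity 0.85) are chosen so a 150 bp read with ~1%
errors still seeds and passes. Reads hanging over a contig end are scored on
the overlap only — there is no cyclic recruitment — so a read needs 120
aligned bases to count, and reads within 30 bp of an array edge can be
gained or lost. That edge effect is bounded by ~90 bp per planted array and
stays well inside one binomial standard deviation at the benchmark's array
counts; it is the main reason the benchmark plants few large arrays per
family (3/2/1), which is also the realistic satellite architecture at this
scale.

Multi-mapping policy: a read counts once per contig however many placements
it has there, counts toward every contig it hits, and counts **once** toward
`total_tandem_fraction` (the union reading — the total is the proportion of
all reads mapping to *any* tandem contig).

## Family extraction

Families are extracted greedily: rank the remaining tandem contigs by
recruited reads (ties: longer contig, then id; contigs whose representative
monomer is shorter than 30 bp cannot lead the ranking, though they may still
join families as members), seed on the top contig's consensus monomer,
absorb all homologs, remove, repeat — 4 times by default, since family
abundance is typically negligible beyond the fourth. If the pool empties or
no eligible seed remains, extraction stops early and reports fewer families;
that is an expected outcome (a genome may simply lack tandem repeats above
30 bp), not an error.

Homology uses ungapped Karlin–Altschul statistics with weights $+1/-2$:
$E = K m n e^{-\lambda S}$, with $\lambda$ solved from
$\frac{1}{4}e^{\lambda} + \frac{3}{4}e^{-2\lambda} = 1$ ($\lambda \approx
1.33$) and $K = 0.621$, the standard tabulated value for these weights at
uniform base composition. $S$ is the best seeded (11 bp word) maximal
ungapped segment score — self-consistent with the ungapped E-value — $m$ the
seed monomer length and $n$ the total length of the searched pool. The seed
monomer is **doubled** before searching so rotated copies in other contigs
are found (cyclic identity is real for tandem monomers), but $m$ uses the
undoubled length: doubling is a mechanical device to expose rotations, not
extra query information. The homolog threshold is $E \le 0.1$ — deliberately
liberal, as befits grouping diverged satellite variants; at that setting the
expected number of spurious homologs is a few percent per search, which the
negative-control tests bound empirically.

Each family's genomic fraction is then re-estimated by recruiting **all**
reads against a family reference built from the doubled seed monomer plus
every member contig. Doubling matters here too: against an undoubled linear
monomer, a read sampled at a random phase of the array has only ~50% chance
of overlapping 80% of its length contiguously, mechanically halving the
estimate — the fragment-length bias that mapping against monomer-plus-
polymer references is designed to remove. With the doubled monomer any
phase aligns contiguously whenever the read is no longer than the monomer,
and the paired-run test confirms monomer-only and full references agree
within binomial noise. Families are disjoint over contigs, not reads, so a
read recruited by two families counts in both fractions; the conservation
test bounds the resulting excess.

## What the simulator does and does not emulate

`build_genome()` plants, in uniform-GC background, head-to-tail arrays of
each family's monomer at non-overlapping loci on random strands, applies
independent per-copy substitutions, and can add a dispersed TE-like repeat.
`shotgun_reads()` draws uniform start positions and strands and applies
i.i.d. substitution errors; reads are emitted single-end directly, because
survey designs that sequence paired-end and split the pairs leave nothing
pair-aware for this pipeline to use. Truth fractions use planted reference
bases over genome length — estimation error, including the read-sampling
noise, is the pipeline's to measure.

The packaged benchmark (`planted_benchmark_spec()`) is a 1 Mb genome with
three families at planted fractions 9.99%, 5.04% and 0.99% and monomer
lengths 180, 350 and 184 bp — the characteristic knob-repeat monomer sizes
of the Andropogoneae — plus a 3 kb TE at 5% divergence and 20 copies as
non-tandem repetitive background. The benchmark's arrays are internally
homogeneous (per-copy mutation 0): it measures abundance ranking and
composition recovery, not divergence tolerance, which is exercised
separately at the detection level (per-copy divergence up to 2% in the
property tests). Features of real data deliberately not emulated: indel
errors and platform error profiles, GC-biased coverage, higher-order repeat
structure, library artifacts (barcodes, adapter read-through), and
polyploidy. Passing tests therefore certify the statistical machinery and
the algorithms, not robustness to every artifact of a real sequencing run.

The divergence limitation is structural, and worth stating plainly: with a
de Bruijn assembler, per-copy divergence above roughly $1/k$ fragments an
array's k-mer cycle into copy-specific paths, so heavily diverged satellite
families would assemble poorly here even though the detector itself
tolerates them. An overlap-based assembler — the choice made by the survey
workflows this package models — degrades far more gracefully on such
families. Within this package the cycle-recovery pass restores the dominant
(consensus) cycle when divergence is modest, which is the regime the
benchmark tests.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere.
* `generate_monomer()` rejection-resamples until the sequence has no perfect
  sub-period, so a planted period is always primitive.
* Deterministic tie-breaks throughout: cycle walks prefer the smallest
  encoded k-mer, consensus votes the alphabetically first base, rankings
  fall back to longer contig then lexicographic id, overlap resolution to
  the smaller period.
* Empty inputs degrade without errors: no reads → no contigs; no tandem
  contigs → zero families and total fraction 0; an empty extraction pool
  stops early with a log line.
* All randomness is confined to the simulator and controlled by explicit
  seeds (`withr::with_seed`, so the caller's RNG state is untouched); the
  pipeline itself is deterministic, and its outputs are byte-identical
  across repeated runs. The implementation is single-threaded; the
  `--threads` flag is accepted for interface stability and results are
  independent of it by construction.

## Worked run

```{r example}
sim <- simulate_dataset(planted_benchmark_spec(seed = 1), coverage = 7.5)
res <- run_pipeline(sim$reads, pipeline_config(quiet = TRUE),
                    truth = sim$truth)
print(res$report)
```

```{r dotplot, fig.width = 5, fig.height = 5}
plot(self_dotplot(substr(res$tandem$seq[1], 1, 400), window = 12,
                  min_identity = 0.9))
```

The dot plot of the top family's contig shows the off-diagonal banding at
the monomer period that defines a tandem array.

## Known limitations

* Families more diverged than a few percent per copy assemble poorly (see
  above); the detector and recruiter tolerate more divergence than the
  assembler does.
* Higher-order repeat structure (dimeric units, variant interleaving) is
  neither simulated nor inferred; the pipeline reports the primitive period.
* E-values use ungapped statistics; indel-mediated homology weaker than the
  word seed is invisible to the clustering step.
* `genome_size_correlation()` is exercised against synthetic per-taxon
  fractions joined to the packaged published genome sizes; the package
  makes no claim about any particular taxon's repeat content.
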