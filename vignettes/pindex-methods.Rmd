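---
title: "Measuring subgenome divergence with the P-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subgenome divergence with the P-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pindexr)
```

## The problem

After a whole-genome duplication (polyploidy), the duplicated gene
complement erodes: most duplicated genes return to single copy, a process
called fractionation. How that loss is distributed between the two (or
more) subgenomes carries a signal about the origin of the polyploid. In an
autopolyploid the subgenomes start identical and tend to lose genes at
similar rates ("balanced" fractionation); in an allopolyploid the
subgenomes descend from diverged parents and one of them — the sensitive
subgenome — typically loses far more genes than the dominant one
("biased" fractionation). For paleopolyploidies, tens or hundreds of
millions of years old, direct evidence of parentage is gone, but the gene
loss pattern is still written into the genome and can be read off against
an outgroup reference genome that escaped the duplication.

`pindexr` implements a windowed statistic of this pattern, the polyploidy
index (P-index), together with everything needed to compute it from
standard comparative-genomics inputs and to validate it by simulation.

## The statistic

All coordinates are gene ranks, not base pairs: the reference genome's
genes are numbered 0, 1, 2, ... along each chromosome in start-coordinate
order, and windows are blocks of `M` consecutive reference genes (default
`M = 100`). Working in rank space removes assembly-scale and intergenic
length effects; the formulas are defined over genes.

For a reference chromosome *c* divided into *N_c* windows, and subgenomes
*A* and *B* of the studied polyploid, let *A_i* and *B_i* be the fractions
of window *i*'s reference genes with a surviving collinear copy in each
subgenome. Windows where the two retention rates are nearly equal carry no
directional information and are removed: the relative difference

d_i = |A_i − B_i| / (0.5 (A_i + B_i))

is compared with a threshold τ (default 0.05), and window *i* is
informative (δ_i = 1) only when d_i ≥ τ. A window with both copies absent
(A_i + B_i = 0) is defined as uninformative — the ratio is 0/0 there and
the window says nothing about direction. With n_c informative windows on
the chromosome, the per-chromosome term is

T_c = | Σ_i sign(A_i − B_i) δ_i | / n_c,

the absolute mean direction of retention difference. The genome-wide index
is the weighted mean P = Σ_c W_c T_c with W_c = n_c / Σ n_c (weights
proportional to informative window counts; weights proportional to raw
window counts are available as `weight_scheme = "raw"`). Balanced loss
makes the signs fluctuate around zero and P ≈ 0; consistently one-sided
loss aligns the signs and pushes P toward 1.

Two presentation details differ deliberately from the formulas as often
printed for statistics of this shape:

* **No leading 1/K factor.** With weights already normalized to sum to 1
  over the K included chromosomes, an extra 1/K would cap the index at
  1/K and contradict both its advertised 0–1 range and every published
  value. The statistic here is exactly the W_c-weighted mean of T_c.
* **Absolute values inside the multi-subgenome d_i.** For S > 2 the
  window filter averages pairwise relative differences; taking them
  signed would let opposite-signed pairs cancel and mark strongly
  divergent windows as uninformative, so the absolute value of each
  pairwise difference is used.

For S > 2 subgenomes the numerator sums sign(A_ki − A_ji) δ_i over all
compared pairs (k, j), and the default denominator is n_c × (number of
pairs), which keeps T_c in [0, 1] and reduces exactly to the pairwise
definition at S = 2. The literal published denominator
N_c × C(S,2) − δ(N_c), which subtracts the uninformative count once
rather than once per pair, is available as
`denominator_scheme = "printed"` for comparison, as is the published 1/S
divisor in the window filter (`pair_norm = "S"`). With S = 2 all variants
coincide.

An event is classified as an allopolyploidy when its mean P-index strictly
exceeds 0.3 (a boundary value of exactly 0.3 classifies as auto). The
threshold is a working boundary anchored by known allo- and
autopolyploids, not an absolute division; `classify_event_table()` exposes
it as a parameter.

## From input files to a profile

The pipeline is:

```
read_gene_positions()  ->  read_collinearity()  ->  partition_subgenomes()
        ->  compute_retention()  ->  compute_flags()  ->  pindex_pair()
```

Collinearity detection itself (homolog search plus block chaining with
tools such as ColinearScan or MCScanX) is out of scope; its output files
are parsed, in either the MCScanX `.collinearity` dialect or a plain
anchor TSV.

`partition_subgenomes()` tiles collinear blocks into S tracks per
reference chromosome with a deterministic greedy rule: blocks are sorted
by anchor count (ties: longer reference interval, then query chromosome
name, then reference start) and each block goes to the lowest-index track
where fewer than `overlap_frac` (default 10%, absorbing block-caller
boundary jitter) of its anchors fall on ranks already covered. A placed
block occupies its entire reference rank interval, not just its anchor
positions — interval occupancy makes boundary overlaps between abutting
segments of different subgenomes visible at their geometric size rather
than discounted by the retention rate, which is what makes the rule
reliable on fragmented assemblies. Anchors of a newcomer that fall on
occupied ranks are trimmed; blocks that fit nowhere are discarded with a
warning.

Two limitations are inherent to the greedy rule and worth knowing.
Track indices are not linked across reference chromosomes (track 1 on one
chromosome need not be the same subgenome as track 1 on another), and two
blocks of *different* subgenomes whose reference intervals are disjoint
can land on the same track, since nothing distinguishes them positionally.
Fragmentary real assemblies with published subgenome assignments (e.g.
wheat A/B/D) should bypass the tiler entirely via
`as_subgenome_assignment()`. Where two placed blocks abut with a gap, the
gap simply remains lost ranks; no concatenation heuristic is applied.

`label_dominance()` orders tracks by total retained genes (the
most-retained track is the dominant subgenome); exact ties keep the input
track order, making the otherwise arbitrary assignment deterministic.

Windowing (`compute_retention()`) tiles each chromosome with
non-overlapping windows of `M` reference genes. "Sliding" window language
in this literature is interpreted as this disjoint tiling: it matches the
"divide into N_c windows" definition and makes N_c well defined. The
trailing partial window is kept only when it has at least `M/2` genes
(its retention uses its actual size as denominator); shorter tails, and
chromosomes shorter than `M/2`, are dropped — tiny windows have
high-variance retention rates that would feed noise into the sign
statistic, while discarding up to half a window of real signal costs
little. Windows are anchored on reference gene ranks, the only convention
a reference-based retention definition supports.

## Special modes

**Self-reference (`pindex_selfref()`).** A genome that preserves its own
paleo-triplication (the archetype being the grape genome's triple
homoeology) can be scored without an outgroup: one copy of each
homoeologous triple acts as the internal reference and the other two are
compared to it. Positions lost from the reference copy are skipped
entirely — under random loss this is a random subsample of loci, i.e. a
sampling experiment, unbiased for the retention *difference* between the
other two copies. Each of the three copies can serve as reference in turn
(`rotate = TRUE`); under homogeneous loss the three estimates agree
closely and their spread is a useful internal consistency check.

**Recursive events (`pindex_recursive()`).** Two nested duplications
leave four homoeologous copies per reference region. Given the event
pairing (which is biological input, not inferred), the younger event is
scored within each pair — per chromosome, the two within-pair terms are
combined as an informative-window-weighted mean before global weighting —
and the older event is scored across the four cross-pair combinations
with the multi-subgenome formula.

**Distance matrices (`pairwise_matrix()`).** For S ≥ 3 the pairwise
P-index behaves as a distance between subgenomes. Tracks are grouped by
average-linkage clustering; the partition (over 2 to S−1 groups) that
maximizes mean between-group minus mean within-group distance is
reported, with group means as integrated indices. The cut criterion is
this package's own choice; it recovers planted group structure in the
test fixtures and is the natural objective when groups are expected to be
internally similar.

## The gene-loss simulator

Fractionation proceeds by deletion of short runs of adjacent genes whose
lengths are approximately geometrically distributed. `simulate_losses()`
implements exactly that: each deletion event starts at a uniformly random
still-retained gene, draws a run length L from a geometric distribution
on {1, 2, ...} with success parameter p (mean 1/p; default p = 0.5, mean
run 2), and deletes the next L still-retained genes in rank order,
truncated at the chromosome end. Consuming only still-retained genes
keeps the marginal run-length law geometric on the surviving sequence.
Events repeat until the retained fraction is at or below the target; the
final event may overshoot rather than stop early, an unbiased stopping
rule whose error is bounded by one run length.

`simulate_pindex()` wraps this into the full experiment: an intact
ancestor is duplicated into S copies, each copy fractionated to its
target, profiled against the ancestor, and scored. The generator's
defaults are the package's canonical study conditions: 10 chromosomes ×
2,000 genes, S = 2, both subgenomes to 60% retention for the balanced
(auto-like) scenario, 75%/40% for the unbalanced (allo-like) scenario,
p = 0.5, M = 100, τ = 0.05, 100 replicates. Retention around 40–75% and
~20,000 genes are typical of paleopolyploid plant genomes measured
against mid-distance outgroups. Unbalanced scenarios are realized as
distinct per-copy retention targets (optionally distinct p); replicate j
is seeded with `seed + j − 1`, and the RNG kind is recorded in the config
echo, so distributions are bit-reproducible.

Under the balanced null the per-chromosome term is the absolute mean of
n_c fair signs, with expectation ≈ √(2/(π n_c)); the index therefore has
a positive sampling floor that shrinks as window count grows (a property
the test suite asserts over increasing genome sizes). This is why short
profiles should not be over-interpreted: a genuinely balanced polyploid
measured over few windows will still show a small positive index.

`calibrate_from_observed()` reads simulation parameters off a real
assignment: per-track retention by counting, and p by method of moments
on observed contiguous lost runs (p = 1/mean run length). Independent
deletion events merge into longer observed runs as fractionation deepens,
so the moment estimate is biased low in heavily fractionated regions; it
is accurate in the sparse-deletion regime (retention ≳ 0.9, where the
parameter-recovery test operates) and should be read as a lower bound on
p elsewhere.

## What the synthetic fixtures do and do not show

`make_polyploid_fixture()` emits complete on-disk bundles (reference
BED/GFF3, query gene TSV, anchor TSV and MCScanX-style collinearity,
truth table) for balanced, biased, two-round and grouped-decaploid
scenarios, so the whole pipeline is exercised from files with no
downloads. Optionally each copy's single block per chromosome is
shattered into three segments with breakpoints staggered across copies
(offset 5% of the chromosome), so segments of different copies
chain-overlap at their boundaries — the hard path for the greedy tiler.

The fixtures emulate fractionation structure only. They do not contain
tandem duplications, translocations, inversions within blocks, gene
family expansion, annotation noise, or assembly fragmentation beyond the
planted segmentation, and each query chromosome holds exactly one
subgenome's copy of one reference chromosome. Passing tests on these
fixtures therefore demonstrate the correctness of the statistic and the
determinism and recovery behavior of the pipeline under its stated model
— not robustness to the full messiness of real genome comparisons, where
block-caller quality and reference choice dominate (a caveat the
published analyses share: closer, better-assembled references give more
credible indices).

## Numerical choices and degenerate inputs

* Ranks are 0-based and all rank intervals half-open, everywhere.
* Rank ties (identical starts) break by end coordinate, then gene id.
* sign(0) = 0; such windows are uninformative by construction.
* A chromosome with no informative window is excluded; if no chromosome
  survives, the result carries `status = "undefined"` and a P-index of 0,
  and is never silently reported as a plain 0.
* τ must lie in (0, 1); d_i ≤ 2 always (it is 2|A−B|/(A+B)), so τ ≥ 2
  would mark everything uninformative.
* Result reports round-trip: `write_pindex_result()` prints with 17
  significant digits and `read_pindex_result()` restores the object to
  12+ digits.
* Event-level classification averages the event's rows; per-row values
  remain the primary output and the mean is used only for the verdict.

## Problem sizes used by the test suite

The shipped tests run the simulation criteria at the canonical
10 × 2,000-gene geometry with 100 replicates per scenario, property
batteries over 1,000 randomized profiles (1–20 chromosomes, 5–50 windows,
S ∈ {2, 3}), and partition-recovery fixtures at 6–10 chromosomes of
800–2,000 genes; these sizes give stable statistics while keeping a full
run to a few minutes on one core. The oracle battery compares the
production implementation against an independent plain-loop
implementation of the refined formula and requires agreement to 1e-12.

## Worked example

```{r example, eval = FALSE}
fx <- make_polyploid_fixture(tempdir(), scenario = "biased",
                             n_chromosomes = 6,
                             genes_per_chromosome = 1000,
                             seed = 1, shatter = TRUE)
ref <- read_gene_positions(fx$files[["reference_bed"]], "bed")
qry <- read_gene_positions(fx$files[["query_genes"]], "tsv")
anchors <- read_collinearity(fx$files[["collinearity"]], "mcscanx",
                             ref, qry)
assignment <- partition_subgenomes(anchors, ref, S = 2) |>
  label_dominance()
profile <- compute_retention(assignment, M = 100)
result <- pindex_pair(profile)
glance(result)
classify_pindex(result$pindex, label = "synthetic biased tetraploidy")
```

## Limitations

* The greedy tiler is near-optimal for long sparse blocks but is not an
  optimal interval scheduler; adversarial block configurations can
  mis-tile, and published assignments should be preferred when they
  exist.
* The self-reference mode assumes loss in the reference copy is
  independent of loss in the compared copies; shared deletion hotspots
  would bias its subsample.
* The run-length calibration is biased low under heavy fractionation
  (run merging), as discussed above.
* Real-genome published index values depend on external genome assemblies
  and collinearity runs and are not reproduced here; the packaged event
  catalog carries them as classification inputs only.
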