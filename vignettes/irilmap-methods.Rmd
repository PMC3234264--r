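---
title: "Methods: linkage mapping from intermated RILs and assembly colinearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping from intermated RILs and assembly colinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irilmap)
```

## The problem

High-density SNP arrays genotype tens of thousands of markers on biparental
mapping populations. For intermated recombinant inbred lines (IRILs) — an F2
intermated at random for *t* generations and then selfed to fixation — the
extra meioses expand the observable recombination signal, which improves map
resolution but means that naive distance estimation overstates centiMorgan
lengths. With a couple hundred lines and thousands of markers, many adjacent
markers are statistically indistinguishable, so a map whose *order* is
asserted for every marker would be largely arbitrary. This package
implements the field's standard answer: build a sparse **scaffold** whose
order is essentially certain, densify it into a **framework** admitting a
marker only when the order stays statistically robust, and then **bin-place**
every remaining marker onto the fixed framework without claiming an order
among markers in the same bin. Genetic maps built this way, on two
populations, can then audit a physical genome assembly: markers mapped to a
different chromosome than the assembly claims (non-syntenic markers), runs
of markers whose within-chromosome order disagrees (non-colinear regions),
recombination-rate landscapes (Marey maps), and predicted positions for
markers missing from the assembly.

## The genetic model

**Meiosis.** Crossovers follow a Haldane model: no interference, so
recombination events in disjoint intervals are independent and an interval
of *d* cM recombines with probability `r = (1 - exp(-2d/100))/2`. The
simulator applies exactly this process marker-to-marker, which keeps the
simulation and the estimation theory in the same model family. Interference
models (gamma, chi-square) are out of scope.

**Line-level recombinant fractions.** Between two loci at meiotic fraction
*r*, fixed selfed RILs show the classical Haldane–Waddington fraction
`R = 2r/(1+2r)`. Each random-intermating generation decays gametic linkage
disequilibrium by `(1-r)`, giving

```
R(r, t) = 1/2 * [ 1 - (1-r)^t * (1-2r) / (1+2r) ]
```

for *t* intermating generations followed by selfing to fixation
(`iril_R()`). The small-*r* map expansion factor is `(t+4)/2`. Because the
source material cites but does not print this correction, the package treats
the closed form as *hypothesis to be validated*: the test suite compares it
against the package's own brute-force meiosis simulation at 100,000 lines
over a grid of `r` and `t` values before anything downstream relies on it.
Distances are reported on two scales: corrected cM (invert `R(r,t)`, then
Haldane) and **pseudo-cM** (invert with `t = 0`, i.e. as if the lines were
plain RILs). Pseudo-cM is systematically larger for `t > 0`; both scales are
written to map tables.

**Residual heterozygosity.** A locus is heterozygous in a random-mating
founder with probability 1/2 (Hardy–Weinberg at allele frequency 1/2), and
each selfing generation halves that, so the simulated population shows
`(1/2)^(n_selfing + 1)` heterozygous calls per locus — each selfing
generation halves heterozygosity exactly as the design contract states; the
extra factor 1/2 is the founder's own heterozygosity. The default design
(239 lines, `t = 4`, 6 selfing generations) mirrors the larger of the two
published populations; the exact number of intermating generations is not
stated in the source text, so `t` is an explicit parameter everywhere.

## What the synthetic data emulates — and what it does not

`simulate_iril_population()` produces genotypes with the exact statistical
structure assumed by the estimators (Haldane meiosis, finite random-mating
population of constant size with distinct parents, single-seed descent).
`corrupt_genotypes()` adds the three array pathologies that drive the QC
design: failed calls (default 4%, the published average failure rate),
genotype flips (default 0.5%, matching the sub-1% triplet inconsistency the
study reports), and per-call GC quality scores from a two-component Beta
mixture — `Beta(30, 2)` for clean calls, `Beta(3, 5)` for flips — chosen so
that the published GC thresholds (0.8 framework / 0.6 placement) genuinely
separate good from bad calls: about 95% of clean calls survive the 0.8
threshold while under 5% of flips do. `simulate_intensities()` reproduces
the four recurrent two-channel cluster geometries (three clusters near
theta 0/0.5/1; the same with a low-intensity failed fraction; three shifted
clusters from a duplicated locus; five clusters from two co-scored loci)
with truncated-normal theta so no artificial point masses appear at the
boundaries.

Not emulated: realistic allele-frequency spectra of diversity panels,
copy-number variation, batch effects, segregation distortion with a
biological cause, or interference. A green synthetic test therefore
establishes that the estimators are correct *under the stated model*, not
that the model captures every pathology of real arrays.

## Ordering engine

All ordering decisions use a composite chain score: the log10-likelihood of
an order is the sum over adjacent pairs of the maximized pairwise binomial
log-likelihood (computed on pairwise-complete lines, recombinant fraction
truncated at 0.5). Inserting a candidate between markers L and R changes the
score by `pl(c,L) + pl(c,R) - pl(L,R)`. This composite score is fast (all
pairwise terms are precomputed as matrices) and is used for scaffold
accretion, framework insertion and bin placement; the final distances are
then re-estimated once per chromosome by a proper 2-state forward–backward
EM (`multipoint_distances()`) that marginalizes missing and heterozygous
calls, to a log-likelihood tolerance of 1e-6.

* **Grouping**: single linkage on `LOD >= 10` and `R <= 0.25`. The classical
  LOD 3 convention is appropriate for hundreds of markers; with ~2,000
  markers and ~240 lines the number of candidate pairs makes spurious
  chromosome-joining edges likely at LOD 3, so the default is deliberately
  strict. Both thresholds are exposed.
* **Scaffold**: greedy accretion from a seed, admission requiring a log10
  placement margin of at least 3 over the second-best position *and* at
  least 10 cM to both prospective neighbours; the order is locally
  re-optimized (sliding window-3 permutations) after each insertion. Ten
  replicate scaffolds are grown from the most informative markers spread
  across the group (max–min two-point distance), and markers whose relative
  order is contradicted in any replicate are dropped — the consensus rule
  the source text implies but does not specify.
* **Framework**: candidates in information order (fewest missing, then
  highest minor-allele frequency, then id) are inserted at their best
  position iff both the position margin and the margin of the
  post-insertion order over every window-3 permutation covering the new
  marker are at least 3 log10 units. Requiring the position margin as well
  as the window margin guards against candidates that would sit equally
  well in two distant intervals.
* **Bin placement**: maximum-likelihood interval on the fixed framework,
  margin computed against the best *non-adjacent* interval (the two
  intervals flanking a framework marker describe the same point, so a
  marker co-segregating with a framework marker is placed, not discarded);
  placements below margin 3 or with fewer than 10 informative lines stay
  unmapped. The point position inside the interval comes from the
  recombinant fraction to the flanking marker, clamped into the interval
  and to coordinate 0 at the chromosome start (coordinates start at 0 at
  the first framework marker, matching the map-table convention).

Genetic maps have no intrinsic orientation; wherever a map is compared to
truth or to a physical assembly the orientation maximizing rank agreement is
chosen first.

## QC statistics

Failure rates are per-marker FAILED fractions; group call rates are per-cell
(not per-sample) means, the assumption documented for the published
per-group figure. Triplet consistency counts markers where two homozygous
parents and the F1 are all called and the F1 violates the Mendelian
expectation. The segregation-distortion scan tests each marker's parent-1
allele frequency among homozygous calls against 0.5 with an exact binomial
rule at the two-sided 1% level using **mid-p** tails: the plain exact rule
attains only ~0.8% under the null for ~239 informative calls (discreteness),
while mid-p centres the attained rate on the nominal 1% — the choice is made
for calibration, before any acceptance measurement, and is asserted by a
null simulation. Dice similarity treats each genotype as the multiset of its
two alleles (AB shares one allele with each homozygote, two with AB);
pairwise similarities use jointly-called markers only, and the dendrogram is
UPGMA on `1 - similarity`.

## Colinearity analysis

Linkage groups are matched to physical chromosomes by majority vote of their
placed markers; a marker disagreeing with its group's majority chromosome is
non-syntenic. Non-syntenic markers within 10 Mbp on the same physical
chromosome and with the same genetic assignment form clusters (a planted
translocation re-emerges as a cluster of exactly its size). Within a
chromosome, a framework marker is *discrepant* when its physical rank
differs from its genetic rank by more than 2 positions or more than 5 Mbp —
both tolerances are package choices (exposed as arguments), standing in for
a qualitative published criterion, and are deliberately loose enough that
mapping noise (adjacent-rank swaps) never triggers them. Each discrepant
marker implies a displacement span, from where it sits to where its genetic
rank expects it; spans that overlap merge into one candidate region. This
matters for inversions: the most displaced markers of an inverted block are
its two ends, whose spans both cover the whole block, so the block is called
as one region rather than two fragments. A region needs two discrepant
markers, or one plus an overlapping region in the other population — the
published cross-population support rule. Regions are named
`<chromosome>.<index><population suffix>` by ascending physical start.

The recombination landscape smooths concordant (bp, cM) pairs by local
linear regression with a physical bandwidth (default 10 Mbp; local *linear*
rather than kernel averaging so that a perfectly linear Marey map yields
exactly rate 1 cM/Mbp with no edge bias), removes outliers beyond 15 cM
from a running-median trend first, enforces monotonicity by isotonic
regression, and pins the endpoints to the observed genetic span so the
derivative integrates to the chromosome's genetic length by construction.
Physical positions of unplaced markers are predicted by linear interpolation
of cM between the nearest concordant framework anchors, extrapolating the
terminal slope beyond the ends, clamped to the chromosome bounds.
Polymorphism deserts are physical gaps of at least 10 Mbp between one
population's polymorphic markers that contain at least 5 of the other
population's — the signature of parental identity by descent.

## Panel selection

Candidate SNPs are prefiltered (duplicates, SNPs flanked by known SNPs on
both sides, design score below threshold) and selected in four steps:
non-Panzea SNPs in high-confidence genes; non-Panzea SNPs outside genes;
Panzea SNPs covering genes not yet represented (best SNP per gene); and a
greedy even-spacing fill that repeatedly places a candidate nearest the
midpoint of the largest remaining physical gap. Ties prefer one-bead
(Infinium II) assays over two-bead, then higher design scores. The greedy
fill is not a global optimizer of the minimum gap — the test suite verifies
it against exhaustive search on configurations where the greedy choice is
provably optimal, and documents the gap-filling heuristic as such.

## Numerical choices and degenerate inputs

* Mixture fitting for cluster patterns is 1-D EM on theta only (intensity is
  used solely for the FAILED floor), quantile-initialized for determinism,
  with a variance floor of 5e-4; component counts 1–6 are compared by BIC
  and components closer than 0.08 in theta are merged before pattern
  assignment, since such components cannot act as distinct calling clusters
  (this also resolves BIC's tendency to split skewed boundary clusters).
  Degenerate (zero-variance) theta input is an error, as is calling from a
  five-cluster model.
* Two-point recombinant fractions are truncated to `[0, 0.5]`; the LOD uses
  the untruncated MLE so it is always non-negative. `R >= 0.5` converted to
  a distance raises an explicit infinite-distance error.
* EM interval fractions are clamped to `[1e-6, 0.4999]`; "zero cM" is
  therefore ~2e-4 cM numerically.
* All simulators accept a seed and restore the caller's RNG state; equal
  seeds give bit-identical output. Tie-breaks in ordering and selection are
  deterministic (score, then assay class, then id).

## Scale of the shipped tests

The acceptance suite runs the stated scales: the 100,000-line map-function
oracle over `r` in {0.01, 0.05, 0.1, 0.2} and `t` in {0, 2, 4}; the
IBM-like recovery at 10 chromosomes x 200 markers x 239 lines; 200 colinear
replicates (3 chromosomes x 60 markers each — the replicate genome size is a
package choice balancing power against runtime) for the false-positive
bound; and a 10,000-marker null distortion scan. Module tests use smaller
scales (e.g. 25 rather than 200 classification replicates per cluster type,
20,000 rather than 100,000 lines for the two-locus check) with the same
statistical guards; the acceptance tests are the authoritative scale. The
printed-count reproductions of the published supplementary tables cannot run
without the original deposited files, which are not redistributable inside
this package; the corresponding acceptance test stays red unless those
files are placed under `inst/extdata/supplementary/`.

## Known limitations

Composite pairwise likelihood is an approximation to the full multipoint
likelihood for *ordering* decisions (distances are exact-EM); extremely
gappy markers can in principle be mis-inserted, which the information-order
insertion and window-robustness margin mitigate. The region caller reports
discrepancies and their cross-population support but deliberately does not
classify them as assembly error versus true rearrangement. The greedy
spacing fill and the scaffold consensus rule are heuristics, documented
above. Map orientation is resolved only relative to an external reference.
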