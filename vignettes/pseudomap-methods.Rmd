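---
title: "Methods: map-guided pseudomolecule construction and assembly evaluation"
author: "pseudomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map-guided pseudomolecule construction and assembly evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudomap)
```

# Scope and model

`pseudomap` implements the computational core of a genetic-map-guided genome
assembly project: evaluating competing assemblies of a diploid plant genome,
building a high-density linkage map from an F2 cross, anchoring scaffolds
along that map into chromosome-scale pseudomolecules, and the variant-level
filtering rules used for assembly error correction and SNP-array marker
design. Everything upstream of these steps — read assembly, read mapping,
variant calling, gene prediction, gene-family clustering — is out of scope;
the package consumes their tabular or FASTA outputs.

# Assembly statistics

For sequence lengths $\ell_1 \ge \ell_2 \ge \dots$ the Nx statistic is the
length $\ell_k$ at which $\sum_{i \le k} \ell_i$ first reaches $x\%$ of the
assembly total. NGx replaces the denominator with an externally estimated
genome size $G$, so assemblies of different completeness become comparable;
NG(x) for $x = 1..100$ traced as a curve (`ng_curve()`) visualises both
contiguity (height) and coverage (where the curve terminates). When the
cumulative sum never reaches $x\%$ of $G$, `ng()` returns 0 rather than an
error — that termination point *is* the information the curve carries.

Two reporting conventions needed pinning down because published tables use
them silently:

* **Means are floor-divided.** Published per-assembly mean lengths are
  reproducible as `floor(total/n)` (e.g. 504,793,233/8,910 = 56,654.68
  printed as 56,654). One cell in the same published table (131,037) is
  instead consistent with rounding; since both conventions cannot hold at
  once we follow floor, which the majority of cells and the clearest
  example pin down.
* **Coverage has two dialects.** `coverage_pct()` exposes `length`
  (assembly total / genome size) and `nongap` ((total − N bases) / genome
  size). Published per-assembly tables are consistent with the former and
  cross-species comparison tables with the latter; the package surfaces the
  choice instead of resolving it. Percentages are reported rounded half-up
  to one decimal.

**Telomere scan.** Plant telomeres are tandem arrays of `TTTAGGG`. A
terminus is called telomeric when a terminal window (default 1,000 bp)
contains at least `min_copies` (default 3) occurrences of the motif or its
reverse complement. The defaults are our choice, not taken from any source:
3 copies in 1 kb is permissive enough to catch degraded arrays while the
expected count of a random 7-mer in 1 kb (~0.06 per orientation) makes
chance calls negligible.

**k-mer genome size.** Given a k-mer multiplicity histogram, the haploid
genome size is estimated as $\sum_m m \cdot c_m / m^\*$ where $c_m$ is the
number of distinct k-mers at multiplicity $m$ and $m^\*$ is the modal
multiplicity — total sequenced k-mers divided by per-locus depth. Entries
below a cutoff (default 4) are excluded first so the sequencing-error peak
at multiplicity 1–2 cannot capture the mode. The cutoff is a convention of
ours; the simulation test (Poisson depth 30 over a known genome) recovers
the truth to well under 5% with any cutoff in 3–8.

# Linkage map construction

Input is an F2 genotype matrix with codominant calls (`AA`/`AB`/`BB`/`NA`).

**Missing-data filter.** Individuals and markers exceeding 10% missing data
are removed. Because removing a bad individual changes every marker's
missing fraction (and vice versa), the filter iterates, removing the single
worst offender — row or column — each round until the bound holds
everywhere. This removes no more than a greedy rule must.

**Recombination fraction.** For a marker pair, the likelihood is the
multinomial over the nine joint-genotype classes. Each class determines its
recombinant-gamete count except the double heterozygote, which mixes the
two-parental (probability $\propto (1-r)^2$) and two-recombinant
($\propto r^2$) configurations; the EM E-step allocates it accordingly and
the M-step sets $r$ to the expected recombinant fraction over $2n$ gametes.
Both phases are fitted (repulsion is coupling with one marker's dose
flipped) and the more likely kept. Convergence: absolute tolerance $10^{-8}$
on $r$, at most 1,000 iterations, deterministic start $r_0 = 0.25$. The LOD
is the base-10 log likelihood ratio against $r = 0.5$.

**Grouping** is connected components of the graph with edges where
LOD ≥ 3 and $r \le 0.35$ (conventional thresholds, exposed as arguments —
the underlying study reports only its outcome, eleven groups). Threshold
sensitivity is the user's to explore; a 50 cM marker gap with `r_max` set
too low will split a chromosome, and raising `r_max` merges it again.

**Ordering** minimises the sum of adjacent recombination fractions — a
travelling-salesman-path objective — by greedy nearest-neighbour chaining
refined with 2-opt moves. For eight or fewer markers the tests verify the
2-opt optimum equals the exhaustive-permutation optimum; at 50 markers with
realistic separations the simulated recovery is Kendall $\tau \ge 0.95$.
Orientation of a finished order is arbitrary, so the end with the smaller
marker id comes first; ties elsewhere break lexicographically.

**Distances.** Adjacent $r$ converts to cM by Kosambi (default, the common
choice in plant maps, modelling partial interference) or Haldane (no
interference). The simulator generates crossovers under Haldane, so
round-trip tests use Haldane for consistency; both are exposed because the
choice is a modelling judgement, not something the data pin down.

# Anchoring and pseudomolecule construction

**Probe placement** searches each 121-mer probe (SNP at the centre, 60 bp
flanks) exactly, both alleles, both strands, over all scaffolds. Only
uniquely and exactly matching probes (`n_hits == 1`) are used downstream —
a multi-copy flank cannot order anything.

**Misassembly detection.** Contradictions between assembly and map come in
two kinds, counted per scaffold (at most one record per scaffold per kind,
so the headline count is "contradicted scaffolds" — the counting unit is
our documented choice):

* *inter-LG chimera*: one scaffold carries usable markers from more than
  one linkage group;
* *order conflict*: within one group, the cM sequence along physical
  position, after collapsing runs of tied cM (ties carry no order
  information), is neither non-decreasing nor non-increasing. Either
  monotone direction is fine because scaffold strand is arbitrary.

Detection is deliberately conservative: with exact placements and a correct
map it cannot false-positive on a clean scaffold, which the clean-control
test asserts. The package only detects and reports; breaking chimeras at
inferred breakpoints requires read-level evidence it does not see.

**Anchoring.** Scaffolds are assigned to the LG of their markers and
ordered by median marker cM (robust to one misplaced marker; ties break by
scaffold id). Orientation comes from the sign of the Kendall rank
correlation between physical position and cM when a scaffold spans at least
two distinct cM values (distinct after rounding to 0.01 cM — below that,
markers are "tightly linked" and carry no orientation signal); otherwise
from a synteny hint table when provided; otherwise it is unknown, emitted
as `+` and flagged.

**Gap sizes.** The gap between adjacent scaffolds is the genetic interval
between the two junction-nearest markers times a global bp/cM ratio
(default: genome size / total map length — the conversion is otherwise
underdetermined), minus each scaffold's physical overhang beyond its
marker. Degenerate cases — tied cM, negative or undefined results — insert
the 1,000 bp N sentinel; positive estimates are clamped below at a 100 bp
minimum so components never abut. The sentinel path is the only part of
the gap rule that is bit-exact by construction; the estimate itself is
validated in simulation by its median relative error.

**AGP.** Pseudomolecules are emitted as FASTA plus AGP v2.0 (`W` component
rows, 1-based inclusive; `N` gap rows with linkage evidence `map`).
Internally all coordinates are 0-based half-open; conversion happens only
at emission. Every build asserts object length consistency, and the test
suite asserts that rebuilding FASTA from AGP + components is byte
identical. Unanchored scaffolds pass through unchanged as single-component
objects. LGs can be renamed to reference chromosome labels by majority
vote of shared markers (`relabel_groups()`), ties to the smaller label.

# Variant filtering rules

All thresholds live in `filter_config()` and all boundaries are inclusive,
read literally from the rules they implement: error sites require ≥10
high-quality reads (base quality ≥ 30 — the depth field of the input is
defined as counting only such reads; the upstream pileup is not
re-derived), alternate frequency ≥ 0.70 (≥ 0.90 for marker candidates,
which must also be homozygous), and no strand bias at Fisher p > 0.01. The
Fisher test is two-sided in the standard convention (sum of all
conditional table probabilities not exceeding the observed one); sidedness
is stated because "no strand bias" alone does not fix it. Allele frequency
is computed over the high-quality depth — implied but not stated by the
source rules, so documented here.

Marker candidates then pass flank screens: no other variant (either
parent) within ±60 bp; the 121-mer flank occurring exactly once in the
assembly — an exact-occurrence uniqueness screen standing in for a BLAST
screen, chosen because it is deterministic and dependency-free; and
cross-parent flank fixity. Each stage logs survivor counts. Selected
markers are thinned to ≥100 kb spacing by a greedy position-order sweep
(the earliest eligible candidate is also the one closest to the ideal
grid position, and first-fit maximises the count).

Homopolymer classification: an indel is homopolymer-associated when the
run of its inserted/deleted base touching the site is ≥ 4 (i.e. more than
three consecutive nucleotides). `apply_edits()` validates `ref` content,
applies right-to-left so coordinates stay valid, and returns both an
old-to-new coordinate map and the exact reverse edit set; the
reverse-application round trip is asserted byte-for-byte.

# Terminal-overlap merging

Scaffolding with long-insert pairs sometimes estimates a *negative* gap —
the bridged contigs' overhangs exceed the insert — which signals that the
contig ends actually overlap. `terminal_overlap()` compares the last 10 kb
of the left contig with the first 10 kb of the right: shared 21-mers vote
for diagonals, the best-supported diagonal band bounds the candidate
overlap, and only that bounded region is aligned (ends-free), never the
full 10 kb × 10 kb dynamic program. Identity is matches over alignment
columns — whether indel columns count in the denominator is a convention,
and ours includes them. A merge requires ≥500 aligned bases at ≥95%
identity reaching within 50 bp of the left end and right start. The merge
junction is the alignment midpoint (an arbitrary but deterministic choice);
for gap-free overlaps the merged length equals
$|L| + |R| - \text{aligned}$, asserted in tests together with equality of
the optimal alignment score against a full dynamic-programming oracle on
small windows. Contained near-duplicates (aligned over >98% of their
length at >98% identity to a longer sequence) are dropped, longest kept.

# Cross-assembly accounting

Gene-family size deltas take one assembly as reference and aggregate,
per other assembly, the families that grew and shrank and the gene totals
gained and lost; a singleton is a gene whose family has one member present
in exactly one assembly. The conservation identity (gained − lost = sum of
deltas) is asserted. Core-gene completeness is a plain percentage at
one-decimal reporting; where a published cell disagrees with its own
arithmetic (285/458 printed as 62.6%), the arithmetic (62.2%) wins.
Recombination tracks tile pseudomolecules into 1 Mb windows, interpolate
cM linearly between flanking markers (the windowing of the original
figures is unstated; linear interpolation is the least-assuming choice),
and report cM/Mb and cM/gene. The population-size rule inverts cM/gene:
one expected recombinant per gene interval among $2n$ gametes needs
$n = 100/d$ plants at $d$ cM/gene — reproducing the worked examples of
2,000 plants at 0.05 and 10,000 at 0.01.

# The synthetic data generator

`sim_config()` defines the study the tests run. It emulates the design of
a map-guided bean genome project — multiple linkage groups with
interspersed repeats and telomeric termini, SNP markers at controlled
spacing with unique 121-mer contexts, an F2 cross, a fragmented scaffold
set with planted defects, and two-parent variant tables with labelled
decoys — at a compressed physical scale. Default problem sizes are 2
linkage groups of 1 Mb with markers every 100 kb and 500 F2 individuals;
the genetic scale is kept realistic rather than the physical one
(`cm_per_mb = 50`, so a 1 Mb group spans ~50 cM like a real bean
chromosome and adjacent markers are ~5 cM apart). Genotyping error
(0.5%) and missingness (3%) sit at plausible SNP-array levels.

Crossovers are Poisson along the genetic map with uniform positions — the
Haldane no-interference model, the simplest process consistent with the
exposed map functions; interference is deliberately not modelled.
Repeats are exact copies from a small library (200–5,000 bp), enough to
create non-unique flanks for the filter tests without a repeat-evolution
model. Defects are planted so they are detectable *in principle*: chimera
partners must carry markers, inversions must span at least two distinct-cM
markers and leave one outside, and fragmentation cuts avoid marker flanks;
the defect log records exactly the realized defects.

What passing these tests shows — and does not. The generator produces
exact placements, complete marker coverage, and error processes that are
independent across calls. Real data add mapping ambiguity, segregation
distortion, clustered missingness and interference; recovery numbers from
the simulator (e.g. Kendall τ of marker order, map-length error) are
therefore contracts on the algorithms, not forecasts of field performance.
One visible instance: simulated maps overestimate total map length by
roughly 10–20% at the default error rate, the classic inflation of
genetic maps by genotyping error, which disappears when the error rate is
set to zero.

# Numerical and degenerate-input choices

* `ng()` returns 0 when the target is unreached (sentinel, not error);
  `nx()` on an empty set is an error.
* Sequences shorter than the telomere window are scanned whole.
* Reported percentages round half-up to 1 decimal; means floor.
* EM: tolerance $10^{-8}$, max 1,000 iterations, start 0.25; estimates are
  clamped to $[0, 0.5]$.
* Marker-order and scaffold-order ties break lexicographically by id; map
  orientation is fixed by the smaller terminal marker id.
* `estimate_gap()`: sentinel 1,000 for tied/negative/undefined, floor 100
  otherwise.
* Overlap alignment scoring: match 1, mismatch −2, gap open 4, extend 2;
  seeds k = 21, diagonal band ±50, terminal slack 50 bp.
* All generators reseed from `cfg$seed` (plus a fixed per-stage offset) at
  entry, so each stage is independently reproducible.

# Known limitations

* The EM estimator covers codominant F2 markers only — no dominant
  markers, backcrosses, or segregation-distortion tests.
* Chimeric scaffolds are detected and excluded, not broken and repaired.
* The global bp/cM ratio ignores local recombination-rate variation, so
  estimated gaps are systematically wrong in hot/cold regions; the
  sentinel path is unaffected.
* `drop_contained()` and `terminal_overlap()` use exact k-mer seeds, so
  containment/overlap below ~90% identity can escape the screen; the
  verification thresholds (98%/95%) sit far above that.
* Problem sizes in the tests (1–3 Mb genomes, hundreds of F2 plants) are
  chosen so the full suite exercises every path in minutes; the algorithms
  scale to real inputs but the suite does not exercise that scale.
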