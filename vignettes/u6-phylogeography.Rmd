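---
title: "Methods: haplogroup U6 phylogeography with u6phylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplogroup U6 phylogeography with u6phylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u6phylo)
```

`u6phylo` implements the computational machinery of a phylogeographic
analysis of mitochondrial haplogroup U6: variant-level haplotype handling,
motif classification, rho-statistic dating, a pedigree mutation-rate
estimator, Fisher wave-of-advance arithmetic, and regional
frequency/diversity statistics. This vignette records the models, the
parameter choices and their rationale, and what the package deliberately
does not do.

## Variants and haplotype profiles

All coordinates are 1-based positions on the rCRS (16,569 bp). A variant
token follows the PhyloTree/EMPOP grammar `digits [ "." index ] [ base | "d" ]
[ "!" ]`: a bare number is a transition, a trailing base a transversion, a
dotted index an insertion, `d` a deletion, and `!` a return to the ancestral
state (back-mutation). A profile is a *set* of variants plus the coordinate
range the underlying sequence actually covers; HVR-1 is taken as
16024–16365, the conventional bound for control-region surveys. Distances
between profiles are symmetric-difference counts on the intersection of
their ranges, which is the substrate of the pi statistic.

Two classes of records are parsed but excluded from distances and
classification by default (an `include_hypervariable` switch restores them):

* length variants of the poly-C tracts (insertions around 303–315 and
  16180–16195, and 16182C/16183C-type transversions) and position 16519 —
  these sites mutate so fast that they carry phylogenetic noise rather than
  signal, and forensic practice routinely sets them aside;
* IUPAC ambiguity codes such as `146Y` (heteroplasmy) — a mixed state is not
  a substitution event.

Whether such sites entered the original haplotype comparisons is not
recorded; exclusion is this package's explicit default, and every statistic
can be recomputed with them included.

## The shipped U6 tree and path-scoring classification

The default tree (`u6_tree()`) encodes the refined U6 phylogeny: every named
clade whose defining-mutation list is printed in the phylogeny description
carries exactly that motif (U6a1a1a2: 13071; U6a1b1b: 2158, 10336, 14034,
16145; …; U6b1: 9738, 15431; U6b1a: 2352, 16163; U6c2a: 3866), and the root
motif {3348, 16172} is the branch separating U6 from macro-haplogroup U.
Where an intermediate clade has no individually printed motif the tree is
path-compressed onto the nearest diagnosable ancestor, with three structural
choices worth recording:

* 16219 sits on an intermediate U6a'b'd node rather than the root, because
  the printed basic U6c haplotype (16129, 16169, 16172, 16189) lacks it;
* the 16189-sharing U6a2/U6a3/U6a8 branches hang off a joint U6a2'3 node
  (16189), and U6a8 carries 16189 in addition to its printed motif, as the
  phylogeny description states it shares that transition;
* U6b and U6d are sister branches that *each* carry the recurrent 16311 —
  exactly the ambiguity the HVR-1 sorting scheme resolves by downstream
  markers. Bare-16311 haplotypes are therefore intrinsically U6b/U6d
  ambiguous; the deterministic tie-break sends them to U6b, and U6d is called
  only when 16261 or 16174 co-occurs.

`classify_profile()` scores every root-to-node path as `matched − missing`
with unit weights, counting only defining variants inside the profile's
covered range. Unscoreable variants (outside the range) count neither way —
without this, no partial sequence could ever be classified. A back-mutation
motif is scored only when the profile carries the explicit `!` token;
otherwise it is unscoreable, and its phylogenetic effect surfaces as the
ancestor's plain variant being absent (a documented limitation for typical
input that never records `!`). Ties are broken by (1) fewest unscoreable
path variants, (2) greater depth, (3) lexicographic name. The first
criterion is deliberate: on an HVR-1 profile, a node's children whose
motifs are entirely coding-region would tie with their parent, and a
depth-first rule would claim resolution the data cannot support; preferring
the path with the least unscored baggage collapses the call to the deepest
clade with actual in-range support.

`classify_hvr1()` implements the eight-way sorting of control-region
haplotypes used for the regional table: U6c on {16169, 16189}; else U6d on
16311 with 16261 or 16174; else U6b1 on {16311, 16163}; else U6b on 16311;
else the four U6a bins split on 16189/16239/16235. The categories are
exhaustive and mutually exclusive by construction (property-tested over all
2^8 combinations of the diagnostic positions). The U6 membership
precondition is 16172 together with either 16219 or the U6c motif — the
disjunction is needed precisely because basic U6c haplotypes lack 16219.
Two known residual ambiguities are inherited from the scheme itself: U6a5
and U6a7 haplotypes fold into plain "U6a (16278)", and U6b3 carries 16278
(a U6a-bin marker) so its HVR-1 haplotypes sort with U6a.

## Rho dating and the Saillard standard error

For a node with N sampled descendants, rho is the multiplicity-weighted mean
number of mutations along each tip-to-node path, and its standard error is
the closed form

$$\sigma = \frac{1}{N}\sqrt{\sum_i l_i\, n_i^2},$$

summing over branches below the node (branch mutation count $l_i$, sampled
descendants $n_i$). Ages are linear in rho: `age = rho × years_per_mutation`
with the whole-molecule calibration of one mutation per 3,624 years as the
default. Two consequences of the linear clock: no purifying-selection
correction is applied (the calculator used in the original analysis applies
one, so published clade ages can differ from linear ages computed here), and
every event — transition, transversion, indel, back-mutation — counts as one
mutation, since the calibration is defined for the complete molecule without
event weighting.

The implementation is validated two ways: exact agreement with brute-force
path enumeration (an independent oracle built on `ape::dist.nodes` and
`phangorn::Descendants`) on 1,000 random trees of up to 12 tips, and
frequentist calibration — on 2,000 simulated 50-tip star trees of true age
10,000 years, the ±1.96 σ interval covers the truth in 95% ± 3% of
replicates. Those problem sizes keep the full suite under a minute while
leaving the binomial noise on the coverage estimate (≈ 0.5%) well inside the
tolerance.

## Pedigree mutation rate

k substitutions in T transmission events give the per-generation rate k/T.
For so few events the choice of exact interval matters, and published
single-event pedigree intervals are often quoted without a stated method —
the conventionally quoted 95% CI for 1/90 (0.0020–0.0616) is reproduced by
neither standard exact method, whose lower bounds for a single event sit
near 0.0003. The package therefore always computes both
the Clopper–Pearson exact binomial interval and the exact Poisson interval
and reports them side-by-side rather than forcing agreement. Conversions:
`rate/(L·G)·10⁶` per site per My (L = 16,569 bp; G = 20, 25 or 30 years,
with 25 recoverable empirically as (reference year − founding year)/
generations, e.g. (2000 − 1625)/15 = 25), and a division by two to undo the
male transmission bias when comparing against phylogenetic rates. Rates are
reported to 3–4 decimals and ages to the nearest year internally, thousands
in narrative output, matching the precisions the figures are usually quoted
at.

## Fisher wave-of-advance arithmetic

The reaction–diffusion relation r = 2√(gm) links the frontier speed r of an
expanding population to its growth rate g and migration rate m. The package
exposes the individual steps (`rate_of_advance`, `migration_rate`,
`advance_from_migration`, `node_gap_years`, `distance_from_gap`) and a
chained `fisher_wave()` object. Unrounded values propagate through chains;
rounding belongs to the reporting layer. One rounding subtlety is preserved
explicitly: the conventional derivation quotes the rate of advance to two
decimals (5,000 km / 9,000 yr → 0.56 km/yr) and inverts Fisher's relation
from that reported figure, giving m = 11.2 at g = 0.007/yr, whereas the
fully unrounded chain gives 11.0. `fisher_wave()` stores both (`m_reported`,
`m`); the radius computation, by contrast, uses the unrounded rate
(7,248 yr × 5,000/9,000 km/yr ≈ 4,027 km, "about 4,000"). Note also that
Fisher's m is dimensionally km²/yr; the km/yr figure is reproduced as
conventionally printed. The defaults — g = 0.007/yr (a Palaeolithic
hunter-gatherer growth rate) and a two-mutation node gap (the 3348/16172
branch separating U6 from macro-haplogroup U) — are the conditions the
analysis is built around.

## Regional statistics

The shipped 25-population HVR-1 frequency table stores the printed
percentage layout; ingestion converts percentages to counts by rounding the
U6 count against the sample size and apportioning category counts by largest
remainder so they always sum to the U6 count (re-validated on load).
Composition percentages are likewise apportioned on the 0.1 grid so every
row sums to exactly 100.0.

Pi diversity is the mean pairwise difference over all unordered pairs, with
the standard error from Tajima's total variance of the mean number of
pairwise differences — the form implemented by the commonly used diversity
software. Group comparisons use a two-sided permutation test of
|π_A − π_B| under label shuffling with the add-one p-value convention; the
original p-values came from an unstated procedure, so exact agreement is not
chased. Regional pi values themselves require the 761-sequence HVR-1
dataset and are out of scope; only the estimator is provided.
Gradient correlations are plain Pearson r with the two-sided t-test, and the
PCA standardises columns (correlation matrix) with a fixed sign convention
(largest-magnitude loading positive per component), since the original
software and scaling are unstated; the figure-level comparison is therefore
qualitative (cluster memberships), and the suite checks only that the
Canarian/Iberoamerican samples fall on the same PC1 side as the U6b1
loading.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their arguments with a mandatory seed:

* `simulate_star_tree()` — Poisson(l | true_age/clock) mutations per lineage
  on a star genealogy: exactly the sampling model under which rho/sigma are
  derived, hence the right substrate for calibration tests.
* `simulate_haplotypes()` — the union of defining variants down a chosen
  root path, back-mutations applied, optional Poisson private noise at
  positions drawn with a configurable HVR-1 weight (default the region's
  share of the molecule). Infinite-sites in spirit: recurrent hits occur
  only under the explicit noise flag.
* `simulate_pedigree()` — per-transmission Bernoulli mutations, so k is
  Binomial(T, rate) with events placed on transmissions.
* `simulate_region_table()` — Binomial U6 carriers, multinomial category
  counts.

None of these emulate recombination-free coalescent genealogies with
variable population size, rate heterogeneity across sites, sequencing error,
or phylogeographic sampling bias. Passing tests therefore demonstrate
internal correctness of the estimators and classifiers under their own
assumptions — not that real U6 data satisfy those assumptions.

## Degenerate inputs and numerical conventions

Zero-length branches give rho = sigma = 0; a node with zero sampled
descendants is an error. k = 0 pedigrees yield a one-sided upper bound.
Empty motif files produce header-only output with exit 0. A profile whose
range contains no diagnostic position of any node classifies to the root
with a warning flag rather than an arbitrary clade. Constant columns are
dropped (with a warning) before PCA; zero-variance vectors make the gradient
correlation an explicit flagged undefined rather than NaN. CSV output is
comma-separated UTF-8 with a header and `.` decimals; Newick uses integer
branch lengths with `*count` tip multiplicities; run manifests carry no
timestamp so identical runs are byte-identical.

## Known limitations

* Published clade ages incorporating a purifying-selection correction are
  not reproduced by the linear clock (by design).
* Back-mutation motifs are invisible in input that lacks explicit `!`
  tokens beyond the induced "missing ancestor variant" signal.
* Bare-16311 HVR-1 haplotypes cannot be split between U6b and U6d; the U6b3
  16278 clash with the U6a bins is inherited from the sorting scheme.
* The tree is an encoding of a published phylogeny, not an inference engine:
  no median-joining or parsimony construction is included.
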