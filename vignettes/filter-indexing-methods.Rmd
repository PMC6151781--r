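---
title: "Range-filter bioactivity indexing: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-filter bioactivity indexing: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iseScreen)
```

# The model

iseScreen builds ligand-based screening models for the common asymmetric
situation in early drug discovery: a small class of known actives (on the
order of 100 molecules) against a large library of putative inactives (on
the order of 3000), each molecule described by a wide pool of numeric 2D
physicochemical descriptors. A model is an ensemble of *range filters*. A
filter is a conjunction of closed intervals over a handful of descriptors;
a molecule passes iff every named value lies inside its interval. Both
interval ends are included — ranges that pin a count descriptor to a single
value (low = high) are legitimate filters, which an open-ended convention
would silently empty.

Two assumptions are load-bearing. First, activity is *range-expressible*:
the actives concentrate inside an axis-aligned box in some low-dimensional
descriptor subspace, while inactives spread more broadly. Second, the
inactive set is only *putatively* inactive; a percent-scale contamination
with true actives shifts pass rates by at most that amount and is tolerated
by the rate-based objective below.

## Filter quality: rate-based MCC

A filter's confusion behaviour is summarized by class-conditional
percentages: PA (actives passing), PNA (inactives passing) and their
complements NA, NNA. `rateMCC()` computes the Matthews correlation
coefficient of the *normalized* confusion matrix (tp = PA/100, fp =
PNA/100, fn = NA/100, tn = NNA/100). On the ~1:30 class imbalance above,
the count-based MCC is dominated by the inactive class and shrinks
severely; the rate-based form weighs both classes equally, keeps per-filter
quality on a stable scale across datasets, and is the optimization
objective throughout. `countMCC()` is provided for comparison, and a test
documents how far the two diverge at realistic imbalance. A degenerate
denominator (an all-pass or all-fail filter) is defined as MCC 0.

## The MBI score

A screened molecule's Molecular Bioactivity Index is the ensemble average

$$\mathrm{MBI} = \frac{1}{n}\sum_{i=1}^{n}\left(\delta_{A_i}\,
\frac{PA_i}{PNA_i} - \delta_{NA_i}\, \frac{NNA_i}{NA_i}\right)$$

with $\delta_{A_i} = 1$ iff the molecule passes filter $i$. The reward
PA/PNA is the filter's efficiency factor for actives. Two penalty
orientations circulate for the failure term; both are implemented and the
trained model records which one it uses:

* `nna_over_na` (default): penalty $NNA_i/NA_i$. With filters of realistic
  efficiency (PA in the 60–90 range, NNA in the 75–95 range) the score
  floor — a molecule failing everything — has magnitude around 4, matching
  the published behaviour of models of this family.
* `na_over_nna`: penalty $NA_i/NNA_i$, giving floors an order of magnitude
  smaller (≈ 0.4). Selectable for comparison; never chosen silently.

Zero denominators arise when a filter passes no training inactive
(PNA = 0) or no training active fails it (NA = 0). Rather than capping the
ratio, the zero rate is replaced by the half-count pseudocount
$100\cdot 0.5/N$ of the relevant class (N from the training metadata),
which keeps efficiency factors finite and monotone in the evidence: a
filter that rejected all of 2000 inactives earns a larger reward than one
that rejected all of 20.

# The ISE search

The optimizer learns where the activity box lies. Its search space is
discrete: candidate interval bounds for each descriptor are percentile
pairs of the *active-class* distribution — lower grid {0, 2.5, 5, 10, 25},
upper grid {75, 90, 95, 97.5, 100} (percent), i.e. at most 25 candidate
ranges per descriptor. Actives define the box; inactives influence the
search only through scoring. A solution is a choice of `filterSize`
(default 4) distinct descriptors plus one candidate range each.

Each iteration samples `sampleSize` (default 2000) solutions uniformly
from the surviving space, scores them by rate-MCC on the training split,
and ranks them. A (descriptor, range) value is *eliminated* when it is
absent from the top `topFraction` (5%) of solutions and more than
`elimFraction` (50%) of its appearances fall in the bottom 50%. With a
sparse sample over a large value space this indicts a value even on a
single bottom-half appearance; the top-5% protection, the recomputation on
pooled restarts and the final exhaustive stage make single unlucky
eliminations cheap, while the aggressive rule keeps the iteration count
low. If an iteration eliminates nothing, the worst-scoring unprotected
value is force-dropped, so the loop provably contracts; values protected by
the current top solutions are never eliminated in that iteration. Once the
surviving space holds at most `exhaustiveLimit` (1e5) solutions it is
enumerated exhaustively — spaces that start below the limit skip sampling
entirely, which is also what makes the optimizer provably equal to
brute-force search on small instances (a property the tests check against
an independent enumeration oracle).

Solution scoring is the hot path and is implemented in compiled code: each
candidate value's pass vector over the training molecules is precomputed
once and bit-packed into 64-bit words, so scoring a 4-condition filter is
three word-wise ANDs and a popcount per 64 molecules.

An ensemble is assembled from `restarts` (default 100) independent runs:
pooled filters are re-scored on the full training split, deduplicated on
(descriptor set, ranges) to 1e-9, floored at `mccFloor` (default 0.55) and
capped at `maxEnsemble` (default 50), with deterministic tie-breaking
(score, then fewer conditions, then lexicographic names). Every stochastic
step flows from one user-visible seed; identical configuration and seed
reproduce the ensemble bit for bit.

The training fraction is 2/3 with round-half-up class sizes — 97 actives
split 65/32 — stratified per class and disjoint by construction; the
held-out third never reaches the optimizer.

# Descriptors: an analog registry

Descriptor tables can be imported unchanged from CSV (names are opaque,
case-sensitive strings, so externally computed tables drive the model
as-is), or computed in-package from SMILES. The built-in registry holds
over 100 documented analogs of the descriptor families that dominate
range-filter models; they are *analogs*, not reimplementations of any
commercial package, and the learning/scoring core is descriptor-source
agnostic because models store only names.

Choices worth knowing:

* Parsing and bulk properties (MW, logP, molar refractivity, TPSA, HBD,
  HBA, canonical SMILES) come from OpenBabel via ChemmineOB. OpenBabel
  silently repairs malformed SMILES, so a syntactic validator (balanced
  parentheses/brackets, paired ring closures, legal symbols) runs first
  and rejections are reported per line. Molecules without a single bond
  (e.g. bare ions) are rejected and reported — a known limitation.
* Partial charges are Gasteiger–Marsili PEOE (8 damped iterations,
  hybridization-resolved parameters, implicit hydrogens as pseudo-atoms,
  their charge folded into the heavy atom).
* Per-atom van der Waals surface areas use a Labute-style cap-subtraction
  approximation on Bondi radii with idealized bond lengths
  (0.85·(r_i+r_j)). Charge bins (`PEOE_VSA±k`, width 0.05), coarse atomic
  logP bins (`SlogP_VSA0–9`) and refractivity bins (`SMR_VSA0–7`) sum
  these areas over atoms falling in each property bin.
* `BCUT_*_0–3` are quartiles of Burden-matrix eigenvalues (diagonal =
  atomic property, 0.1·bond order off-diagonal, 0.001 elsewhere);
  `GCUT_*_0–3` replace the off-diagonal with inverse-square topological
  distance.
* `logS` is an ESOL-style linear estimate
  (0.16 − 0.63·logP − 0.0062·MW + 0.066·RB − 0.74·AP).
* `Chiral` counts carbons with four distinct one-bond substituent
  signatures — a deliberately local approximation that misses centers
  distinguishable only at longer range; `Chiral_u` subtracts stereo marks
  present in the input SMILES. `Reactive` counts matches of a small SMARTS
  registry (acyl/sulfonyl halides, aldehydes, peroxides, azides,
  diazonium, iso(thio)cyanates, anhydrides).
* `prunePool()` removes constant and duplicate columns before a search, so
  the optimizer never wastes eliminations on dead dimensions.

Diversity profiling uses OpenBabel FP2 hashed path fingerprints (1024
bits; the scheme is recorded on every result and cross-scheme comparisons
are refused). Two all-zero fingerprints have Tanimoto similarity 1 by
documented convention. Lipinski violations are counted against MW ≤ 500,
logP ≤ 5, HBD ≤ 5, HBA ≤ 10 with "obeys" meaning at most one violation
(the rule's conventional reading); lead-likeness uses the MOE-style clause
set (MW ≤ 450, logP in [−3.5, 4.5], rings ≤ 4, rotatable bonds ≤ 10,
HBD ≤ 5, HBA ≤ 8, zero violations to pass) — definitions of this rule vary
across the literature and this one is an explicit, documented choice.

# Evaluation statistics

* ROC curves come from a descending-score sweep in which tied scores move
  as one block; the trapezoidal area then equals the Mann–Whitney
  probability with ties half-credited (tests verify this equivalence
  against brute-force pair counting and against pROC).
* Enrichment factors divide the captured-active fraction within the top
  ⌈f·N⌉ ranks by f. Molecules tied across the cutoff are attributed
  fractionally (block-averaged) — deterministic and unbiased where a
  random tie-break would not be. EF at f = 1 is exactly 1.
* The MCC-vs-threshold curve evaluates tp%, fp% and rate-MCC on 200
  uniform grid points plus every observed score; below the minimum score
  everything is classified active and the MCC degenerates to 0.
* Descriptor-appearance enrichment relates a descriptor's condition count
  across the ensemble to the uniform expectation (total slots / pool
  size), reported at full precision plus the 1-decimal rounding used for
  display.

# The synthetic benchmark

`generateBenchmark()` provides the study conditions for every seeded test:
97 actives vs 2892 inactives over 186 descriptors, 6 informative, planted
box width 0.25 of the descriptor range, 5% of active draws outside their
box. Inactive values are i.i.d. uniform per descriptor over fixed ranges;
uniform (rather than Gaussian) marginals are chosen deliberately so that
pass rates have closed-form expectations — a planted box passes an
inactive with probability exactly its width fraction — giving analytic
oracles for every downstream stage. Actives share the inactive
distribution on uninformative descriptors, so irrelevant columns carry
strictly no signal.

What the generator does *not* emulate: correlated descriptor structure,
heavy-tailed or discrete descriptor marginals, activity cliffs, or any
real chemistry (no SMILES are generated). Passing the synthetic
end-to-end checks therefore demonstrates that the optimizer recovers
axis-aligned range structure under noise at realistic dimensionality — not
that any particular real screen will reach the same numbers.

# Problem sizes and numerical choices

Percentiles use R's default type-7 interpolation. Splits round half up.
JSON models serialize doubles at 17 significant digits, making write/read
round-trips exact. The test suite runs the heavier seeded experiments at
sizes chosen to keep the whole suite in the minutes range on one core:
optimizer-vs-oracle equivalence on 50 tiny instances, planted-descriptor
recovery over 20 runs of a 50-descriptor/2-informative benchmark, and one
end-to-end default-size run with 6 restarts (ensembles saturate well below
the 100-restart default; additional restarts add filters but change
held-out AUC only marginally on this benchmark).

# Known limitations

* Descriptor values are analogs; models trained on tables from other
  software are fully supported, but mixing computed-here and
  computed-elsewhere values of the "same" descriptor is not meaningful.
* Single-atom and multi-fragment edge cases: bond-less records are
  rejected; fragment counts (`Nmol`) treat dot-disconnected SMILES as one
  record.
* The elimination rule is one concrete, reproducible variant of the ISE
  idea; other variants (protecting more of the elite, slower elimination
  schedules) trade runtime against search thoroughness and can be emulated
  through `IseConfig`.
* Formal-charge handling in descriptor computation covers common
  protonation states; exotic valences fall back to defaults and are worth
  checking when importing unusual libraries.
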