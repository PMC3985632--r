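---
title: "Reconstructing 3D chromosome structures from Hi-C contact data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D chromosome structures from Hi-C contact data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromo3d)
```

## The problem

Hi-C experiments count, genome-wide, how often pairs of genomic loci are
captured in spatial proximity. Binned at a fixed resolution (say 1 Mb), a
chromosome's intra-chromosomal reads form a square interaction-frequency
(IF) matrix. chromo3d reconstructs a *preferred* 3D conformation of the
chromosome directly from that matrix: each bin becomes one point (the bin
midpoint), the chromosome is the piece-wise linear curve through the points
in genomic order, and the configuration is chosen to satisfy as many
observed contacts and non-contacts as possible. Centromere bins, which
receive no mappable reads, are excluded from the model.

Working directly on contacts distinguishes this approach from
distance-based reconstruction: interaction frequencies are never converted
into target distances, which avoids committing to an uncertain IF-distance
transfer function. The price is that the data constrain each pair only
through a classification (closer than the contact threshold, or not), so
the geometry is identified only up to whatever the contact pattern implies
— including the well-known mirror ambiguity, handled at evaluation time.

## From raw counts to constraints

**Normalization.** The raw matrix `C` is corrected by the marginal-product
(observed/expected) null:

$$N_{ij} = \frac{C_{ij}}{m_i\,m_j / T},$$

with `m_i` the total interaction count of bin *i* and `T` the grand total.
`N_ij` is a likelihood ratio — how much more often the pair interacts than
expected from its coverage. The transform is invariant to global scaling
of the counts and the expected matrix preserves the marginals. Bins with
zero marginal carry no information and are masked (flagged unmodeled).
More elaborate bias models (iterative correction and the like) are
deliberately out of scope.

**Cutoff filtering.** A pair `(i, j)` with `i + 1 < j` becomes a *contact*
when `N_ij` strictly exceeds a cutoff, otherwise a *non-contact*. The
calibrated cutoffs are 0.66 at 1 Mb (normal B-cell data), 2.0 at 200 kb
and 0.5 for the leukemia B-cell data; `contact_percentages()` supports
choosing a cutoff on new data by inspecting how many pairs survive — on
real genomes the guiding feature is that chromosome territories should not
appear entangled, a judgment the package reports on but does not automate.
Consecutive pairs `(i, i+1)` bypass the cutoff: the adjacency term of the
objective governs them. The exception is a pair of modeled bins flanking a
centromere gap — the physical linker between them is not modeled, so they
are classified by the cutoff like any distant pair.

## The objective

With squared distances $d^2_{ij}$ between bin midpoints, the score being
maximized is

$$F = \sum_{\text{contacts}} \left[ w_{ij} W_1 \tanh(d_c^2 - d^2_{ij}) + W_2 \tanh(d^2_{ij} - d_{min}^2) \right]
  + \sum_{\text{non-contacts}} W_3 \left[ \tanh(d^2_{ij} - d_c^2) + \tanh(d_{max}^2 - d^2_{ij}) \right]
  + \sum_{\text{adjacent}} W_4 \left[ \tanh(d_{maxadj}^2 - d^2_{ij}) + \tanh(d^2_{ij} - d_{min}^2) \right]$$

Each tanh term smoothly rewards being on the right side of a threshold and
is bounded in (−1, 1), which keeps the objective differentiable
everywhere and every constraint's influence finite. Contacts are pulled
inside the contact threshold $d_c$ but kept apart by the minimum distance
$d_{min}$ (excluded volume); non-contacts are pushed outside $d_c$ but
kept inside the territory bound $d_{max}$; adjacent bins stay within bond
range $d_{maxadj}$. The contact weight $w_{ij} = N_{ij}/\max_{kl} N_{kl}$
makes high-likelihood contacts dominate (a `weight_denominator = "total"`
variant divides by the total IF instead).

### Parameters and units

Distance thresholds are stored as *squared* distances (the
squared-distance convention): the 1 Mb contact threshold is $d_c^2 = 7$,
consistent with reported violation statistics in which the average squared
distance of unsatisfied contacts sits just above 7 while unsatisfied
non-contacts sit just below it. Model units are nominally micrometers via
the FISH calibration that produced the thresholds. Defaults:

| parameter | 1 Mb | 200 kb | meaning |
|---|---|---|---|
| `dc2` | 7.0 | 4.5 | squared contact threshold |
| `dmin2` | 0.04 | 0.02 | squared minimum separation |
| `dmaxadj2` | 1.5 | 1.0 | squared adjacent-bin bound |
| `dmax2` | 20 | 20 | squared territory bound |

The 200 kb minimum and adjacency values follow the published calibration;
the corresponding 1 Mb bounds are less tightly pinned by the available
distance measurements beyond sitting *above* the 200 kb ones, so the
package fixes them slightly higher (0.04 and 1.5). A
`threshold_convention = "linear"` switch squares the stored values before
use, for users who read the calibration as linear distances.

The term weights $W_1..W_4$ default to 1. On maps with heavy-tailed IFs
(any real Hi-C map, or the graded synthetic model), $w_{ij}$ is tiny for
most contacts and the contact term is then dominated by the unit-weight
terms — reconstruction quality collapses. The published protocol tunes the
weights per chromosome around the average IF until contact and non-contact
scores balance; `calibrate_weights()` packages the same idea as a single
deterministic rescale of $W_1$ so the mean effective contact weight equals
1 (or any chosen target). Raising $W_1$ further trades non-contact score
for contact score, and vice versa for $W_3$; that trade-off is left to the
user.

## Optimization

Structures are initialized with all coordinates i.i.d. uniform on
(−0.5, 0.5) and improved by steepest gradient ascent with a backtracking
(Armijo) line search. Two numerical choices matter:

* **Normalized ascent direction.** The step is taken along the *unit*
  gradient direction, so the line-search step is a displacement in model
  units (default start 0.2, halved on rejection, restarted at twice the
  last accepted step). Stepping along the raw gradient instead lets the
  first accepted steps throw the expanding structure deep into the
  saturated tail of the tanh terms, where the restoring gradient vanishes
  and unsatisfied contacts freeze at large distance; on synthetic
  instances this collapses contact scores from above 0.95 to below 0.2.
* **Stopping rule.** Ascent stops when the relative improvement stays
  below 1e-8 for 40 consecutive iterations (or at 10,000 iterations, or
  when the line search underflows at a stationary point — reported, not an
  error). Every accepted step satisfies the sufficient-increase condition,
  so the objective trace is non-decreasing by construction and is returned
  with the fit.

An ensemble (`build_ensemble()`, default 300 members as in the published
protocol) runs independent seeds `seed, seed + 1, ...`; the whole pipeline
is a pure function of the constraint set, parameters and seeds.

## Evaluation and model selection

`score_structure()` reports the contact score (fraction of contacts with
$d^2 < d_c^2$), the non-contact score (fraction of non-contacts with
$d^2 \ge d_c^2$), the percentage of total IF carried by satisfied
contacts, and violation statistics (average squared distance and average
IF of the unsatisfied pairs).

Structural similarity uses GDT-HA adapted to chromosome scale: after one
global least-squares (Kabsch) superposition, the fraction of index-matched
points within 2.0, 1.5, 1.0 and 0.5 model units is averaged. Because
contact data cannot distinguish a structure from its mirror image, the
score is mirror-aware by default: the reflected partner is also scored and
the better value returned. The superposition is a single proper rotation
(chirality-preserving); the protein-style fragment search is intentionally
not reproduced, keeping the score deterministic.

The representative model of an ensemble is the exact medoid under the
distance `1/GDT-HA` (floored at 1e-6; a `1 − GDT-HA` variant is
available). With one cluster, K-medoids reduces to this exact search — no
iterative PAM, no tie-break ambiguity beyond lowest index.

`robustness_test()` re-fits after withholding a fraction (default 30%) of
the contacts *as non-contacts* and reports how many withheld contacts the
model nevertheless satisfies. Recovered contacts concentrate at high IF:
in the packaged replicates the pooled recovery rate rises monotonically
across IF quartiles. Two caveats discovered while building the test are
worth recording. First, recovery rewards geometric implication *against*
the training labels, so it cannot be expected to exceed the recovery of a
random structure occupying the same territory — in a dense-contact regime
a volume-matched random placement trivially "recovers" withheld contacts
at the marginal contact rate. Second, a baseline drawn from the same
generator as the truth is a draw from the truth's own prior and is
stronger still. The acceptance suite states the random-placement
comparison anyway and documents its failure rather than weakening it.

## Compartments

The two-compartment (A/B, euchromatin/heterochromatin) organization is
detected as the sign of the first principal component of the
column-centered normalized map, by default after a Pearson-correlation
transform (which also makes the assignment invariant to symmetric
row/column scaling). The PC sign is fixed deterministically (the largest
absolute loading is made positive) and near-degenerate spectra are
flagged. Labels are neutral {1, 2}: deciding which side is euchromatin
needs external covariates (gene density, GC) that are out of scope.
`compartment_profiles()` reproduces the distance/IF-versus-separation
summaries within and between compartments, and `color_structure()` writes
the labels into the B-factor column of a PDB trace for visualization.

## The synthetic generator

Because the real calibration data are external, every stage is tested
against synthetic ground truth (`make_instance()`):

* `random_walk` — a fixed-step (1 unit) walk reflected inside a
  confinement sphere. The default radius is $\sqrt{d_{max}^2}/2 =
  \sqrt{20}/2 \approx 2.24$, so the simulated territory respects the
  model's own territory bound; with $d_c^2 = 7$ this reproduces the dense
  intra-chromosomal contact regime of 1 Mb maps (roughly 75–90% of pairs
  in contact, against a reported 77% for a mid-size chromosome). The step
  length keeps adjacent bins within the adjacency bound.
* `helix` — deterministic, for exactness tests (equal consecutive
  distances, no seed).
* `two_blob` — two Gaussian clusters joined in sequence, the minimal
  two-compartment caricature.

IFs are either `binary` (count 1 exactly when the true squared distance is
below `dc2` — cutoff filtering then recovers the true contact partition
exactly) or `inverse_distance` (expected count $\propto 1/d^2$, capped at
close range). The `noise` parameter scales Poisson dispersion around the
same expectation (`noise * rpois(mean/noise)`); 0 gives the deterministic
expectation. For graded IFs, thresholding the *normalized* map cannot
reproduce the true geometric partition (the marginal correction distorts
the IF-distance relation), so `true_constraints()` builds the constraint
set with truth-derived labels and IF-derived weights — the fixture used
wherever label noise would confound what is being tested.

What the generator does *not* emulate: real coverage biases, restriction
fragment structure, TADs and loops, inter-chromosomal contacts, or
polymer physics beyond chain connectivity and confinement. Passing the
synthetic suite therefore demonstrates correctness of the machinery and
recoverability under the method's own assumptions, not performance on
real nuclei.

## Problem sizes and determinism

The shipped tests and the acceptance script use instances of 10–50 bins,
ensembles of 10–20 and 10–20 replicates per property; at these sizes the
whole suite completes in a few minutes on one core while leaving the
conclusions statistically stable. Real 1 Mb chromosomes (≈50–250 bins,
ensembles of 300) run in minutes to hours with the same code paths. All
randomness flows through explicit seeds; reruns are bit-identical, and
seeded helpers restore the caller's RNG state.

## Known limitations

* Contacts constrain geometry only through threshold classifications:
  instances exist (and appear among the test seeds) whose contact graph
  admits genuinely different embeddings, mirror substructures being the
  common case. Ensemble consensus mitigates but cannot remove this.
* The observed/expected normalization is the simple marginal model by
  design; maps with strong unmodeled biases need external correction
  first.
* Inter-chromosomal modeling, whole-genome assembly of per-chromosome
  models, and biological interpretation of compartment polarity are out
  of scope.
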