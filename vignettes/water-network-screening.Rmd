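---
title: "Water-network hot spots and fragment screening: methods and design notes"
author: "twnscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-network hot spots and fragment screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twnscreen)
```

# The model

Explicit waters in a protein binding pocket form transient hydrogen-bonded
cyclic networks. Four-membered rings are a convenient probe of binding hot
spots: they are about the size of a drug fragment, usually close to planar,
and they recur at specific sub-sites across a trajectory of a restrained,
ligand-free protein. This package operationalises that observation in three
stages — detect rings per frame, group recurrent rings across frames, and
screen docked fragment poses against the grouped networks by shape and
location.

## Hydrogen-bond criterion

Two rigid three-site waters $a$ and $b$ interact with

$$v(a,b) \;=\; \sum_{i \in a}\sum_{j \in b} \frac{q_i q_j e^2}{r_{ij}}
\;+\; \frac{A}{r_{oo}^{12}} \;-\; \frac{C}{r_{oo}^{6}},$$

nine Coulomb terms over the O/H/H interaction sites plus one Lennard-Jones
term between the oxygens. The parameters are the TIP3P values
($q_O = -0.834\,e$, $q_H = +0.417\,e$, $A = 582000$ kcal Å$^{12}$ mol$^{-1}$,
$C = 595$ kcal Å$^{6}$ mol$^{-1}$), matching the water model of the
simulations the method consumes. A pair is hydrogen bonded when
$v \le -2.25$ kcal mol$^{-1}$, the minimum of the water pair-energy
distribution; the comparison is *inclusive*, and hydrogen positions are
taken from the file rather than idealised (the model is rigid, so frames
from a rigid-water simulation carry exact geometry).

The Coulomb conversion constant is not fixed by the published equation; we
use $e^2 = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$, the CHARMM convention, for
consistency with the force-field family the frames come from. It is a
visible field of `energyParameters()`.

## Neighbour cutoff: why 4.5 Å and not less

Evaluating all water pairs per frame is wasteful; pairs whose oxygens are
far apart cannot be hydrogen bonded. The safe radius is larger than
intuition suggests: numerically minimising $v$ over all mutual orientations
gives approximately

| $r_{oo}$ (Å) | 3.6 | 3.8 | 4.0 | 4.2 | 4.4 |
|---|---|---|---|---|---|
| best $v$ (kcal/mol) | −3.45 | −2.90 | −2.46 | −2.11 | −1.82 |

so orientation-favourable pairs can satisfy the −2.25 criterion out to
$r_{oo} \approx 4.1$ Å. The default cutoff is therefore **4.5 Å**, beyond
the bound with margin; the test suite verifies on random frames that the
cutoff reproduces the exhaustive all-pairs edge set exactly. A tighter,
seemingly natural choice such as 3.6 Å silently drops bonded pairs (the
suite constructs such pairs), which would make the optimisation lossy.

## Ring enumeration

Rings are simple cycles of exactly four distinct waters in the per-frame
hydrogen-bond graph. Two conventions matter and are fixed here:

* **Chords are permitted.** A 4-clique contributes its three distinct
  cyclic pairings; no chordless ("induced cycle") condition and no
  planarity filter is applied.
* **Canonical order.** Each (vertex set, cyclic pairing) is reported once,
  rotated/reflected to start at the smallest molecule id with the smaller
  of its two neighbours second. This makes ring identity deterministic and
  order-independent.

Rings whose oxygen centroid lies within the binding-site sphere (default
20 Å — wide enough to cover a full kinase pocket around an anchor such as
the DFG motif, see `siteCenterFromResidues()`) are kept; the boundary is
inclusive and membership is judged by the centroid, the least ambiguous
single-point criterion.

## Grouping recurrent rings

Grouping runs on oxygen positions only; no energies are re-used.

1. **Grid.** All ring oxygens are indexed on a 0.5 Å grid. Cells are
   half-open; the origin is the componentwise minimum snapped down to a
   multiple of the spacing. The origin is arbitrary, which is acceptable
   because the linkage criterion spans a ±1-cell neighbourhood; the tests
   shift all coordinates by half a cell and require the identical
   partition.
2. **Primary grouping.** Two rings link when a one-to-one correspondence
   of their four oxygens exists with every matched pair inside each
   other's extended zone (the own cell ±1 per axis). Cyclic order is *not*
   trusted across frames — waters exchange roles — so the correspondence is
   found by exact minimum-cost assignment over the 24 permutations.
   Groups are connected components; the chosen correspondences propagate
   along a spanning forest so every member ring contributes exactly one
   oxygen to each of the four clusters.
3. **Cluster centers.** DBSCAN runs on each oxygen cluster; the center is
   the mean of the largest cluster, outliers are ignored, and an all-noise
   result falls back to the plain mean with a warning. The upstream
   literature cites DBSCAN without parameters; we default to
   $\varepsilon = 1$ Å and `minSamples = 1` (every point is then a core
   point, making the step a conservative single-linkage consolidation) and
   expose both knobs.
4. **Secondary grouping.** Primary groups whose four centers can be
   matched pairwise within 1 Å (inclusive, again by optimal assignment)
   merge; merging is transitively closed, i.e. single linkage, which is
   the natural closure of a pairwise "within 1 Å" rule. Merged groups pool
   their oxygen clouds slot-wise and *re-derive* centers from the pooled
   points rather than averaging the old centers — the two differ when
   member counts are unequal, and pooled re-derivation uses all the data.
5. **Planes.** One total-least-squares plane per member ring (SVD of the
   centered 4-point set; normal = smallest singular vector, sign fixed
   toward positive z, then y, then x). Collinear point sets raise a
   degenerate-geometry error. Per-ring planes, not one average plane, are
   what the distance score runs over.

Occupancy (members / frames analysed) is reported per group; grouping is
purely geometric and never weights by interaction energy.

## Scoring fragment poses

Both scores are computed **in the shared laboratory frame**, with no
rotation or translation of either side — the location of the water network
is the signal. Consequently fragment poses must be docked against the same
coordinates the frames use; the screen only warns (bounding-box check) if
the two clouds are implausibly far apart.

**Shape.** Atom $i$ carries the spherical Gaussian
$\rho_i(r) = p\, e^{-\alpha_i (r - R_i)^2}$ with a common amplitude
$p = 2\sqrt2$ and $\alpha_i = \pi \left(3p/(4\pi r_i^3)\right)^{2/3}$, the
standard calibration that makes the Gaussian enclose the volume of a hard
sphere with the element's van der Waals radius $r_i$ (O 1.52, C 1.70,
N 1.55, S 1.80, H 1.20 Å, halogens per the usual table). Overlaps use the
closed-form Gaussian product integral, and similarity is the Hodgkin index
$2 O_{AB}/(O_{AA}+O_{BB}) \in [0,1]$ — the normalisation shape-matching
tools report for field overlaps; a min/max alternative sits behind
`shapeParameters(normalization = "minmax")`. The grouped network enters as
its four cluster centroids treated as oxygen pseudo-atoms (default) or as
all member oxygens (`representation = "members"`); the fragment enters as
its heavy atoms only, hydrogens being both noisy in docked poses and
irrelevant to a water-sized envelope.

**Distance.** The unsigned orthogonal distance from the fragment's
heavy-atom centroid to each member ring's plane, averaged over the group's
rings so that heavily and sparsely populated groups are comparable.

**Thresholds.** A pose passes a group at $S \ge 0.6$ and $D \le 0.5$ Å,
both inclusive; a pose is *screened* when it passes at least one group in
the queried region. `thresholdSweep()` reproduces the surrounding
sensitivity grid ($S \in \{0.5, 0.6, 0.7\}$, $D \in \{0.3, 0.5, 1.0\}$)
whose screened sets nest monotonically.

# The synthetic generator

`plantedSite()`/`makeFrames()` emulate the one property the pipeline
needs: rings that recur at fixed sub-sites in co-registered frames,
surrounded by unstructured solvent. Each site is a square of oxygens with
half-diagonal 1.98 Å (O–O edge ≈ 2.8 Å, the bottom of the hydrogen-bond
well), re-planted every frame with isotropic Gaussian jitter and an
occupancy probability. Hydrogens lie in the ring plane: each water donates
toward the next oxygen and holds its free hydrogen rotated 104.52° away
from the ring interior — the orientation that minimises the consecutive
pair energies (−6.13 kcal mol$^{-1}$ per edge at zero jitter, comfortably
below −2.25; a naive out-of-plane free hydrogen yields only −1.35 and
would not even bond). The fixture's validity is *recomputed* in the tests,
never assumed. Noise waters are uniform in the box with random rigid
orientations, rejected within 4 Å of any planted oxygen so that noise
neither perturbs nor spuriously extends the planted networks.

`demoSites()` places five sites with centers about 8 Å apart and varied
plane orientations. Recovery is only well-posed for clearly separated
sites: at 4 Å center spacing neighbouring rings would physically
interleave (the ring half-diagonal is already 1.98 Å), so the demo keeps a
wide margin. Default study conditions, used by the acceptance script and
the heavier tests, are 200 frames, 0.1 Å jitter, 30 noise waters per
frame — large enough for stable statistics, small enough that the full
pipeline runs in well under a minute on one core.

What the generator does **not** emulate: bulk water structure, dynamics or
thermodynamics, competing 3- or 5-membered networks, protein atoms, or
docking noise. Passing the planted-recovery tests therefore demonstrates
the pipeline's correctness and stability, not the biological validity of
hot-spot inference on any particular target.

# Numerical and engineering choices

* **Determinism.** The analysis itself has no randomness; all generator
  randomness flows from one seed, through a private RNG stream that leaves
  the caller's `.Random.seed` untouched. Identical config + seed gives
  byte-identical outputs (tested).
* **Assignments.** All 4×4 point correspondences use exhaustive 24-
  permutation minimum-cost assignment — exact, branchless, and trivially
  fast at this size.
* **Ties.** Largest-DBSCAN-cluster ties break toward the earliest label;
  plane-normal sign ties cascade z → y → x; candidate ring pairs are
  processed in ring-id order, making partitions independent of input
  order (tested by shuffling).
* **Degenerate inputs.** Overlapping oxygens (< 0.1 Å) and collinear
  plane points raise errors naming the condition; empty frame sets, empty
  ring sets and missing sidecars are distinct, classed conditions
  (`twnInputError`, `twnEmptyResult`) with distinct CLI exit codes.
* **File formats.** Water frames: PDB, either multi-MODEL or one file per
  frame (lexicographic order), waters recognised by residue name
  (HOH/SOL/WAT/TIP3, configurable), incomplete waters skipped with a
  counted warning. Because frames may contain different water counts per
  MODEL block, blocks are parsed record-wise rather than through a
  fixed-shape trajectory container. Coordinates are used as-is: the
  intended input is a restrained-protein simulation, so frames are
  already co-registered, and no periodic wrapping is applied (binding-site
  waters sit far from box edges in the intended use).
* **Problem sizes.** The test suite runs the full study fixture (200
  frames, 5 sites, ~10,000 waters) plus a shifted replica in about half a
  minute; oracle comparisons use frames of ≤ 12 waters where exhaustive
  enumeration is exact.

# Known limitations

* Results inherit the quality of the fragment poses; a mis-docked pose
  scores against the wrong location by construction.
* Only 4-membered rings are analysed; 3-, 5- and 6-membered networks are
  out of scope.
* No energetic weighting of groups and no free-energy estimates — the
  method is deliberately geometric.
* Unrestrained or drifting trajectories must be aligned before use.
* XTC/DCD and other binary trajectory formats are not read; PDB is the
  reference path.

# A minimal run

```{r example, eval = FALSE}
sites <- demoSites()[1:3]
wf <- makeFrames(sites, nFrames = 20, nNoiseWaters = 15, seed = 42)
tg <- groupRings(detectRings(wf, site = siteDefinition(c(0, 0, 1))))
tg

onsite <- makeFragmentAt(tg, group = 1, elements = "O")
screenRecords(screenFragments(onsite, tg))
```
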