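# twnscreen

Topological water network detection and fragment screening for
explicit-water snapshots of protein binding sites.

Water molecules in a binding pocket transiently arrange into
hydrogen-bonded cyclic networks ("topological water networks", TWNs).
Four-membered rings are roughly fragment-sized, mostly near-planar, and
recur at preferred locations; those locations behave like binding hot
spots. `twnscreen` finds the rings, maps where they recur, and asks of
each docked fragment pose: *does it occupy the same place and shape as a
recurrent water ring?* A pose that does is a candidate hot-spot binder.
The intended users are structure-based/fragment-based drug designers with
restrained-protein MD snapshots of a solvated apo binding site (for
example a kinase ATP pocket) and docked fragment poses in the same
coordinate frame.

## Method

**Detection.** Two waters are hydrogen bonded when their rigid three-site
(TIP3P) interaction energy

v(a,b) = Σᵢ Σⱼ qᵢ qⱼ e² / rᵢⱼ + A/r_oo¹² − C/r_oo⁶

is at or below −2.25 kcal·mol⁻¹ (q_O = −0.834 e, q_H = +0.417 e,
A = 582000 kcal·Å¹²·mol⁻¹, C = 595 kcal·Å⁶·mol⁻¹,
e² = 332.0636 kcal·Å·mol⁻¹·e⁻²). Every simple 4-cycle of the resulting
per-frame hydrogen-bond graph inside a spherical binding-site region
(default radius 20 Å) is a ring; planar and non-planar rings both count.

**Grouping.** Ring oxygens are indexed on a 0.5 Å grid; rings whose four
oxygens can be matched one-to-one within each other's 3×3×3 cell
neighbourhoods are linked, and connected components form primary groups.
DBSCAN (ε = 1 Å) locates the center of each group's four oxygen clusters;
primary groups whose center quadruples match within 1 Å merge into the
final grouped networks.

**Screening.** Each fragment pose is scored against each grouped network
*without superposition*: (i) Gaussian shape-density similarity — every
atom is a spherical Gaussian ρᵢ(r) = p·exp(−αᵢ|r−Rᵢ|²), overlaps are
closed-form, and the Hodgkin index 2·O_AB/(O_AA+O_BB) compares the
fragment's heavy atoms with the network's four centroid pseudo-oxygens;
(ii) the mean orthogonal distance from the fragment's heavy-atom centroid
to the per-ring best-fit planes. A pose passes at S ≥ 0.6 and D ≤ 0.5 Å
(both inclusive).

## Worked example

Synthetic frames with two planted ring sites, detection, grouping and
screening of an on-site pose against an off-plane decoy:

```r
library(twnscreen)
sites <- demoSites()[1:2]
wf <- makeFrames(sites, nFrames = 20, nNoiseWaters = 15, seed = 42)
rs <- detectRings(wf, site = siteDefinition(c(0, 0, 1), radius = 20))
tg <- groupRings(rs)
tg
#> TwnGroups: 2 group(s), 40 member ring(s), 20 frame(s) analysed
#>   members per group: 20, 20

onsite <- makeFragmentAt(tg, group = 1, elements = "O", fragId = "onsite")
decoy  <- makeFragmentAt(tg, group = 1, offset = c(0, 0, 4), fragId = "decoy")
frags  <- fragmentSet(rbind(fragAtoms(onsite)[, 1:5], fragAtoms(decoy)[, 1:5]))
res <- screenFragments(frags, tg)
screenRecords(res)
#>     frag group shape_similarity avg_distance passed
#> 1 onsite     1         1.00e+00       0.0373   TRUE
#> 2 onsite     2         5.56e-05       0.2395  FALSE
#> 3  decoy     1         5.71e-04       3.9934  FALSE
#> 4  decoy     2         7.42e-08       2.8211  FALSE
```

Both planted sites are recovered as groups present in every frame
(occupancy 1). The on-site pose reproduces group 1's footprint exactly
(S = 1, D = 0.04 Å → screened); the same atoms shifted 4 Å off-plane
fail both criteria, and the pose near the *other* site fails on shape
despite a small plane distance — location and shape must agree
simultaneously.

The same workflow is available from a shell via the installed script
(`exec/twnscreen`): subcommands `synth`, `gridbox`, `analysis` and
`automation`, with YAML config plus flag overrides, a run log, and
PDB/CSV/JSON outputs (see `?runGridbox`, `?runAnalysis`).

## Input expectations

- Frames must be co-registered (the method assumes a restrained protein;
  align trajectories beforehand otherwise). Periodic boxes are read but
  no wrapping or minimum-image search is applied.
- Water residues are recognised by name (HOH/SOL/WAT/TIP3, configurable);
  each needs one O and two H records.
- Fragment poses (SDF or PDB) must be docked in the same laboratory
  frame as the frames — both scores are location-aware by design.
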