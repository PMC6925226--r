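---
title: "Capsid shell geometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid shell geometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsgeom)
```

# The problem and the model

Retroviral capsid (CA) proteins assemble into closed fullerene shells:
trivalent polyhedral lattices of pentameric and hexameric rings. Modelling
the shell as a polyhedron whose faces are the P pentagons and H hexagons
gives F = P + H faces, E = (5P + 6H)/2 edges and V = (5P + 6H)/3 vertices,
and the Euler characteristic V − E + F evaluates to P/6. A closed shell
therefore requires exactly P = 12, independent of H — this is what
`validateShell()` checks, and why every shell family in the package has 12
pentamers. Two families are implemented:

* **Caspar–Klug icosahedra**, indexed by lattice vectors (h, k) with
  triangulation number T = h² + hk + k²: 60·T monomers as 12 pentamers and
  10(T − 1) hexamers under icosahedral symmetry (`casparKlug`). (h, k) and
  (k, h) are enantiomers; a handedness flag is carried but never changes
  counts.
* **Dihedral capsules**, elongated shells with 5- or 6-fold poles and r
  equatorial rings of hexamers (`capsuleComposition`): a 5-fold pole gives
  12 pentamers + 5r hexamers (D5), a 6-fold pole gives 2 polar hexamers,
  12 surrounding pentamers and 6r equatorial hexamers (D6). Only r = 1 has
  been observed for each class; other r are labelled extrapolations and
  are validated only in the Euler sense.

Within a shell, each CA monomer contributes an N-terminal domain (NTD) to
a ring-axis cluster and a C-terminal domain (CTD) to the inter-ring
"inner cage". The package's analytical core quantifies the CTD–CTD dimer
conformation by two observables measured on the α8 helix of each partner:

* **Helix vector**: the whole-helix centroid is the unweighted mean of all
  backbone (N, CA, C) atoms in the helix interval; the centroids of the
  first and second halves of the interval are the start and end of the
  directed vector (an odd residue count gives the first half the extra
  residue, a deterministic and documented tie-break). The direction points
  N→C.
* **Crossing angle**: arccos of the normalised dot product of the two
  directed vectors, reported in [0°, 180°]. Directedness matters — the
  hexamer–hexamer family sits near 95°, which an undirected [0°, 90°]
  convention would alias onto 85°.
* **Centroid displacement**: the Euclidean distance between the two
  whole-helix centroids.

Interfaces are classified into three groups by nearest reference angle
with fixed boundaries at the midpoints of the empirical group centres 20°,
65° and 95°: angle < 42.5° → group 1 (solution-dimer-like), 42.5°–80° →
group 2 (pentamer-involving lattice contacts), ≥ 80° → group 3
(hexamer–hexamer contacts). Boundaries are fixed rather than fitted
(e.g. by k-means) so the classification is deterministic and directly
traceable to the stated group centres; the distance to the nearest
reference is reported alongside the label so borderline cases are visible.

# Pipeline assumptions

`analyzeShell()` composes the stages with these conventions:

* **Particle centre**: unweighted centroid of all non-hydrogen atoms.
  Hydrogens and waters are excluded from every centroid and contact
  computation because their presence is deposition-dependent.
* **Ring detection**: chains are nodes; an edge joins two chains when the
  minimum heavy-atom distance between their NTD selections is below the
  ring cutoff (default 6.0 Å). Connected components must have 5 or 6
  members — anything else raises a diagnostic error rather than a silent
  partial result, since it signals a wrong cutoff or a broken assembly.
  NTD (not CTD) contacts define rings because NTDs cluster at ring axes
  while CTDs mediate *inter*-ring contacts.
* **Interface enumeration**: unordered chain pairs in different rings with
  minimum heavy-atom CTD–CTD distance below the interface cutoff (default
  5.0 Å). Symmetric copies are kept by default (the full list is the
  interface point cloud); `uniqueInterfaces()` clusters records agreeing
  within 1° and 0.5 Å.
* **Layer metrics**: NTD/CTD layer centres of mass are mass-weighted over
  pooled non-hydrogen atoms (standard atomic weights; unknown elements
  fall back to carbon with a warning), radii are distances from the
  particle centre, and the vertical displacement is the CoM separation
  projected on the local ring axis. Per-ring radial profiles use the
  unweighted all-atom ring centroid.
* **Conformational fingerprint**: hydrogen bonds are proxied by heavy-atom
  donor–acceptor distances ≤ 3.5 Å with no angular term (deposited models
  may lack hydrogens; a documented limitation). The pentamer state
  requires R143–K182(main-chain O) ≤ 3.5 Å *and* K229–D90′ ≤ 3.5 Å; the
  hexamer state requires R143–Q181(side chain) ≤ 3.5 Å with K229–D90′
  absent (> 3.5 Å); anything else is indeterminate. The interacting ring
  neighbour is chosen as the one with the smaller D171–S79′ distance, so
  the result does not depend on ring traversal direction.
* **Superposition**: Kabsch least squares with reflection correction; the
  rotation angle comes from the trace and the axis from the antisymmetric
  part, falling back to the +1-eigenvector near 180° with the
  largest-component-positive sign convention. `relativeDomainMotion`
  superposes two monomers on NTD Cα atoms and reports the residual
  CTD-on-CTD rotation and CTD centroid shift in that NTD-aligned frame.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| NTD interval | 1–153 | residues | domain boundary of the CA chain |
| CTD interval | 154–246 | residues | complementary domain |
| α8 marker interval | 186–203 | residues | spans the hydrophobic interface face (A189…M197); exact helix termini are not pinned by depositions, so configurable. A longer window averages more backbone atoms and stabilises the half-centroid vector against coordinate noise |
| ring contact cutoff | 6.0 | Å | NTD–NTD heavy-atom contact distance |
| interface cutoff | 5.0 | Å | CTD–CTD heavy-atom contact distance |
| H-bond proxy cutoff | 3.5 | Å | heavy donor–acceptor distance |
| group boundaries | 42.5°, 80° | degrees | midpoints of group centres 20/65/95° |
| POLAR/LONG/LAT threshold | 45° | degrees | ring-latitude band and contact-vector orientation split for capsules |

All are arguments of the corresponding functions; `analyzeShell` threads
them through and `writeReports` echoes every effective value in
`summary.json` for auditability.

# The synthetic-data generator

`makeShell()` builds complete T=1, D5, D6 and T=3 shells from toy
monomers, with a machine-readable ground-truth manifest, so the entire
pipeline can be exercised and checked without downloading coordinates.

**What it emulates.** Ring placement follows the real architectures:
pentamer rings on the 12 icosahedral vertex directions (I2 frame, 2-fold
axes along x, y, z), T=3 hexamers on the 20 face directions, and capsule
rings on dihedral direction tables with the two hemispheres shifted apart
along the principal axis (default elongation 30 Å) — the elongation is
what makes capsules capsular and gives the equatorial hexamer belt room.
Default ring radii mirror the measured particles where values exist
(T=3 pentamers 143.9 Å, hexamers 136.5 Å; T=1 NTD/CTD layers 86.3/64.7 Å
with their 21.6 Å separation); capsule radii are not printed for the
deposited particles and default to 90/95 Å, between the T=1 and T=3
scales. Each inter-ring contact gets exactly one CTD–CTD dimer whose α8
pair is constructed *exactly* at the recipe geometry (65°/12 Å at
pentamer-involving contacts, 95°/14 Å at hexamer–hexamer contacts, the
stated empirical group centres): the two helices are placed with
directions cos(γ/2)e₁ ± sin(γ/2)e₂ and centroids ±d/2 along the mutual
perpendicular, after mapping each ideal helix so its *measured* centroid
and half-centroid direction hit the targets. A contact-knob atom pair
(2.8 Å apart) marks each designated interface so contact detection is
unambiguous. Monomer bodies carry the full fingerprint atom set placed at
the state's hydrogen-bond distances, realised between ring neighbours.
Per ring, the NTD blob backbone is finally translated so the ring's
unweighted all-atom centroid sits exactly at the recipe radius along the
ring direction (this never moves fingerprint or helix atoms, so exact
interface and fingerprint geometry survives).

Ideal helices (`makeIdealHelix`) use rise 1.5 Å, twist 100° and backbone
radius 2.3 Å per residue, with the N/CA/C triplet spaced 120° around the
helical circle and ±0.5 Å along the axis so the per-residue backbone
centroid lies exactly on the axis — making the half-centroid vector
exactly axial at zero noise, which is what lets fixtures hit target
crossing angles to 1e-6. Optional noise is isotropic Gaussian per
coordinate with a mandatory recorded seed; generation is byte-identical
for a fixed recipe and seed.

**What it does not emulate — and what a green test establishes.** Toy
monomers are marker scaffolds, not folds: blobs plus marker helices, with
no side chains beyond the named fingerprint atoms, no physical packing,
no clash avoidance and no energetics. T=3 hexamers do not alternate
pentamer-like/hexamer-like states around the ring (all hexamer members
are built hexamer-like), and full-shell per-ring *layer* metrics are
approximate because interface helices sit at ring boundaries —
`makeRing()` is the controlled fixture where NTD/CTD layer radii and
separation are exact (it solves the two layer heights so the
mass-weighted layer CoMs land exactly on target). A green full-circle
test therefore establishes that the measurement chain — parsing, ring
detection, helix vectorisation, angle/displacement arithmetic,
classification — is correct, deterministic and rigid-motion invariant; it
cannot establish anything about real packing, flexibility or map quality.

# Numerical choices

* Point groups are generated in closed form (Cn, Dn) or by closure over a
  generator pair (icosahedral: a 2-fold about z and a 5-fold about the
  vertex direction (0, 1, φ)), deduplicated with rounded signatures;
  group checks use a 1e-9 tolerance since operators come from closed-form
  angles. Antipodal symmetry axes are merged with a first-nonzero-positive
  sign convention, which is stable under component ties.
* The identity copy in `expandAssembly` bypasses multiplication so it
  preserves input coordinates bitwise.
* Contact searches use bounding-sphere prefilters before exact minimum
  heavy-atom distances, keeping the O(chains²) loops fast at T=3 scale.
* Degenerate inputs error loudly: < 4-residue helices, incomplete
  backbones (naming the residues), collinear superposition inputs, empty
  selections in analysis paths, ring components of size ∉ {5, 6}.
* PDB output is strict v3.3: single-character chain identifiers and at
  most 99,999 atoms, otherwise the error advises mmCIF; synthetic chain
  ids are drawn from a deterministic sequence (62 single characters, then
  two-character ids, which only mmCIF can carry). Alternate conformers
  resolve to the highest occupancy, ties to first-seen, for deterministic
  geometry.
* Multi-model files keep all models; analyses default to model 1 (taken
  to be the lowest-energy member of an NMR ensemble, the usual deposition
  order), configurable via `selectAtoms(model = )`.

# Open design decisions taken

* **α8 interval.** Only the hydrophobic member residues are named in the
  source structures, not the helix termini; the default interval 186–203
  starts after the α7 region (Q181/K182) and ends before the α8–α9 loop.
  It is a `domainScheme()` argument precisely because it is a choice.
* **Group-boundary placement.** Only group centres and ranges are
  empirical; the midpoint rule (42.5°/80°) is this package's decision and
  is echoed in the report metadata.
* **Displacement convention.** Whole-helix centroids (consistent with the
  centroid definition used for the vectors), not half-helix centroids;
  configurable through the helix interval.
* **Capsule topology tags.** POLAR when both rings lie within 45° of the
  principal axis; otherwise LONG/LAT by whether the inter-ring contact
  vector is within 45° of the axis. The tag nomenclature is standard; the
  numeric rule is ours.
* **Direct shell construction.** Shells are built by deterministic
  placement from ring-direction tables rather than by expanding a literal
  asymmetric-unit coordinate file, because exact control of every
  interface's angle and displacement requires per-interface helix
  placement (non-symmetry-related pairs, e.g. T=3 pentamer–hexamer, could
  not all be exact under a single-copy expansion). `expandAssembly` is a
  first-class, separately tested operation.

# Limitations

* The hydrogen-bond proxy has no angular term and will over-call bonds in
  unusual geometries.
* Ring detection assumes NTD clusters separate cleanly at the 6 Å scale;
  heavily distorted or partial assemblies fail loudly rather than being
  rescued.
* No secondary-structure assignment: helix intervals come from the
  residue scheme, never from geometry.
* No map handling, refinement, crystallographic symmetry expansion or
  buried-surface-area computation; those belong to the upstream
  structure-determination pipeline, not this analysis layer.
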