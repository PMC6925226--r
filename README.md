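# capsgeom

Geometric analysis of retroviral capsid (CA) fullerene shells in R.

Retroviral capsid proteins polymerise into closed polyhedral shells built
from pentameric and hexameric rings. Euler's formula forces every closed
trivalent pentagon/hexagon lattice to contain exactly 12 pentagons, so the
possible shells form discrete families: Caspar–Klug icosahedra with
triangulation number *T* = h² + hk + k² (60·*T* subunits, 12 pentamers,
10(*T*−1) hexamers) and dihedral (D5/D6) capsules with equatorial hexamer
belts. Within a shell, each CA monomer has an N-terminal domain (NTD,
residues 1–153) clustered at the ring axes and a C-terminal domain (CTD,
154–246) forming an inner cage of CTD–CTD dimer contacts between rings.
The dimer conformation is captured by two numbers measured on the α8 helix
of each partner:

* the **crossing angle** Ω between the directed helix vectors, where each
  vector runs from the backbone (N, CA, C) centroid of the first half of
  the helix to that of the second half, and
  cos Ω = v₁·v₂ / (|v₁||v₂|);
* the **centroid displacement** d, the distance between the whole-helix
  backbone centroids.

Observed CTD–CTD dimers quantise into three groups (Ω ≈ 20°, 65°, 95°):
solution-state dimers, pentamer-involving lattice contacts, and
hexamer–hexamer lattice contacts respectively. `capsgeom` implements this
whole analysis chain:

* **Structure I/O** — PDB v3.3 and mmCIF `atom_site` reading/writing,
  residue/chain/atom selection, a configurable NTD/CTD/helix residue
  scheme (`readStructure`, `selectAtoms`, `writeStructure`,
  `domainScheme`).
* **Point groups** — exact Cn, Dn and icosahedral (I, "I2" setting)
  rotation groups, asymmetric-unit expansion and symmetry-axis tables
  (`makePointGroup`, `expandAssembly`, `symmetryAxes`).
* **Shell arithmetic** — Caspar–Klug and capsule compositions with Euler
  validation (`casparKlug`, `capsuleComposition`, `validateShell`).
* **Rigid geometry** — helix vectors, crossing angles, displacements,
  Kabsch superposition, NTD-aligned domain-motion decomposition, layer
  centre-of-mass metrics (`helixVector`, `crossingAngle`, `superpose`,
  `relativeDomainMotion`, `layerMetrics`).
* **Whole-particle pipeline** — ring detection from NTD–NTD contacts,
  CTD–CTD interface enumeration and group 1/2/3 classification, radial
  profiles, NTD–CTD conformational-state fingerprints and deterministic
  CSV/JSON reports (`analyzeShell`, `detectRings`, `enumerateInterfaces`,
  `classifyInterface`, `conformationFingerprint`, `writeReports`).
* **Synthetic shells** — fully controlled T=1/D5/D6/T=3 toy shells with a
  ground-truth manifest, so every analysis stage is testable without
  downloads (`makeShell`, `makeRing`, `makeIdealHelix`,
  `makeTwoHelixFixture`).

A thin command-line wrapper (`inst/scripts/capsgeom.R`) exposes
`compose`, `synth`, `analyze`, `expand` and `helixpair` subcommands.

## Worked example

```r
library(capsgeom)

casparKlug(1, 1)
#> ShellComposition T3 (I): 180 monomers = 12 pentamers + 20 hexamers [T=3]

# generate a T=1 shell (60 chains) and run the full pipeline
shell <- makeShell(shellRecipe("T1", seed = 1))
an <- analyzeShell(shell$model)
length(an$rings$rings)                 # 12 pentamer rings
#> [1] 12
head(an$interfaces[, c("kind", "angle", "displacement", "group")], 1)
#>                kind angle displacement group
#> 1 pentamer-pentamer    65           12     2
table(an$fingerprints$state)
#> pentamer-like
#>            60
```

The 30 inter-pentamer interfaces all measure 65°/12 Å and classify as
group 2, reproducing the generator's manifest exactly; every monomer's
NTD–CTD hydrogen-bond fingerprint reads pentamer-like. The solution-dimer
geometry classifies as group 1:

```r
iv <- markerInterval(domainScheme())
nmr <- makeTwoHelixFixture(20, 11)     # 20 deg crossing, 11 A displacement
g <- pairGeometry(helixVector(nmr, iv, "A"), helixVector(nmr, iv, "B"))
g
#> PairGeometry A-B: angle 20.00 deg, displacement 11.00 A
classifyInterface(g)$group
#> [1] 1
```

See `vignettes/capsid-shell-geometry.Rmd` for the model, parameter and
design documentation.

## Acceptance script

`scripts/acceptance.R` recomputes the shell-census quantities (monomer and
hexamer counts of the T=1, T=3, D5 and D6 particle classes) from scratch
with the installed package — running the composition calculators, passing
each census through the Euler validator, and cross-checking the T=1 count
against a generated shell run through ring detection — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
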