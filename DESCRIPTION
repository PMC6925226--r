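Package: capsgeom
Title: Geometric Analysis of Retroviral Capsid Fullerene Shells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the geometric characterisation of closed retroviral
    capsid (CA) shells built from pentamers and hexamers. Provides reading,
    selection and writing of atomic models (PDB/mmCIF), finite rotation
    point groups (cyclic, dihedral, icosahedral) with assembly expansion,
    Caspar-Klug and capsule shell composition arithmetic with Euler
    validation, helix-vector crossing-angle and centroid-displacement
    parameterisation of CTD-CTD dimer interfaces with group classification,
    rigid-body superposition, per-ring radial and domain-layer metrics,
    NTD-CTD conformational-state fingerprints, and a fully controlled
    synthetic shell generator with ground-truth manifests for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'structure-io.R'
    'pointgroup.R'
    'composition.R'
    'geometry.R'
    'assembly.R'
    'reports.R'
    'synthetic.R'
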