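## S4 classes for the capsid-geometry toolkit.

.atomColumns <- c("serial", "name", "alt_loc", "res_name", "chain_id",
                  "res_seq", "x", "y", "z", "occupancy", "b_iso",
                  "element", "model_num")

#' StructureModel: hierarchical atomic coordinates
#'
#' Holds atomic coordinates read from PDB/mmCIF (or built synthetically) as a
#' flat atom table; the model/chain/residue hierarchy is encoded by the
#' \code{model_num}, \code{chain_id} and \code{res_seq} columns, with file
#' order preserved.  Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns serial, name, alt_loc, res_name,
#'   chain_id, res_seq, x, y, z, occupancy, b_iso, element, model_num.
#' @slot title character title (may be empty).
#' @slot format source format tag ("pdb", "cif" or "memory").
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", title = "character",
                 format = "character"),
  prototype(title = "", format = "memory")
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  missing <- setdiff(.atomColumns, names(a))
  if (length(missing))
    return(sprintf("atom table lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("non-finite coordinates")
    occ <- a$occupancy
    if (any(occ < 0 | occ > 1, na.rm = TRUE))
      return("occupancy outside [0,1]")
    key <- paste(a$model_num, a$chain_id, a$res_seq, a$name, a$alt_loc)
    if (anyDuplicated(key))
      return("duplicate (model, chain, residue, atom, alt_loc) records")
  }
  TRUE
})

## Lightweight constructor used throughout: fills defaulted columns.
newStructureModel <- function(atoms, title = "", format = "memory") {
  n <- nrow(atoms)
  if (is.null(atoms$serial))    atoms$serial    <- seq_len(n)
  if (is.null(atoms$alt_loc))   atoms$alt_loc   <- rep("", n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$b_iso))     atoms$b_iso     <- rep(0, n)
  if (is.null(atoms$model_num)) atoms$model_num <- rep(1L, n)
  if (is.null(atoms$element))   atoms$element   <- elementFromName(atoms$name)
  atoms <- atoms[, .atomColumns]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, title = title, format = format)
}

#' @describeIn StructureModel number of atoms
#' @param x,object a \code{StructureModel}
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn StructureModel atom table accessor
#' @export
atomTable <- function(x) x@atoms

#' @describeIn StructureModel coordinates as an n x 3 matrix
#' @export
coords <- function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @describeIn StructureModel unique chain identifiers, in file order
#' @export
chainIds <- function(x) unique(x@atoms$chain_id)

#' @describeIn StructureModel model numbers present
#' @export
modelNums <- function(x) unique(x@atoms$model_num)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf(
    "StructureModel (%s): %d atoms, %d chain(s), %d model(s)\n",
    object@format, nrow(a), length(unique(a$chain_id)),
    length(unique(a$model_num))))
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
})

#' DomainScheme: residue intervals for domains and marker helices
#'
#' The residue scheme used by all downstream analysis: the NTD/CTD split of
#' the CA chain and the named helix intervals, including the marker helix used
#' for interface parameterisation.  Intervals are 1-based and inclusive.
#'
#' @slot ntd integer length-2 inclusive interval, default c(1, 153).
#' @slot ctd integer length-2 inclusive interval, default c(154, 246).
#' @slot helices named list of integer length-2 intervals.
#' @slot marker name of the marker helix (default "a8").
#' @export
setClass("DomainScheme",
  representation(ntd = "integer", ctd = "integer", helices = "list",
                 marker = "character"))

setValidity("DomainScheme", function(object) {
  chk <- function(iv) length(iv) == 2L && iv[1L] <= iv[2L]
  if (!chk(object@ntd) || !chk(object@ctd))
    return("ntd/ctd must be inclusive intervals lo <= hi")
  if (object@ntd[2L] >= object@ctd[1L] && object@ctd[2L] >= object@ntd[1L])
    return("NTD and CTD intervals overlap")
  for (nm in names(object@helices)) {
    h <- object@helices[[nm]]
    if (!chk(h)) return(sprintf("helix %s: invalid interval", nm))
    inN <- h[1L] >= object@ntd[1L] && h[2L] <= object@ntd[2L]
    inC <- h[1L] >= object@ctd[1L] && h[2L] <= object@ctd[2L]
    if (!inN && !inC)
      return(sprintf("helix %s does not lie inside one domain", nm))
  }
  if (!object@marker %in% names(object@helices))
    return("marker helix not among named helices")
  TRUE
})

#' Default CA domain scheme
#'
#' NTD spans residues 1-153 and CTD 154-246.  The marker helix "a8" defaults
#' to residues 186-203, an 18-residue window spanning the hydrophobic
#' interface face (A189, V192, I193, V194, L196, M197) and ending before the
#' a8-a9 loop.  The exact helix boundaries are not pinned down by the
#' depositions, so the interval is configurable; a longer interval also
#' stabilises the half-centroid vector against coordinate noise.
#'
#' @param ntd,ctd inclusive residue intervals.
#' @param helices named list of inclusive intervals.
#' @param marker marker helix name.
#' @return a \code{DomainScheme}
#' @export
domainScheme <- function(ntd = c(1L, 153L), ctd = c(154L, 246L),
                         helices = list(a8 = c(186L, 203L)),
                         marker = "a8") {
  new("DomainScheme", ntd = as.integer(ntd), ctd = as.integer(ctd),
      helices = lapply(helices, as.integer), marker = marker)
}

#' @describeIn domainScheme the marker-helix interval of a scheme
#' @param scheme a \code{DomainScheme}
#' @export
markerInterval <- function(scheme) scheme@helices[[scheme@marker]]

setMethod("show", "DomainScheme", function(object) {
  cat(sprintf("DomainScheme: NTD [%d,%d], CTD [%d,%d], marker %s [%d,%d]\n",
              object@ntd[1L], object@ntd[2L], object@ctd[1L], object@ctd[2L],
              object@marker, markerInterval(object)[1L],
              markerInterval(object)[2L]))
})

#' PointGroup: a finite rotation group
#'
#' An ordered list of proper orthonormal 3x3 operators forming a cyclic (Cn),
#' dihedral (Dn) or icosahedral (I) rotation group, plus the symmetry axes with
#' their folds.
#'
#' @slot name group name ("C5", "D6", "I", ...).
#' @slot operators list of 3x3 rotation matrices; first element is identity.
#' @slot labels operator labels.
#' @slot axes data.frame with columns x, y, z (unit axis) and fold.
#' @export
setClass("PointGroup",
  representation(name = "character", operators = "list",
                 labels = "character", axes = "data.frame"))

setValidity("PointGroup", function(object) {
  ops <- object@operators
  if (!length(ops)) return("no operators")
  for (R in ops) {
    if (max(abs(crossprod(R) - diag(3L))) > 1e-9)
      return("operator not orthonormal within 1e-9")
    if (abs(det(R) - 1) > 1e-9)
      return("operator determinant != +1")
  }
  if (max(abs(ops[[1L]] - diag(3L))) > 1e-9)
    return("first operator is not the identity")
  TRUE
})

#' @describeIn PointGroup number of operators
#' @param x,object a \code{PointGroup}
#' @export
groupOrder <- function(x) length(x@operators)

#' @describeIn PointGroup list of operator matrices
#' @export
groupOperators <- function(x) x@operators

setMethod("show", "PointGroup", function(object) {
  cat(sprintf("PointGroup %s: order %d, %d symmetry axis/axes\n",
              object@name, length(object@operators), nrow(object@axes)))
})

#' ShellComposition: pentamer/hexamer census of a closed shell
#'
#' @slot label shell class label (e.g. "T1", "D5-capsule").
#' @slot T triangulation number, or NA for capsules.
#' @slot pentamers,hexamers,monomers non-negative integer counts.
#' @slot symmetry point-group name.
#' @slot handedness "laevo"/"dextro"/"achiral" flag (does not affect counts).
#' @export
setClass("ShellComposition",
  representation(label = "character", T = "numeric", pentamers = "integer",
                 hexamers = "integer", monomers = "integer",
                 symmetry = "character", handedness = "character"),
  prototype(handedness = "achiral"))

setValidity("ShellComposition", function(object) {
  if (object@pentamers < 0L || object@hexamers < 0L)
    return("negative counts")
  if (object@monomers != 5L * object@pentamers + 6L * object@hexamers)
    return("monomers != 5*pentamers + 6*hexamers")
  TRUE
})

setMethod("show", "ShellComposition", function(object) {
  cat(sprintf(
    "ShellComposition %s (%s): %d monomers = %d pentamers + %d hexamers%s\n",
    object@label, object@symmetry, object@monomers, object@pentamers,
    object@hexamers,
    if (is.na(object@T)) "" else sprintf(" [T=%g]", object@T)))
})

#' HelixVector: directed axis estimate of a helix
#'
#' The helix direction is the vector from the backbone centroid of the first
#' half of the residue interval to that of the second half, normalised; it
#' points from the N- to the C-terminus.  The whole-helix centroid is the
#' unweighted mean of all backbone (N, CA, C) atoms.
#'
#' @slot start,end half-centroids (Angstrom).
#' @slot centroid whole-helix backbone centroid.
#' @slot direction unit vector end - start.
#' @slot chain source chain id.
#' @slot interval source residue interval.
#' @export
setClass("HelixVector",
  representation(start = "numeric", end = "numeric", centroid = "numeric",
                 direction = "numeric", chain = "character",
                 interval = "integer"))

setValidity("HelixVector", function(object) {
  if (abs(vecNorm(object@direction) - 1) > 1e-9)
    return("direction not unit length")
  if (vecNorm(object@end - object@start) < 1e-9)
    return("degenerate helix: start == end")
  TRUE
})

setMethod("show", "HelixVector", function(object) {
  cat(sprintf(
    "HelixVector %s[%d-%d]: centroid (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
    object@chain, object@interval[1L], object@interval[2L],
    object@centroid[1L], object@centroid[2L], object@centroid[3L],
    object@direction[1L], object@direction[2L], object@direction[3L]))
})

#' SuperpositionResult: least-squares rigid superposition
#'
#' @slot rotation 3x3 proper rotation applied to the moving set.
#' @slot translation length-3 translation (Angstrom).
#' @slot rmsd root-mean-square deviation after transform.
#' @slot nPairs number of paired coordinates.
#' @slot angle rotation angle (degrees).
#' @slot axis unit rotation axis.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nPairs = "integer", angle = "numeric",
                 axis = "numeric"))

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("Superposition: rmsd %.4f A over %d pairs; rotation %.2f deg\n",
              object@rmsd, object@nPairs, object@angle))
})

#' LayerMetrics: NTD/CTD layer centre-of-mass and radial metrics
#'
#' @slot ntdCom,ctdCom mass-weighted centres of mass of the pooled domain
#'   selections (Angstrom).
#' @slot ntdRadius,ctdRadius distances of the CoMs from the particle centre.
#' @slot verticalDisplacement |(ntdCom - ctdCom) . axis|.
#' @slot axis local symmetry axis (unit).
#' @slot centre particle centre used.
#' @export
setClass("LayerMetrics",
  representation(ntdCom = "numeric", ctdCom = "numeric", ntdRadius = "numeric",
                 ctdRadius = "numeric", verticalDisplacement = "numeric",
                 axis = "numeric", centre = "numeric"))

setMethod("show", "LayerMetrics", function(object) {
  cat(sprintf(
    "LayerMetrics: NTD radius %.2f A, CTD radius %.2f A, vertical displacement %.2f A\n",
    object@ntdRadius, object@ctdRadius, object@verticalDisplacement))
})

#' PairGeometry: crossing angle and displacement of one CTD-CTD dimer
#'
#' @slot crossingAngle degrees in [0, 180] between the directed helix vectors.
#' @slot displacement distance between whole-helix centroids (Angstrom).
#' @slot members the two chain ids.
#' @slot kind interface kind ("pentamer-pentamer", "pentamer-hexamer",
#'   "hexamer-hexamer", or "" when unknown).
#' @slot tag topology tag ("POLAR", "LONG", "LAT" or "").
#' @export
setClass("PairGeometry",
  representation(crossingAngle = "numeric", displacement = "numeric",
                 members = "character", kind = "character", tag = "character"),
  prototype(kind = "", tag = ""))

setValidity("PairGeometry", function(object) {
  if (object@crossingAngle < -1e-9 || object@crossingAngle > 180 + 1e-9)
    return("crossing angle outside [0, 180] degrees")
  if (object@displacement < 0) return("negative displacement")
  TRUE
})

setMethod("show", "PairGeometry", function(object) {
  cat(sprintf("PairGeometry %s-%s: angle %.2f deg, displacement %.2f A %s\n",
              object@members[1L], object@members[2L], object@crossingAngle,
              object@displacement,
              if (nzchar(object@kind)) paste0("(", object@kind, ")") else ""))
})
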