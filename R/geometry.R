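## Core geometry: helix vectors from half-centroids, crossing angles,
## centroid displacements, Kabsch superposition, relative domain motion and
## domain-layer metrics.

#' Helix vector from half-centroids
#'
#' The whole-helix centroid is the unweighted mean of all backbone (N, CA, C)
#' atom positions in the residue interval.  The centroids of the first and
#' second halves of the interval are the start and end points of the directed
#' helix vector (N- to C-terminus); for an odd residue count the first half
#' takes the extra residue.
#'
#' @param x a \linkS4class{StructureModel} containing the helix.
#' @param interval inclusive residue interval of the helix.
#' @param chain restrict to one chain (required when x has several).
#' @return a \linkS4class{HelixVector}
#' @export
helixVector <- function(x, interval, chain = NULL) {
  if (is.null(chain)) {
    ch <- chainIds(x)
    if (length(ch) > 1L)
      capsParamError("model has several chains: specify `chain`")
    chain <- ch
  }
  a <- x@atoms
  a <- a[a$chain_id == chain & a$res_seq >= interval[1L] &
           a$res_seq <= interval[2L] & a$name %in% c("N", "CA", "C"), ]
  resIds <- sort(unique(a$res_seq))
  if (length(resIds) < 4L)
    capsGeometryError(sprintf(
      "helix interval [%d,%d] has %d residue(s) with backbone atoms; need >= 4",
      interval[1L], interval[2L], length(resIds)))
  counts <- table(a$res_seq)
  incomplete <- names(counts)[counts < 3L]
  if (length(incomplete))
    capsGeometryError(sprintf("incomplete backbone (N, CA, C) in residue(s) %s",
                              paste(incomplete, collapse = ", ")))
  m <- length(resIds)
  firstHalf <- resIds[seq_len(ceiling(m / 2))]
  secondHalf <- setdiff(resIds, firstHalf)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  start <- colMeans(xyz[a$res_seq %in% firstHalf, , drop = FALSE])
  end <- colMeans(xyz[a$res_seq %in% secondHalf, , drop = FALSE])
  if (vecNorm(end - start) < 1e-9)
    capsGeometryError("degenerate helix: half-centroids coincide")
  new("HelixVector", start = unname(start), end = unname(end),
      centroid = unname(centroid), direction = unitVector(end - start),
      chain = chain, interval = as.integer(interval))
}

#' Crossing angle between two helix vectors
#'
#' The angle between the directed (N to C) half-centroid vectors, from the
#' normalised dot product, reported in degrees in [0, 180].  Using directed
#' vectors matters: interface families near 95 degrees are indistinguishable
#' from 85 degrees under an undirected convention.
#'
#' @param a,b \linkS4class{HelixVector}s.
#' @return angle in degrees
#' @export
crossingAngle <- function(a, b) {
  va <- a@end - a@start
  vb <- b@end - b@start
  na <- vecNorm(va); nb <- vecNorm(vb)
  if (na < 1e-9 || nb < 1e-9)
    capsGeometryError("zero-length helix vector")
  cosang <- sum(va * vb) / (na * nb)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Displacement between whole-helix centroids
#'
#' @param a,b \linkS4class{HelixVector}s.
#' @return Euclidean distance in Angstrom
#' @export
centroidDisplacement <- function(a, b) vecNorm(a@centroid - b@centroid)

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' \eqn{\sum_i |R m_i + t - f_i|^2} over paired coordinates, with reflection
#' correction via the sign of the smallest singular value.  The rotation
#' angle is extracted from the trace and the axis from the antisymmetric part.
#'
#' @param fixed,moving n x 3 coordinate matrices (or
#'   \linkS4class{StructureModel}s, in which case their coordinates are paired
#'   in atom order).
#' @return a \linkS4class{SuperpositionResult}
#' @export
superpose <- function(fixed, moving) {
  if (is(fixed, "StructureModel")) fixed <- coords(fixed)
  if (is(moving, "StructureModel")) moving <- coords(moving)
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (nrow(fixed) != nrow(moving))
    capsParamError("fixed and moving must have the same number of points")
  n <- nrow(fixed)
  if (n < 3L) capsGeometryError("need >= 3 paired points to superpose")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  F0 <- sweep(fixed, 2L, cf); M0 <- sweep(moving, 2L, cm)
  ## Collinearity check: rank of the centred point cloud.
  sv <- svd(M0)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1))
    capsGeometryError("degenerate (collinear) coordinates")
  H <- crossprod(M0, F0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cf - as.vector(R %*% cm)
  moved <- moving %*% t(R) + matrix(t, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  aa <- rotationAngleAxis(R)
  new("SuperpositionResult", rotation = R, translation = t, rmsd = rmsd,
      nPairs = as.integer(n), angle = aa$angle, axis = aa$axis)
}

## Apply a superposition (or plain R, t) to a coordinate matrix.
applyTransform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  if (is(rotation, "SuperpositionResult")) {
    translation <- rotation@translation
    rotation <- rotation@rotation
  }
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3L, byrow = TRUE)
}

## Apply a rigid transform to a whole StructureModel.
transformStructure <- function(x, rotation, translation = c(0, 0, 0)) {
  p <- applyTransform(coords(x), rotation, translation)
  x@atoms$x <- p[, 1L]; x@atoms$y <- p[, 2L]; x@atoms$z <- p[, 3L]
  x
}

#' Relative NTD-CTD domain motion between two monomers
#'
#' Superposes the two monomers on their NTD CA atoms, then reports the
#' residual CTD-on-CTD rotation angle and the CTD centroid displacement
#' measured in the NTD-aligned frame.  This is the quantity behind statements
#' like "the CTD is rotated by a further 15 degrees with an accompanying
#' 2 Angstrom shift" when comparing pentamer- and hexamer-state monomers.
#'
#' @param ref,other single-chain \linkS4class{StructureModel}s with complete
#'   NTD and CTD selections.
#' @param scheme a \linkS4class{DomainScheme}.
#' @return list(rotationAngle = degrees, ctdShift = Angstrom,
#'   ntdRmsd, ctdRmsd)
#' @export
relativeDomainMotion <- function(ref, other, scheme = domainScheme()) {
  caOf <- function(m, iv) coords(selectAtoms(m, residues = iv, atoms = "CA"))
  refN <- caOf(ref, scheme@ntd);  othN <- caOf(other, scheme@ntd)
  refC <- caOf(ref, scheme@ctd);  othC <- caOf(other, scheme@ctd)
  if (nrow(refN) != nrow(othN) || nrow(refC) != nrow(othC))
    capsParamError("monomers have different NTD/CTD CA atom counts")
  supN <- superpose(refN, othN)
  ## Bring `other` into the NTD frame of `ref`, then compare CTDs.
  othCAligned <- applyTransform(othC, supN)
  supC <- superpose(refC, othCAligned)
  shift <- vecNorm(colMeans(othCAligned) - colMeans(refC))
  list(rotationAngle = supC@angle, ctdShift = shift,
       ntdRmsd = supN@rmsd,
       ctdRmsd = supC@rmsd)
}

#' NTD/CTD layer metrics of a ring
#'
#' Pools the NTD and CTD selections of all ring members and reports the
#' mass-weighted centre of mass of each layer (non-hydrogen atoms), the
#' radial distance of each CoM from the particle centre, and the vertical
#' displacement between the layers projected on the local symmetry axis.
#'
#' @param ring a \linkS4class{StructureModel} holding the ring members.
#' @param scheme a \linkS4class{DomainScheme}.
#' @param centre particle centre (length-3).
#' @param axis local symmetry axis (unit length-3).
#' @return a \linkS4class{LayerMetrics}
#' @export
layerMetrics <- function(ring, scheme = domainScheme(),
                         centre = c(0, 0, 0), axis = c(0, 0, 1)) {
  axis <- unitVector(axis)
  comOf <- function(iv) {
    sel <- heavyAtoms(selectAtoms(ring, residues = iv))
    if (nAtoms(sel) == 0L)
      capsAnalysisError(sprintf("empty domain selection [%d,%d]",
                                iv[1L], iv[2L]))
    w <- elementMasses(sel@atoms$element)
    colSums(coords(sel) * w) / sum(w)
  }
  ntd <- comOf(scheme@ntd)
  ctd <- comOf(scheme@ctd)
  new("LayerMetrics",
      ntdCom = unname(ntd), ctdCom = unname(ctd),
      ntdRadius = vecNorm(ntd - centre), ctdRadius = vecNorm(ctd - centre),
      verticalDisplacement = abs(sum((ntd - ctd) * axis)),
      axis = axis, centre = centre)
}

#' Pair geometry of two marker helices
#'
#' Convenience wrapper building the \linkS4class{PairGeometry} (crossing
#' angle + centroid displacement) from two helix vectors.
#'
#' @param a,b \linkS4class{HelixVector}s.
#' @param kind interface kind tag.
#' @param tag topology tag.
#' @return a \linkS4class{PairGeometry}
#' @export
pairGeometry <- function(a, b, kind = "", tag = "") {
  new("PairGeometry",
      crossingAngle = crossingAngle(a, b),
      displacement = centroidDisplacement(a, b),
      members = c(a@chain, b@chain), kind = kind, tag = tag)
}
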