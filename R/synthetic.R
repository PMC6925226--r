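## Synthetic shells with ground truth: ideal marker helices, two-domain toy
## monomers, C5/C6 rings and complete T=1/D5/D6/T=3 shells whose ring radii,
## interface crossing angles and displacements are controlled exactly.
##
## Toy monomers are minimal: an NTD "blob" of backbone triplets (residues
## 60-99) carrying the S79/D90 marker atoms and the R143 switch residue, a
## CTD body carrying the D171/Q181/K182/K229 fingerprint atoms, one alpha-8
## marker helix, and (in shells) a contact-knob atom at the designated
## interface.  The analysis consumes only backbone/marker geometry, so
## fixtures are fast and fully controlled rather than physically packed.

.HELIX_DEFAULTS <- list(rise = 1.5, twist = 100, radius = 2.3)

## Ideal helix in the z-frame.  The N/CA/C triplet of each residue is placed
## symmetrically around the helical circle (120 degrees apart, -0.5/0/+0.5
## along z), so the per-residue backbone centroid lies exactly on the axis
## and the half-centroid helix vector is exactly axial.
idealHelixCoords <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- rep(seq_len(n) - 1L, each = 3L)
  off <- rep(c(-1, 0, 1), n)
  ang <- (i * twist + off * 120) * pi / 180
  z <- i * rise + off * 0.5
  pos <- cbind(radius * cos(ang), radius * sin(ang), z)
  list(pos = pos, res = i + 1L, name = rep(c("N", "CA", "C"), n))
}

#' Generate an ideal poly-alanine marker helix
#'
#' Backbone (N, CA, C) atoms on an ideal helical path about \code{axis}
#' through \code{origin}: rise 1.5 Angstrom and twist 100 degrees per residue,
#' backbone circle radius 2.3 Angstrom.  The residue triplet is placed so the
#' per-residue backbone centroid lies exactly on the helix axis, making the
#' half-centroid helix vector exactly axial at zero noise.  Optional isotropic
#' Gaussian coordinate noise; deterministic for a fixed seed.
#'
#' @param nResidues number of residues (>= 4).
#' @param rise,twist,helixRadius helix parameters (Angstrom, degrees,
#'   Angstrom).
#' @param axis helix axis (unit not required; normalised).
#' @param origin point on the axis at the first residue.
#' @param chain chain id.
#' @param resStart first residue number.
#' @param seed RNG seed for the noise (required when noiseSigma > 0).
#' @param noiseSigma isotropic Gaussian noise sigma (Angstrom).
#' @return a \linkS4class{StructureModel}
#' @export
makeIdealHelix <- function(nResidues, rise = 1.5, twist = 100,
                           helixRadius = 2.3, axis = c(0, 0, 1),
                           origin = c(0, 0, 0), chain = "A", resStart = 1L,
                           seed = NULL, noiseSigma = 0) {
  if (nResidues < 4L) capsParamError("need >= 4 residues for a helix")
  h <- idealHelixCoords(nResidues, rise, twist, helixRadius)
  axis <- unitVector(axis)
  R <- rotationBetween(c(0, 0, 1), axis)
  pos <- h$pos %*% t(R) + matrix(origin, nrow(h$pos), 3L, byrow = TRUE)
  if (noiseSigma > 0)
    pos <- pos + withLocalSeed(seed,
      matrix(rnorm(length(pos), 0, noiseSigma), nrow(pos), 3L))
  atoms <- data.frame(
    name = h$name, res_name = "ALA", chain_id = chain,
    res_seq = h$res + resStart - 1L,
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L], stringsAsFactors = FALSE)
  newStructureModel(atoms)
}

## Proper rotation taking unit vector a to unit vector b.
rotationBetween <- function(a, b) {
  a <- unitVector(a); b <- unitVector(b)
  c <- sum(a * b)
  if (c > 1 - 1e-12) return(diag(3L))
  if (c < -1 + 1e-12) {
    fr <- perpFrame(a)
    return(axisAngleMatrix(fr$e1, pi))
  }
  axisAngleMatrix(pracmaCross(a, b), acos(max(-1, min(1, c))))
}

## Helix atom rows rigidly mapped so that the measured whole-helix centroid
## and half-centroid direction are exactly the targets.
placedHelixRows <- function(chain, interval, centroid, direction) {
  n <- interval[2L] - interval[1L] + 1L
  h <- idealHelixCoords(n, .HELIX_DEFAULTS$rise, .HELIX_DEFAULTS$twist,
                        .HELIX_DEFAULTS$radius)
  c0 <- colMeans(h$pos)                    # on the z axis by construction
  R <- rotationBetween(c(0, 0, 1), direction)
  pos <- h$pos %*% t(R)
  pos <- pos + matrix(centroid - colMeans(pos), nrow(pos), 3L, byrow = TRUE)
  data.frame(name = h$name, res_name = "ALA", chain_id = chain,
             res_seq = h$res + interval[1L] - 1L,
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             stringsAsFactors = FALSE)
}

#' Two-helix interface fixture
#'
#' Two ideal marker helices (chains A and B, marker-interval numbering) whose
#' half-centroid vectors cross at exactly \code{angle} degrees and whose
#' whole-helix centroids are exactly \code{displacement} Angstrom apart: the
#' helix directions are \eqn{\cos(\gamma/2) e_1 \pm \sin(\gamma/2) e_2} and
#' the centroids sit at \eqn{\pm d/2} along the mutual perpendicular.
#'
#' @param angle target crossing angle, degrees in [0, 180].
#' @param displacement target centroid displacement, Angstrom >= 0.
#' @param scheme a \linkS4class{DomainScheme} (provides the marker interval).
#' @return a \linkS4class{StructureModel} with chains "A" and "B"
#' @export
makeTwoHelixFixture <- function(angle, displacement,
                                scheme = domainScheme()) {
  if (angle < 0 || angle > 180) capsParamError("angle must be in [0, 180]")
  if (displacement < 0) capsParamError("displacement must be >= 0")
  iv <- markerInterval(scheme)
  g <- angle * pi / 180
  d1 <- c(cos(g / 2), sin(g / 2), 0)
  d2 <- c(cos(g / 2), -sin(g / 2), 0)
  w <- c(0, 0, 1)
  a <- placedHelixRows("A", iv, (displacement / 2) * w, d1)
  b <- placedHelixRows("B", iv, (-displacement / 2) * w, d2)
  newStructureModel(rbind(a, b))
}

## ---- toy monomer bodies -------------------------------------------------

## Deterministic quasi-uniform directions (golden-angle spiral on the sphere).
spiralDirections <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z * z))
  ang <- k * pi * (3 - sqrt(5))
  cbind(r * cos(ang), r * sin(ang), z)
}

.BLOB_RESIDUES <- 60:99
.BLOB_RADIUS <- 1.5

atomRows <- function(chain, res, name, resName, pos) {
  data.frame(name = name, res_name = resName, chain_id = chain,
             res_seq = as.integer(res),
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             stringsAsFactors = FALSE)
}

## NTD blob backbone: 40 residue triplets on a small sphere around `centre`.
blobRows <- function(chain, centre) {
  nres <- length(.BLOB_RESIDUES)
  dirs <- spiralDirections(nres)
  ca <- dirs * .BLOB_RADIUS + matrix(centre, nres, 3L, byrow = TRUE)
  oN <- matrix(c(0.30, 0.12, -0.15), nres, 3L, byrow = TRUE)
  oC <- matrix(c(-0.22, 0.25, 0.14), nres, 3L, byrow = TRUE)
  pos <- matrix(0, 3L * nres, 3L)
  pos[seq(1L, 3L * nres, by = 3L), ] <- ca + oN
  pos[seq(2L, 3L * nres, by = 3L), ] <- ca
  pos[seq(3L, 3L * nres, by = 3L), ] <- ca + oC
  atomRows(chain, rep(.BLOB_RESIDUES, each = 3L),
           rep(c("N", "CA", "C"), nres), "ALA", pos)
}

## Fingerprint distances by conformational state (Angstrom):
## d171_s79' and k229_d90', plus how R143 is satisfied.
.STATE_GEOM <- list(
  pentamer = list(dDS = 2.9, dKD = 2.9, r143 = "k182"),
  hexamer = list(dDS = 3.2, dKD = 8.0, r143 = "q181"),
  indeterminate = list(dDS = 6.0, dKD = 8.0, r143 = "none"))

## Body atoms (everything except the marker helix and the contact knob) of
## ring member k, in the ring frame.  `u` is the ring axis, e1/e2 span the
## ring plane; zN/zC are the NTD/CTD layer offsets along u from ringCentre.
memberBodyRows <- function(chain, k, fold, ringCentre, u, e1, e2,
                           zN, zC, state, rhoN = 4, rhoC = 4) {
  psi <- 2 * pi * k / fold
  psi1 <- 2 * pi * ((k + 1L) %% fold) / fold
  rk <- cos(psi) * e1 + sin(psi) * e2
  tk <- -sin(psi) * e1 + cos(psi) * e2
  rk1 <- cos(psi1) * e1 + sin(psi1) * e2
  tk1 <- -sin(psi1) * e1 + cos(psi1) * e2
  nb <- ringCentre + zN * u + rhoN * rk
  nb1 <- ringCentre + zN * u + rhoN * rk1
  cb <- ringCentre + zC * u + rhoC * rk
  g <- .STATE_GEOM[[state]]

  s79 <- nb + 1.2 * tk
  d90 <- nb + 1.1 * tk + 0.9 * rk
  s79next <- nb1 + 1.2 * tk1
  d90next <- nb1 + 1.1 * tk1 + 0.9 * rk1
  d171 <- s79next - g$dDS * u
  k229 <- d90next - g$dKD * u
  k182O <- cb
  q181 <- cb + 5 * tk
  r143 <- switch(g$r143,
                 k182 = k182O + 2.9 * u,
                 q181 = q181 + 2.9 * u,
                 none = cb + 5.5 * u)
  one <- function(res, name, resName, p)
    atomRows(chain, res, name, resName, matrix(p, 1L, 3L))
  rbind(
    blobRows(chain, nb),
    one(79L, "OG", "SER", s79),
    one(90L, "OD1", "ASP", d90),
    one(143L, "NH1", "ARG", r143),
    one(143L, "N", "ARG", r143 + 1.1 * rk),
    one(143L, "CA", "ARG", r143 + 1.1 * rk + 0.8 * tk),
    one(143L, "C", "ARG", r143 + 1.1 * rk - 0.8 * tk),
    one(171L, "OD1", "ASP", d171),
    one(171L, "CA", "ASP", d171 + 0.8 * rk),
    one(181L, "NE2", "GLN", q181),
    one(181L, "CA", "GLN", q181 + 0.8 * rk),
    one(182L, "O", "LYS", k182O),
    one(182L, "N", "LYS", k182O + 1.0 * rk),
    one(182L, "CA", "LYS", k182O + 1.0 * rk + 0.7 * tk),
    one(182L, "C", "LYS", k182O + 0.6 * tk),
    one(229L, "NZ", "LYS", k229),
    one(229L, "CA", "LYS", k229 + 0.8 * rk))
}

#' Build a standalone C5/C6 ring with exact layer metrics
#'
#' A ring of \code{fold} toy monomers about the +z axis, centred so that the
#' mass-weighted NTD layer centre of mass sits exactly at
#' \code{(0, 0, ntdRadius)} and the CTD layer CoM exactly at
#' \code{(0, 0, ctdRadius)}: with the particle centre at the origin and axis
#' +z, \code{\link{layerMetrics}} recovers the two radii and their difference
#' (the vertical NTD-CTD displacement) exactly.  The exact placement is
#' obtained by solving the two layer heights after all state-dependent marker
#' atoms are positioned.
#'
#' @param fold 5 or 6.
#' @param ntdRadius,ctdRadius target layer CoM radii (defaults 86.3/64.7,
#'   hence a 21.6 Angstrom vertical displacement).
#' @param state "pentamer", "hexamer" or "indeterminate": controls the
#'   NTD-CTD fingerprint geometry of every member.
#' @param chains chain ids (default first \code{fold} letters).
#' @param seed,noiseSigma optional isotropic coordinate noise.
#' @return a \linkS4class{StructureModel}
#' @export
makeRing <- function(fold = 5L, ntdRadius = 86.3, ctdRadius = 64.7,
                     state = c("pentamer", "hexamer", "indeterminate"),
                     chains = NULL, seed = NULL, noiseSigma = 0) {
  state <- match.arg(state)
  if (!fold %in% c(5L, 6L)) capsParamError("fold must be 5 or 6")
  if (is.null(chains)) chains <- chainIdSequence(fold)
  u <- c(0, 0, 1); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  rows <- lapply(seq_len(fold) - 1L, function(k)
    memberBodyRows(chains[k + 1L], k, fold, c(0, 0, 0), u, e1, e2,
                   zN = ntdRadius, zC = ctdRadius, state = state))
  body <- do.call(rbind, rows)
  ## symmetric marker helices at the CTD layer (tangential direction)
  helixRows <- lapply(seq_len(fold) - 1L, function(k) {
    psi <- 2 * pi * k / fold
    rk <- cos(psi) * e1 + sin(psi) * e2
    tk <- -sin(psi) * e1 + cos(psi) * e2
    placedHelixRows(chains[k + 1L], markerInterval(domainScheme()),
                    c(0, 0, ctdRadius) + 6 * rk, tk)
  })
  atoms <- rbind(body, do.call(rbind, helixRows))
  atoms <- solveLayerHeights(atoms, ntdRadius, ctdRadius)
  if (noiseSigma > 0) {
    jitter <- withLocalSeed(seed,
      matrix(rnorm(3L * nrow(atoms), 0, noiseSigma), nrow(atoms), 3L))
    atoms$x <- atoms$x + jitter[, 1L]
    atoms$y <- atoms$y + jitter[, 2L]
    atoms$z <- atoms$z + jitter[, 3L]
  }
  newStructureModel(atoms)
}

## Translate (a) the NTD blob + S79/D90 markers and (b) the marker helices
## so the mass-weighted NTD and CTD layer CoMs land exactly on the target
## points (on the ring axis at the two layer radii).  Solved sequentially:
## the NTD equation involves only the blob-tied atoms (R143 sits at a fixed
## CTD-layer position), after which D171/K229 (placed relative to S79'/D90')
## are re-tied by the same shift and the CTD equation is solved for the
## helix placement.
solveLayerHeights <- function(atoms, ntdTarget, ctdTarget) {
  sch <- domainScheme()
  w <- elementMasses(elementFromName(atoms$name))
  xyz <- c("x", "y", "z")
  isN <- atoms$res_seq >= sch@ntd[1L] & atoms$res_seq <= sch@ntd[2L]
  isC <- atoms$res_seq >= sch@ctd[1L] & atoms$res_seq <= sch@ctd[2L]
  movN <- atoms$res_seq %in% .BLOB_RESIDUES
  com <- function(sel)
    vapply(xyz, function(cc) sum(w[sel] * atoms[[cc]][sel]) / sum(w[sel]), 0)
  shift <- function(sel, d)
    for (i in 1:3) atoms[[xyz[i]]][sel] <<- atoms[[xyz[i]]][sel] + d[i]
  dN <- (c(0, 0, ntdTarget) - com(isN)) * sum(w[isN]) / sum(w[isN & movN])
  shift(movN, dN)
  ## D171/K229 follow their S79'/D90' anchors
  shift(atoms$res_seq %in% c(171L, 229L), dN)
  mk <- markerInterval(sch)
  movH <- atoms$res_seq >= mk[1L] & atoms$res_seq <= mk[2L]
  dC <- (c(0, 0, ctdTarget) - com(isC)) * sum(w[isC]) / sum(w[isC & movH])
  shift(movH, dC)
  atoms
}

#' Build a toy CA monomer
#'
#' One monomer of a default ring (see \code{\link{makeRing}}): an NTD blob
#' plus CTD body and marker helix, numbered per the default
#' \linkS4class{DomainScheme}, with the NTD-CTD fingerprint geometry of the
#' requested conformational state.  For fingerprint tests use
#' \code{\link{makeRing}} and pick adjacent chains (the state's inter-monomer
#' distances are realised between ring neighbours).
#'
#' @param state "pentamer", "hexamer" or "indeterminate".
#' @param fold ring context (5 or 6).
#' @param chain chain id.
#' @return a single-chain \linkS4class{StructureModel}
#' @export
makeToyMonomer <- function(state = c("pentamer", "hexamer", "indeterminate"),
                           fold = NULL, chain = "A") {
  state <- match.arg(state)
  if (is.null(fold)) fold <- if (state == "hexamer") 6L else 5L
  others <- setdiff(chainIdSequence(fold + 1L), chain)[seq_len(fold - 1L)]
  ring <- makeRing(fold = fold, state = state, chains = c(chain, others))
  selectAtoms(ring, chains = chain)
}

## ---- icosahedral direction tables --------------------------------------

icoVertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

icoAdjacency <- function(V) {
  d <- tcrossprod(V)
  which(d > 0.4 & d < 0.5 & upper.tri(d), arr.ind = TRUE)
}

icoFaces <- function(V) {
  adj <- tcrossprod(V) > 0.4 & tcrossprod(V) < 0.5
  faces <- list()
  n <- nrow(V)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (adj[i, j] && adj[j, k] && adj[i, k])
      faces[[length(faces) + 1L]] <- c(i, j, k)
  faces
}

## ---- shell recipes and construction ------------------------------------

#' Shell recipe
#'
#' Generator parameters for a synthetic shell.  Defaults mirror the measured
#' particle geometry: T=3 pentamer/hexamer ring radii 143.9/136.5 Angstrom, a
#' 21.6 Angstrom NTD-CTD layer separation, T=1 CTD (interface) layer at
#' 64.7 Angstrom, and interface geometry 65 degrees/12 Angstrom at
#' pentamer-pentamer and pentamer-hexamer contacts and 95 degrees/14 Angstrom
#' at hexamer-hexamer contacts.  Capsule ring radii are not printed for the
#' deposited particles and default to 90 (D5) and 95 (D6) Angstrom,
#' intermediate between the T=1 and T=3 scales.
#'
#' @param class "T1", "D5", "D6" or "T3".
#' @param pentamerRadius,hexamerRadius ring centroid radii (Angstrom).
#' @param elongation polar elongation of capsules (Angstrom): the two
#'   hemispheres of ring centres are shifted apart by this amount along the
#'   principal axis, which is what makes D5/D6 particles capsular rather
#'   than spherical.  0 for icosahedral classes.
#' @param layerSeparation NTD-CTD layer separation within a monomer
#'   (Angstrom).
#' @param interfaceGeometry named list: for each interface kind, c(crossing
#'   angle degrees, displacement Angstrom).
#' @param noiseSigma isotropic Gaussian coordinate noise (Angstrom).
#' @param seed RNG seed (recorded in the manifest).
#' @return a list of class "shellRecipe"
#' @export
shellRecipe <- function(class = c("T1", "D5", "D6", "T3"),
                        pentamerRadius = NULL, hexamerRadius = NULL,
                        elongation = NULL,
                        layerSeparation = 21.6,
                        interfaceGeometry = list(
                          "pentamer-pentamer" = c(65, 12),
                          "pentamer-hexamer" = c(65, 12),
                          "hexamer-hexamer" = c(95, 14)),
                        noiseSigma = 0, seed = 1L) {
  class <- match.arg(class)
  def <- switch(class,
    T1 = list(p = 75.5, h = NA, e = 0),
    T3 = list(p = 143.9, h = 136.5, e = 0),
    D5 = list(p = 90, h = 90, e = 30),
    D6 = list(p = 95, h = 95, e = 30))
  if (is.null(pentamerRadius)) pentamerRadius <- def$p
  if (is.null(hexamerRadius)) hexamerRadius <- def$h
  if (is.null(elongation)) elongation <- def$e
  if (pentamerRadius <= 0 || (!is.na(hexamerRadius) && hexamerRadius <= 0))
    capsParamError("ring radii must be positive")
  if (noiseSigma < 0) capsParamError("noiseSigma must be >= 0")
  structure(list(class = class, pentamerRadius = pentamerRadius,
                 hexamerRadius = hexamerRadius, elongation = elongation,
                 layerSeparation = layerSeparation,
                 interfaceGeometry = interfaceGeometry,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "shellRecipe")
}

## Ring direction table + interface (ringA, ringB) list per shell class.
shellTopology <- function(class) {
  deg <- pi / 180
  if (class %in% c("T1", "T3")) {
    V <- icoVertices()
    rings <- data.frame(x = V[, 1L], y = V[, 2L], z = V[, 3L], fold = 5L)
    edges <- icoAdjacency(V)
    if (class == "T1") {
      interfaces <- lapply(seq_len(nrow(edges)), function(e)
        c(edges[e, 1L], edges[e, 2L]))
    } else {
      faces <- icoFaces(V)
      F <- t(vapply(faces, function(f) unitVector(colSums(V[f, ])),
                    numeric(3L)))
      rings <- rbind(rings, data.frame(x = F[, 1L], y = F[, 2L], z = F[, 3L],
                                       fold = 6L))
      interfaces <- list()
      for (fi in seq_along(faces)) for (v in faces[[fi]])
        interfaces[[length(interfaces) + 1L]] <- c(v, 12L + fi)
      for (fi in 1:(length(faces) - 1L)) for (fj in (fi + 1L):length(faces))
        if (length(intersect(faces[[fi]], faces[[fj]])) == 2L)
          interfaces[[length(interfaces) + 1L]] <- c(12L + fi, 12L + fj)
    }
  } else if (class == "D5") {
    thU <- acos(1 / sqrt(5))
    dirAt <- function(th, lon) c(sin(th) * cos(lon), sin(th) * sin(lon),
                                 cos(th))
    rings <- rbind(
      data.frame(x = 0, y = 0, z = 1, fold = 5L),                  # 1 top
      do.call(rbind, lapply(0:4, function(k) {                     # 2-6 upper
        d <- dirAt(thU, 72 * k * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 5L)
      })),
      do.call(rbind, lapply(0:4, function(k) {                     # 7-11 lower
        d <- dirAt(pi - thU, (36 + 72 * k) * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 5L)
      })),
      data.frame(x = 0, y = 0, z = -1, fold = 5L),                 # 12 bottom
      do.call(rbind, lapply(0:4, function(k) {                     # 13-17 hex
        d <- dirAt(pi / 2, (36 + 72 * k) * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 6L)
      })))
    up <- function(k) 2L + k %% 5L
    lo <- function(k) 7L + k %% 5L
    hx <- function(k) 13L + k %% 5L
    interfaces <- list()
    for (k in 0:4) {
      interfaces <- c(interfaces,
        list(c(1L, up(k)), c(12L, lo(k)),                 # polar P-P
             c(up(k), up(k + 1)), c(lo(k), lo(k + 1)),    # ring P-P
             c(hx(k), up(k)), c(hx(k), up(k + 1)),        # P-H
             c(hx(k), lo(k)), c(hx(k), lo(k + 1)),
             c(hx(k), hx(k + 1))))                        # H-H
    }
  } else {  # D6
    thP <- 52 * deg
    dirAt <- function(th, lon) c(sin(th) * cos(lon), sin(th) * sin(lon),
                                 cos(th))
    rings <- rbind(
      data.frame(x = 0, y = 0, z = 1, fold = 6L),                  # 1 polar top
      data.frame(x = 0, y = 0, z = -1, fold = 6L),                 # 2 polar bot
      do.call(rbind, lapply(0:5, function(k) {                     # 3-8 top P
        d <- dirAt(thP, 60 * k * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 5L)
      })),
      do.call(rbind, lapply(0:5, function(k) {                     # 9-14 bot P
        d <- dirAt(pi - thP, (30 + 60 * k) * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 5L)
      })),
      do.call(rbind, lapply(0:5, function(k) {                     # 15-20 eq H
        d <- dirAt(pi / 2, (30 + 60 * k) * deg)
        data.frame(x = d[1L], y = d[2L], z = d[3L], fold = 6L)
      })))
    tp <- function(k) 3L + k %% 6L
    bp <- function(k) 9L + k %% 6L
    eh <- function(k) 15L + k %% 6L
    interfaces <- list()
    for (k in 0:5) {
      interfaces <- c(interfaces,
        list(c(1L, tp(k)), c(2L, bp(k)),                  # polar P-H
             c(tp(k), tp(k + 1)), c(bp(k), bp(k + 1)),    # ring P-P
             c(eh(k), tp(k)), c(eh(k), tp(k + 1)),        # eq P-H
             c(eh(k), bp(k)), c(eh(k), bp(k + 1)),
             c(eh(k), eh(k + 1))))                        # eq H-H
    }
  }
  rownames(rings) <- NULL
  list(rings = rings, interfaces = interfaces)
}

#' Generate a complete synthetic shell with ground-truth manifest
#'
#' Builds the requested shell class (T=1, D5, D6 or T=3) from toy monomers:
#' pentamer rings at the icosahedral five-fold directions (and hexamer rings
#' at the three-fold/equatorial positions as the class requires) at the
#' recipe radii, one CTD-CTD interface per inter-ring contact with exactly
#' the recipe's crossing angle and centroid displacement, and a contact-knob
#' atom pair marking each designated interface.  Each ring's all-atom
#' centroid is placed exactly at its recipe radius.  Chain counts equal the
#' \code{\link{casparKlug}}/\code{\link{capsuleComposition}} predictions.
#'
#' @param recipe a \code{\link{shellRecipe}} (or a class name, taking recipe
#'   defaults).
#' @return list with elements \code{model} (a
#'   \linkS4class{StructureModel}) and \code{manifest} (ground truth: per
#'   chain ring and fold, per ring axis/centroid/radius, per interface kind,
#'   true angle, true displacement and topology tag, plus all generator
#'   parameters and the seed).
#' @export
makeShell <- function(recipe = shellRecipe("T1")) {
  if (is.character(recipe)) recipe <- shellRecipe(recipe)
  if (!inherits(recipe, "shellRecipe"))
    capsParamError("recipe must come from shellRecipe()")
  topo <- shellTopology(recipe$class)
  rings <- topo$rings
  nR <- nrow(rings)
  folds <- rings$fold
  nChains <- sum(folds)
  comp <- switch(recipe$class,
    T1 = casparKlug(1, 0), T3 = casparKlug(1, 1),
    D5 = capsuleComposition(5, 1), D6 = capsuleComposition(6, 1))
  stopifnot(nChains == comp@monomers)
  chains <- chainIdSequence(nChains)
  ringChainIdx <- split(seq_len(nChains),
                        factor(rep(seq_len(nR), folds), levels = seq_len(nR)))
  ringRadius <- ifelse(folds == 5L, recipe$pentamerRadius,
                       recipe$hexamerRadius)
  D <- as.matrix(rings[, c("x", "y", "z")])  # unit lattice directions
  ## capsule elongation: shift each hemisphere of ring centres apart along z
  centres <- D * ringRadius +
    cbind(0, 0, sign(round(D[, 3L], 6L)) * recipe$elongation / 2)
  U <- t(apply(centres, 1L, unitVector))     # ring axes (radial)
  frames <- lapply(seq_len(nR), function(r) {
    fr <- perpFrame(U[r, ])
    list(u = U[r, ], e1 = fr$e1, e2 = fr$e2, centre = centres[r, ])
  })

  ## assign one free member of each ring to each of its interfaces
  nextFree <- rep(1L, nR)
  ifaceRows <- list()
  helixTargets <- vector("list", nChains)
  knobs <- vector("list", nChains)
  zN <- recipe$layerSeparation / 2
  zC <- -recipe$layerSeparation / 2
  for (e in seq_along(topo$interfaces)) {
    ab <- topo$interfaces[[e]]
    rA <- ab[1L]; rB <- ab[2L]
    mA <- nextFree[rA]; nextFree[rA] <- mA + 1L
    mB <- nextFree[rB]; nextFree[rB] <- mB + 1L
    if (mA > folds[rA] || mB > folds[rB])
      capsGeometryError("interface table exceeds ring folds")
    chA <- chains[ringChainIdx[[rA]][mA]]
    chB <- chains[ringChainIdx[[rB]][mB]]
    kind <- paste(sort(c(ifelse(folds[rA] == 5L, "pentamer", "hexamer"),
                         ifelse(folds[rB] == 5L, "pentamer", "hexamer")),
                       decreasing = TRUE), collapse = "-")
    geo <- recipe$interfaceGeometry[[kind]]
    ## interface midpoint between the two rings' CTD-layer anchors
    p <- (frames[[rA]]$centre + zC * frames[[rA]]$u +
            frames[[rB]]$centre + zC * frames[[rB]]$u) / 2
    w <- unitVector(p)
    t0 <- frames[[rB]]$centre - frames[[rA]]$centre
    e1 <- unitVector(t0 - sum(t0 * w) * w)
    e2 <- pracmaCross(w, e1)
    g <- geo[1L] * pi / 180
    helixTargets[[match(chA, chains)]] <- list(
      centroid = p + (geo[2L] / 2) * w,
      direction = cos(g / 2) * e1 + sin(g / 2) * e2)
    helixTargets[[match(chB, chains)]] <- list(
      centroid = p - (geo[2L] / 2) * w,
      direction = cos(g / 2) * e1 - sin(g / 2) * e2)
    knobs[[match(chA, chains)]] <- p + 1.4 * w
    knobs[[match(chB, chains)]] <- p - 1.4 * w
    tag <- ""
    if (recipe$class %in% c("D5", "D6")) {
      polar <- abs(U[c(rA, rB), 3L]) > cos(pi / 4)
      tag <- if (all(polar)) "POLAR"
             else if (abs(unitVector(t0)[3L]) > cos(pi / 4)) "LONG" else "LAT"
    }
    ifaceRows[[e]] <- data.frame(
      chain_a = chA, chain_b = chB, ring_a = rA, ring_b = rB, kind = kind,
      angle = geo[1L], displacement = geo[2L], tag = tag,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(nextFree == folds + 1L))

  ## build atoms ring by ring, then anchor each ring's all-atom centroid
  allRows <- vector("list", nR)
  for (r in seq_len(nR)) {
    f <- frames[[r]]
    state <- if (folds[r] == 5L) "pentamer" else "hexamer"
    memberRows <- lapply(seq_len(folds[r]) - 1L, function(k) {
      ch <- chains[ringChainIdx[[r]][k + 1L]]
      body <- memberBodyRows(ch, k, folds[r], f$centre, f$u, f$e1, f$e2,
                             zN, zC, state)
      ht <- helixTargets[[match(ch, chains)]]
      helix <- placedHelixRows(ch, markerInterval(domainScheme()),
                               ht$centroid, ht$direction)
      knob <- atomRows(ch, 210L, "CA", "GLY",
                       matrix(knobs[[match(ch, chains)]], 1L, 3L))
      rbind(body, helix, knob)
    })
    ringAtoms <- do.call(rbind, memberRows)
    ## translate the NTD blob backbone so the ring's unweighted all-atom
    ## centroid sits exactly at the recipe radius along the ring direction
    target <- f$centre
    mean0 <- c(mean(ringAtoms$x), mean(ringAtoms$y), mean(ringAtoms$z))
    movable <- ringAtoms$res_seq %in% .BLOB_RESIDUES &
      ringAtoms$name %in% c("N", "CA", "C")
    delta <- (target - mean0) * nrow(ringAtoms) / sum(movable)
    ringAtoms$x[movable] <- ringAtoms$x[movable] + delta[1L]
    ringAtoms$y[movable] <- ringAtoms$y[movable] + delta[2L]
    ringAtoms$z[movable] <- ringAtoms$z[movable] + delta[3L]
    allRows[[r]] <- ringAtoms
  }
  atoms <- do.call(rbind, allRows)
  if (recipe$noiseSigma > 0) {
    jitter <- withLocalSeed(recipe$seed,
      matrix(rnorm(3L * nrow(atoms), 0, recipe$noiseSigma), nrow(atoms), 3L))
    atoms$x <- atoms$x + jitter[, 1L]
    atoms$y <- atoms$y + jitter[, 2L]
    atoms$z <- atoms$z + jitter[, 3L]
  }
  model <- newStructureModel(atoms, title = sprintf("synthetic %s shell",
                                                    recipe$class))
  manifest <- list(
    class = recipe$class,
    seed = recipe$seed,
    noiseSigma = recipe$noiseSigma,
    composition = list(monomers = comp@monomers, pentamers = comp@pentamers,
                       hexamers = comp@hexamers),
    params = recipe[c("pentamerRadius", "hexamerRadius", "elongation",
                      "layerSeparation")],
    chains = data.frame(
      chain = chains,
      ring = rep(seq_len(nR), folds),
      fold = rep(folds, folds), stringsAsFactors = FALSE),
    rings = data.frame(
      ring = seq_len(nR), fold = folds,
      axis_x = U[, 1L], axis_y = U[, 2L], axis_z = U[, 3L],
      radius = sqrt(rowSums(centres^2)), stringsAsFactors = FALSE),
    interfaces = do.call(rbind, ifaceRows))
  list(model = model, manifest = manifest)
}
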