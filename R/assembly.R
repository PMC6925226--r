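## Whole-particle pipeline: particle centre, pentamer/hexamer ring detection
## from NTD-NTD contacts, CTD-CTD interface enumeration and group
## classification, per-ring radial profiles and NTD-CTD conformational-state
## fingerprints.

#' Particle centre
#'
#' Unweighted centroid of all non-hydrogen atoms.  For a point-group-expanded
#' shell this is the symmetry origin.
#'
#' @param x a \linkS4class{StructureModel}.
#' @return length-3 numeric
#' @export
particleCentre <- function(x) {
  h <- heavyAtoms(x)
  if (nAtoms(h) == 0L) capsAnalysisError("no heavy atoms in assembly")
  unname(colMeans(coords(h)))
}

## Split heavy-atom coordinates by chain for a residue interval.
chainCoordsByInterval <- function(x, interval) {
  h <- heavyAtoms(x)
  a <- h@atoms
  a <- a[a$res_seq >= interval[1L] & a$res_seq <= interval[2L], ]
  split(cbind(a$x, a$y, a$z), a$chain_id) |>
    lapply(function(v) matrix(v, ncol = 3L))
}

## Minimum inter-set distance with a bounding-sphere prefilter.
minPairDist <- function(A, B, cutoff = Inf, cA = NULL, rA = NULL,
                        cB = NULL, rB = NULL) {
  if (is.null(cA)) { cA <- colMeans(A); rA <- sqrt(max(rowSums(sweep(A, 2L, cA)^2))) }
  if (is.null(cB)) { cB <- colMeans(B); rB <- sqrt(max(rowSums(sweep(B, 2L, cB)^2))) }
  lb <- sqrt(sum((cA - cB)^2)) - rA - rB
  if (lb > cutoff) return(Inf)
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Detect pentamer/hexamer rings
#'
#' Builds a contact graph on chains with an edge whenever the minimum
#' non-hydrogen interatomic distance between the two chains' NTD selections is
#' below \code{cutoff} (NTDs cluster at the ring axes, so connected components
#' are rings).  Every component must have 5 or 6 members; anything else
#' signals a wrong cutoff or a broken assembly and raises an analysis error
#' listing the offending component.
#'
#' @param x a \linkS4class{StructureModel} (the assembly).
#' @param scheme a \linkS4class{DomainScheme}.
#' @param cutoff NTD-NTD contact cutoff in Angstrom (default 6.0).
#' @param centre particle centre; computed if NULL.
#' @return a list with elements \code{rings} (list of per-ring lists: id,
#'   chains ordered around the ring axis, fold, centroid, radius, axis) and
#'   \code{chainRing} (named vector mapping chain id to ring id).
#' @export
detectRings <- function(x, scheme = domainScheme(), cutoff = 6.0,
                        centre = NULL) {
  if (is.null(centre)) centre <- particleCentre(x)
  ntd <- chainCoordsByInterval(x, scheme@ntd)
  chains <- chainIds(x)
  missing <- setdiff(chains, names(ntd))
  if (length(missing))
    capsAnalysisError(sprintf("chain(s) without NTD atoms: %s",
                              paste(missing, collapse = ", ")))
  ntd <- ntd[chains]
  n <- length(chains)
  if (n < 5L) capsAnalysisError("need >= 5 chains to detect rings")
  cents <- t(vapply(ntd, colMeans, numeric(3L)))
  radii <- vapply(seq_len(n), function(i)
    sqrt(max(rowSums(sweep(ntd[[i]], 2L, cents[i, ])^2))), 0)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    ## bounding-sphere prefilter keeps this O(n^2) loop cheap
    dc <- sqrt(rowSums(sweep(cents[(i + 1L):n, , drop = FALSE], 2L,
                             cents[i, ])^2))
    cand <- which(dc - radii[i] - radii[(i + 1L):n] <= cutoff) + i
    for (j in cand) {
      if (minPairDist(ntd[[i]], ntd[[j]], cutoff, cents[i, ], radii[i],
                      cents[j, ], radii[j]) < cutoff)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  bad <- names(sizes)[!sizes %in% c(5L, 6L)]
  if (length(bad)) {
    listing <- vapply(bad, function(b)
      sprintf("{%s}", paste(chains[comp == as.integer(b)], collapse = ",")), "")
    capsAnalysisError(sprintf(
      "ring detection found component(s) of size not in {5,6}: %s (check the contact cutoff)",
      paste(listing, collapse = " ")))
  }
  ## heavy-atom coordinates per chain for centroid/radius
  allc <- chainCoordsByInterval(x, c(-.Machine$integer.max, .Machine$integer.max))
  rings <- list()
  compIds <- unique(comp)
  firstChain <- vapply(compIds, function(cid) min(chains[comp == cid]), "")
  compIds <- compIds[order(firstChain)]
  for (k in seq_along(compIds)) {
    members <- chains[comp == compIds[k]]
    mc <- cents[match(members, chains), , drop = FALSE]
    ringCentroid <- colMeans(do.call(rbind, allc[members]))
    ## local axis: normal of the NTD-centroid circle, oriented outward
    pc <- sweep(mc, 2L, colMeans(mc))
    ev <- eigen(crossprod(pc), symmetric = TRUE)
    axis <- ev$vectors[, 3L]
    out <- ringCentroid - centre
    if (vecNorm(out) > 1e-6 && sum(axis * out) < 0) axis <- -axis
    fr <- perpFrame(axis)
    ang <- atan2(pc %*% fr$e2, pc %*% fr$e1)[, 1L]
    ord <- order(ang)
    start <- which(members[ord] == min(members))
    ord <- ord[c(start:length(ord), seq_len(start - 1L))]
    rings[[k]] <- list(
      id = sprintf("R%02d", k),
      chains = members[ord],
      fold = length(members),
      centroid = unname(ringCentroid),
      radius = vecNorm(ringCentroid - centre),
      axis = unname(axis))
  }
  chainRing <- unlist(lapply(rings, function(r)
    stats::setNames(rep(r$id, r$fold), r$chains)))
  list(rings = rings, chainRing = chainRing[chains], centre = centre)
}

#' Classify an interface by crossing angle
#'
#' Nearest-reference-angle rule with fixed boundaries at the midpoints of the
#' three reference centres (20, 65 and 95 degrees): angle < 42.5 is group 1
#' (solution-dimer-like), 42.5 <= angle < 80 is group 2 (pentamer-pentamer and
#' pentamer-hexamer interfaces), angle >= 80 is group 3 (hexamer-hexamer
#' interfaces).  Boundaries are deterministic and traceable, not fitted.
#'
#' @param geom a \linkS4class{PairGeometry}, or a numeric crossing angle in
#'   degrees.
#' @return list(group = 1/2/3, refAngle, refDistance)
#' @export
classifyInterface <- function(geom) {
  angle <- if (is(geom, "PairGeometry")) geom@crossingAngle else as.numeric(geom)
  if (is.na(angle) || angle < 0 || angle > 180)
    capsParamError("crossing angle must be in [0, 180] degrees")
  refs <- c(20, 65, 95)
  group <- if (angle < 42.5) 1L else if (angle < 80) 2L else 3L
  list(group = group, refAngle = refs[group],
       refDistance = abs(angle - refs[group]))
}

#' Enumerate and parameterise CTD-CTD interfaces
#'
#' For every pair of chains in different rings whose CTD selections approach
#' within \code{cutoff} (minimum heavy-atom distance), computes the marker
#' helix pair geometry, the interface kind from the two ring folds, the group
#' classification, and (for capsules, when \code{principalAxis} is given) a
#' POLAR/LONG/LAT topology tag: POLAR when both rings lie within 45 degrees
#' of the principal axis, otherwise LONG/LAT according to whether the
#' inter-ring contact vector is mostly parallel or perpendicular to the axis
#' (45 degree threshold).
#'
#' Each unordered chain pair is reported once; symmetric copies are kept (the
#' full list reproduces the interface point cloud).  Use
#' \code{\link{uniqueInterfaces}} to cluster equivalent records.
#'
#' @param x assembly \linkS4class{StructureModel}.
#' @param rings result of \code{\link{detectRings}}.
#' @param scheme a \linkS4class{DomainScheme}.
#' @param cutoff CTD-CTD heavy-atom contact cutoff in Angstrom (default 5.0).
#' @param principalAxis optional unit vector enabling POLAR/LONG/LAT tags.
#' @return data.frame, one row per interface, sorted by
#'   (ring_a, ring_b, chain_a): chain_a, chain_b, ring_a, ring_b, fold_a,
#'   fold_b, kind, angle, displacement, group, ref_distance, min_contact, tag.
#' @export
enumerateInterfaces <- function(x, rings, scheme = domainScheme(),
                                cutoff = 5.0, principalAxis = NULL) {
  ctd <- chainCoordsByInterval(x, scheme@ctd)
  chains <- chainIds(x)
  ctd <- ctd[chains]
  chainRing <- rings$chainRing
  ringOf <- lapply(rings$rings, function(r) r)
  names(ringOf) <- vapply(rings$rings, `[[`, "", "id")
  marker <- markerInterval(scheme)
  hv <- lapply(chains, function(ch) helixVector(x, marker, chain = ch))
  names(hv) <- chains
  n <- length(chains)
  cents <- t(vapply(ctd, colMeans, numeric(3L)))
  radii <- vapply(seq_len(n), function(i)
    sqrt(max(rowSums(sweep(ctd[[i]], 2L, cents[i, ])^2))), 0)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    dc <- sqrt(rowSums(sweep(cents[(i + 1L):n, , drop = FALSE], 2L,
                             cents[i, ])^2))
    cand <- which(dc - radii[i] - radii[(i + 1L):n] <= cutoff) + i
    for (j in cand) {
      ri <- chainRing[[chains[i]]]; rj <- chainRing[[chains[j]]]
      if (ri == rj) next
      md <- minPairDist(ctd[[i]], ctd[[j]], cutoff, cents[i, ], radii[i],
                        cents[j, ], radii[j])
      if (md >= cutoff) next
      fi <- ringOf[[ri]]$fold; fj <- ringOf[[rj]]$fold
      kind <- paste(sort(c(ifelse(fi == 5L, "pentamer", "hexamer"),
                           ifelse(fj == 5L, "pentamer", "hexamer")),
                         decreasing = TRUE), collapse = "-")
      geom <- pairGeometry(hv[[chains[i]]], hv[[chains[j]]], kind = kind)
      cl <- classifyInterface(geom)
      tag <- ""
      if (!is.null(principalAxis)) {
        p <- unitVector(principalAxis)
        lat <- function(r) abs(sum(unitVector(r$centroid - rings$centre) * p))
        if (lat(ringOf[[ri]]) > cos(pi / 4) && lat(ringOf[[rj]]) > cos(pi / 4))
          tag <- "POLAR"
        else {
          v <- unitVector(ringOf[[rj]]$centroid - ringOf[[ri]]$centroid)
          tag <- if (abs(sum(v * p)) > cos(pi / 4)) "LONG" else "LAT"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = chains[i], chain_b = chains[j], ring_a = ri, ring_b = rj,
        fold_a = fi, fold_b = fj, kind = kind,
        angle = geom@crossingAngle, displacement = geom@displacement,
        group = cl$group, ref_distance = cl$refDistance,
        min_contact = md, tag = tag, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyInterfaceTable())
  df <- do.call(rbind, rows)
  ## canonical member order, then deterministic sort
  swap <- df$ring_a > df$ring_b | (df$ring_a == df$ring_b & df$chain_a > df$chain_b)
  if (any(swap)) {
    tmp <- df[swap, ]
    df[swap, c("chain_a", "chain_b", "ring_a", "ring_b", "fold_a", "fold_b")] <-
      tmp[, c("chain_b", "chain_a", "ring_b", "ring_a", "fold_b", "fold_a")]
  }
  df <- df[order(df$ring_a, df$ring_b, df$chain_a), ]
  rownames(df) <- NULL
  df
}

emptyInterfaceTable <- function() {
  data.frame(chain_a = character(), chain_b = character(),
             ring_a = character(), ring_b = character(),
             fold_a = integer(), fold_b = integer(), kind = character(),
             angle = numeric(), displacement = numeric(), group = integer(),
             ref_distance = numeric(), min_contact = numeric(),
             tag = character(), stringsAsFactors = FALSE)
}

#' Cluster equivalent interface records
#'
#' Collapses records whose (angle, displacement) agree within the given
#' tolerances into one representative row with a \code{multiplicity} column.
#'
#' @param interfaces result of \code{\link{enumerateInterfaces}}.
#' @param angleTol,dispTol clustering tolerances (1 degree, 0.5 Angstrom).
#' @return data.frame of representatives
#' @export
uniqueInterfaces <- function(interfaces, angleTol = 1, dispTol = 0.5) {
  if (!nrow(interfaces)) {
    out <- emptyInterfaceTable(); out$multiplicity <- integer(); return(out)
  }
  key <- paste(interfaces$kind,
               round(interfaces$angle / angleTol),
               round(interfaces$displacement / dispTol))
  reps <- interfaces[!duplicated(key), ]
  reps$multiplicity <- as.integer(table(key)[key[!duplicated(key)]])
  rownames(reps) <- NULL
  reps
}

#' Per-ring radial profile
#'
#' For every detected ring: the radial distance of the ring centroid
#' (unweighted centre of the members' non-hydrogen atoms) from the particle
#' centre, plus the NTD/CTD layer metrics computed along the ring's local
#' axis.
#'
#' @param x assembly \linkS4class{StructureModel}.
#' @param rings result of \code{\link{detectRings}}.
#' @param scheme a \linkS4class{DomainScheme}.
#' @return data.frame with one row per ring: ring_id, fold, radius,
#'   ntd_radius, ctd_radius, vertical_displacement.
#' @export
radialProfile <- function(x, rings, scheme = domainScheme()) {
  centre <- rings$centre
  rows <- lapply(rings$rings, function(r) {
    sub <- selectAtoms(x, chains = r$chains)
    lm <- layerMetrics(sub, scheme, centre = centre, axis = r$axis)
    data.frame(ring_id = r$id, fold = r$fold, radius = r$radius,
               ntd_radius = lm@ntdRadius, ctd_radius = lm@ctdRadius,
               vertical_displacement = lm@verticalDisplacement,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

## Atom choices for the hydrogen-bond proxies (heavy donor/acceptor atoms;
## deposited models may lack hydrogens, so no angular term is applied).
.fingerprintAtoms <- list(
  R143 = c("NH1", "NH2", "NE"), K182mc = "O", Q181sc = c("NE2", "OE1"),
  D171 = c("OD1", "OD2"), S79 = "OG", K229 = "NZ", D90 = c("OD1", "OD2"))

#' NTD-CTD conformational-state fingerprint
#'
#' Measures the four diagnostic donor-acceptor distances that distinguish the
#' pentamer from the hexamer conformation of a CA monomer: R143 to the
#' main-chain carbonyl of K182 (pentamer state), R143 to the Q181 side chain
#' (hexamer state), D171 to S79' and K229 to D90' of the neighbouring monomer.
#' With the 3.5 Angstrom heavy-atom hydrogen-bond proxy, the state is
#' pentamer-like when R143-K182(mc) <= 3.5 and K229-D90' <= 3.5; hexamer-like
#' when R143-Q181(sc) <= 3.5 and K229-D90' > 3.5; otherwise indeterminate.
#'
#' @param monomer single-chain \linkS4class{StructureModel}.
#' @param neighbour the adjacent monomer in the ring (provides S79'/D90').
#' @param scheme a \linkS4class{DomainScheme} (residue numbering).
#' @param hbondCutoff heavy-atom donor-acceptor cutoff (default 3.5).
#' @return list with the four distances (r143_k182, r143_q181, d171_s79,
#'   k229_d90) and \code{state}.
#' @export
conformationFingerprint <- function(monomer, neighbour,
                                    scheme = domainScheme(),
                                    hbondCutoff = 3.5) {
  atomPos <- function(m, res, names) {
    a <- m@atoms
    a <- a[a$res_seq == res & a$name %in% names, ]
    if (!nrow(a))
      capsAnalysisError(sprintf("residue %d lacks atom(s) %s", res,
                                paste(names, collapse = "/")))
    as.matrix(a[, c("x", "y", "z")])
  }
  pairDist <- function(A, B) {
    d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
    sqrt(max(0, min(d2)))
  }
  r143 <- atomPos(monomer, 143L, .fingerprintAtoms$R143)
  d <- list(
    r143_k182 = pairDist(r143, atomPos(monomer, 182L, .fingerprintAtoms$K182mc)),
    r143_q181 = pairDist(r143, atomPos(monomer, 181L, .fingerprintAtoms$Q181sc)),
    d171_s79 = pairDist(atomPos(monomer, 171L, .fingerprintAtoms$D171),
                        atomPos(neighbour, 79L, .fingerprintAtoms$S79)),
    k229_d90 = pairDist(atomPos(monomer, 229L, .fingerprintAtoms$K229),
                        atomPos(neighbour, 90L, .fingerprintAtoms$D90)))
  state <- if (d$r143_k182 <= hbondCutoff && d$k229_d90 <= hbondCutoff)
    "pentamer-like"
  else if (d$r143_q181 <= hbondCutoff && d$k229_d90 > hbondCutoff)
    "hexamer-like"
  else "indeterminate"
  c(d, list(state = state))
}

#' Fingerprint all monomers of an assembly
#'
#' Applies \code{\link{conformationFingerprint}} to every chain.  Each chain
#' has two ring neighbours; the interacting one (whose S79'/D90' face the
#' chain's CTD) is identified as the neighbour giving the smaller D171-S79'
#' distance, so the result does not depend on the traversal direction of the
#' detected ring.
#'
#' @param x assembly \linkS4class{StructureModel}.
#' @param rings result of \code{\link{detectRings}}.
#' @param scheme a \linkS4class{DomainScheme}.
#' @return data.frame with one row per chain: chain, ring_id, neighbour, the
#'   four distances and the assigned state.
#' @export
fingerprintAssembly <- function(x, rings, scheme = domainScheme()) {
  rows <- list()
  for (r in rings$rings) {
    f <- length(r$chains)
    for (k in seq_along(r$chains)) {
      ch <- r$chains[k]
      mono <- selectAtoms(x, chains = ch)
      cand <- r$chains[c(if (k == f) 1L else k + 1L,
                         if (k == 1L) f else k - 1L)]
      fps <- lapply(cand, function(nb)
        conformationFingerprint(mono, selectAtoms(x, chains = nb), scheme))
      pick <- which.min(vapply(fps, `[[`, 0, "d171_s79"))
      fp <- fps[[pick]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, ring_id = r$id, neighbour = cand[pick],
        r143_k182 = fp$r143_k182, r143_q181 = fp$r143_q181,
        d171_s79 = fp$d171_s79, k229_d90 = fp$k229_d90, state = fp$state,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$ring_id, df$chain), ]
  rownames(df) <- NULL
  df
}
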