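## Pentamer/hexamer/monomer composition arithmetic for closed fullerene
## shells: Caspar-Klug icosahedra and D5/D6 capsules, with Euler validation.

#' Caspar-Klug icosahedral shell composition
#'
#' For lattice indices (h, k) the triangulation number is
#' \eqn{T = h^2 + hk + k^2}; the shell has 60T monomers arranged as 12
#' pentamers and 10(T - 1) hexamers under icosahedral symmetry.  (h, k) and
#' (k, h) are enantiomers with identical counts; a handedness flag is carried.
#'
#' @param h,k non-negative integers, not both zero.
#' @return a \linkS4class{ShellComposition}
#' @examples
#' casparKlug(1, 0)  # T=1: 60 monomers, 12 pentamers
#' casparKlug(1, 1)  # T=3: 180 monomers, 12 pentamers, 20 hexamers
#' @export
casparKlug <- function(h, k = 0L) {
  h <- as.integer(h); k <- as.integer(k)
  if (is.na(h) || is.na(k) || h < 0L || k < 0L || (h == 0L && k == 0L))
    capsParamError("need integers h >= 0, k >= 0 with h + k > 0")
  T <- h * h + h * k + k * k
  hand <- if (h == k || h == 0L || k == 0L) "achiral"
          else if (h > k) "dextro" else "laevo"
  new("ShellComposition",
      label = sprintf("T%d", T), T = as.numeric(T),
      pentamers = 12L, hexamers = 10L * (T - 1L), monomers = 60L * T,
      symmetry = "I", handedness = hand)
}

#' Capsule (dihedral) shell composition
#'
#' Dihedral capsules with pentameric or hexameric poles and \code{rings}
#' equatorial rings of hexamers.  A 5-fold pole gives 12 pentamers and
#' \code{5 * rings} hexamers under D5 symmetry; the single observed particle
#' has one ring (90 monomers).  A 6-fold pole gives 2 polar hexamers, 12
#' pentamers surrounding them, and \code{6 * rings} equatorial hexamers under
#' D6; the single observed particle again has one ring (108 monomers).  Ring
#' counts other than 1 are mathematical extrapolations of the observed
#' particles, not observed structures.  \code{pole = 5, rings = 0} degenerates
#' to the T=1 icosahedron and is labelled accordingly.
#'
#' @param pole 5 or 6.
#' @param rings number of equatorial hexamer rings, >= 0.
#' @return a \linkS4class{ShellComposition}
#' @examples
#' capsuleComposition(5, 1)  # 90 monomers: 12 pentamers + 5 hexamers
#' capsuleComposition(6, 1)  # 108 monomers: 12 pentamers + 8 hexamers
#' @export
capsuleComposition <- function(pole, rings = 1L) {
  pole <- as.integer(pole); rings <- as.integer(rings)
  if (is.na(pole) || !pole %in% c(5L, 6L))
    capsParamError("pole must be 5 or 6")
  if (is.na(rings) || rings < 0L)
    capsParamError("rings must be a non-negative integer")
  if (pole == 5L) {
    hex <- 5L * rings
    if (rings == 0L)
      return(new("ShellComposition", label = "T1", T = 1, pentamers = 12L,
                 hexamers = 0L, monomers = 60L, symmetry = "I"))
    new("ShellComposition", label = sprintf("D5-capsule-r%d", rings),
        T = NA_real_, pentamers = 12L, hexamers = hex,
        monomers = 60L + 30L * rings, symmetry = "D5")
  } else {
    hex <- 2L + 6L * rings
    new("ShellComposition", label = sprintf("D6-capsule-r%d", rings),
        T = NA_real_, pentamers = 12L, hexamers = hex,
        monomers = 60L + 6L * hex, symmetry = "D6")
  }
}

#' Euler validation of a pentamer/hexamer shell
#'
#' Models the shell as a trivalent polyhedron whose faces are the P pentagons
#' and H hexagons: \eqn{F = P + H}, \eqn{E = (5P + 6H)/2},
#' \eqn{V = (5P + 6H)/3}.  The shell is a valid closed fullerene polyhedron
#' iff E and V are integers and Euler's formula \eqn{V - E + F = 2} holds,
#' which forces P = 12 exactly.
#'
#' @param pentamers,hexamers non-negative integer counts, or a
#'   \linkS4class{ShellComposition} as the first argument.
#' @return a list with elements \code{valid}, \code{V}, \code{E}, \code{F},
#'   \code{pentamers}, \code{hexamers} and \code{reason} ("" when valid).
#' @examples
#' validateShell(12, 0)   # dodecahedron: V=20, E=30, F=12
#' validateShell(11, 5)   # invalid: pentagon count must be 12
#' @export
validateShell <- function(pentamers, hexamers = NULL) {
  if (is(pentamers, "ShellComposition")) {
    hexamers <- pentamers@hexamers
    pentamers <- pentamers@pentamers
  }
  P <- as.numeric(pentamers); H <- as.numeric(hexamers)
  if (is.na(P) || is.na(H) || P < 0 || H < 0 || P != round(P) || H != round(H))
    capsParamError("counts must be non-negative integers")
  s <- 5 * P + 6 * H
  E <- s / 2; V <- s / 3; F <- P + H
  reasons <- character()
  if (E != round(E)) reasons <- c(reasons, "edge count not integral")
  if (V != round(V)) reasons <- c(reasons, "vertex count not integral")
  if (E == round(E) && V == round(V) && V - E + F != 2)
    reasons <- c(reasons, sprintf("Euler characteristic %g != 2", V - E + F))
  list(valid = length(reasons) == 0L, V = V, E = E, F = F,
       pentamers = as.integer(P), hexamers = as.integer(H),
       reason = paste(reasons, collapse = "; "))
}
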