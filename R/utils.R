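## Internal helpers shared across modules: classed conditions, small linear
## algebra, atomic masses, chain-identifier sequences.

#' @import methods
#' @importFrom stats rnorm prcomp
#' @importFrom utils write.csv
NULL

## Classed errors so that callers (and the command-line wrapper) can map
## failure modes to exit codes without string matching.
capsAbort <- function(msg, class) {
  stop(structure(
    class = c(class, "capsgeomError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

capsIOError       <- function(msg) capsAbort(msg, "capsgeomIOError")
capsParseError    <- function(msg) capsAbort(msg, "capsgeomParseError")
capsParamError    <- function(msg) capsAbort(msg, "capsgeomParamError")
capsGeometryError <- function(msg) capsAbort(msg, "capsgeomGeometryError")
capsAnalysisError <- function(msg) capsAbort(msg, "capsgeomAnalysisError")

vecNorm <- function(v) sqrt(sum(v * v))

unitVector <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) capsGeometryError("cannot normalise a zero-length vector")
  v / n
}

## Proper rotation by `angle` radians about unit `axis` (Rodrigues).
axisAngleMatrix <- function(axis, angle) {
  u <- unitVector(axis)
  c <- cos(angle); s <- sin(angle)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * c + s * K + (1 - c) * tcrossprod(u)
}

## Angle (degrees) and unit axis of a proper rotation matrix.  Angle from the
## trace; axis from the antisymmetric part, falling back to the +1 eigenvector
## near 180 degrees where the antisymmetric part vanishes.  Ties at 180 are
## resolved by making the largest-magnitude axis component positive.
rotationAngleAxis <- function(R) {
  tr <- sum(diag(R))
  cosA <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cosA)
  if (angle < 1e-9) {
    return(list(angle = 0, axis = c(0, 0, 1)))
  }
  if (angle < pi - 1e-6) {
    ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
    ax <- ax / (2 * sin(angle))
  } else {
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, i])
    ax <- ax / vecNorm(ax)
  }
  k <- which.max(abs(ax))
  if (ax[k] < 0) ax <- -ax
  list(angle = angle * 180 / pi, axis = ax)
}

## Any orthonormal pair perpendicular to unit vector u.
perpFrame <- function(u) {
  u <- unitVector(u)
  ref <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitVector(pracmaCross(ref, u))
  e2 <- pracmaCross(u, e1)
  list(e1 = e1, e2 = e2)
}

pracmaCross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Standard atomic weights for the mass-weighted centre-of-mass computations.
## Unknown elements fall back to carbon with a warning (logged once per call).
.atomicMasses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990,
  K = 39.098, CL = 35.45, CA = 40.078
)

elementMasses <- function(elements) {
  key <- toupper(trimws(elements))
  m <- .atomicMasses[key]
  bad <- is.na(m)
  if (any(bad)) {
    warning(sprintf("unknown element(s) %s: using carbon mass",
                    paste(unique(key[bad]), collapse = ", ")))
    m[bad] <- .atomicMasses[["C"]]
  }
  unname(m)
}

## Deterministic chain-identifier sequence: the 62 single-character PDB ids
## first, then two-character ids (mmCIF territory).
.chainAlphabet <- c(LETTERS, letters, as.character(0:9))

chainIdSequence <- function(n) {
  if (n <= 62L) return(.chainAlphabet[seq_len(n)])
  ids <- .chainAlphabet
  for (a in .chainAlphabet) {
    ids <- c(ids, paste0(a, .chainAlphabet))
    if (length(ids) >= n) break
  }
  ids[seq_len(n)]
}

## Guess an element symbol from a PDB atom name.
elementFromName <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1L, 2L))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL"), two,
         toupper(substr(nm, 1L, 1L)))
}

## Run `expr` with a locally seeded RNG, restoring the caller's state.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
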