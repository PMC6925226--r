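## Finite rotation point groups (Cn, Dn, I), assembly expansion and symmetry
## axes.  All operators are pure rotations about the origin: the particle
## centre must be translated to the origin before expansion.

.GRP_TOL <- 1e-9

#' Construct a finite rotation point group
#'
#' Supported groups: cyclic \code{Cn} (n rotations about +z), dihedral
#' \code{Dn} (the n-fold along +z plus n two-folds in the xy-plane, one along
#' +x: the standard crystallographic setting) and icosahedral \code{I} in the
#' "I2" setting with two-fold axes along x, y and z (the convention used by
#' icosahedral reconstruction software).  The icosahedral group is produced by
#' closure over a documented generator pair (a two-fold about z and a
#' five-fold about the vertex direction (0, 1, phi)).
#'
#' @param name "C<n>" or "D<n>" with n >= 2, or "I".
#' @return a \linkS4class{PointGroup}
#' @export
makePointGroup <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    capsParamError("group name must be a single string")
  if (name == "I") return(icosahedralGroup())
  m <- regmatches(name, regexec("^([CD])([0-9]+)$", name))[[1L]]
  if (length(m) != 3L)
    capsParamError(sprintf("unknown point group '%s' (use Cn, Dn or I)", name))
  n <- as.integer(m[3L])
  if (n < 2L)
    capsParamError("cyclic/dihedral groups require n >= 2")
  z <- c(0, 0, 1)
  ops <- lapply(seq_len(n) - 1L, function(k) axisAngleMatrix(z, 2 * pi * k / n))
  labels <- sprintf("C%d^%d", n, seq_len(n) - 1L)
  axes <- data.frame(x = 0, y = 0, z = 1, fold = n)
  if (m[2L] == "D") {
    two <- lapply(seq_len(n) - 1L, function(k) {
      ax <- c(cos(pi * k / n), sin(pi * k / n), 0)
      axisAngleMatrix(ax, pi)
    })
    ops <- c(ops, two)
    labels <- c(labels, sprintf("C2'_%d", seq_len(n) - 1L))
    axes <- rbind(axes, data.frame(
      x = cos(pi * (seq_len(n) - 1L) / n),
      y = sin(pi * (seq_len(n) - 1L) / n), z = 0, fold = 2))
  }
  grp <- new("PointGroup", name = name, operators = ops, labels = labels,
             axes = axes)
  validObject(grp)
  grp
}

## Icosahedral group, I2 setting: generated by closure from a 2-fold about z
## and a 5-fold about the icosahedron vertex direction (0, 1, phi)/|.|.
icosahedralGroup <- function() {
  phi <- (1 + sqrt(5)) / 2
  gen <- list(
    axisAngleMatrix(c(0, 0, 1), pi),
    axisAngleMatrix(c(0, 1, phi), 2 * pi / 5)
  )
  ops <- closeGroup(gen)
  if (length(ops) != 60L)
    capsGeometryError(sprintf("icosahedral closure produced %d operators",
                              length(ops)))
  ## Deterministic order: identity first, then by rotation angle and axis.
  keyOf <- function(R) {
    aa <- rotationAngleAxis(R)
    sprintf("%08.4f|%+.6f|%+.6f|%+.6f", aa$angle, aa$axis[1L], aa$axis[2L],
            aa$axis[3L])
  }
  ops <- ops[order(vapply(ops, keyOf, ""))]
  grp <- new("PointGroup", name = "I", operators = ops,
             labels = sprintf("g%02d", seq_along(ops)),
             axes = axesFromOperators(ops))
  validObject(grp)
  grp
}

## Multiply generators until no new element appears (tolerance 1e-9).
closeGroup <- function(gens) {
  ops <- list(diag(3L))
  sig <- function(R) {
    x <- round(R, 7L)
    x[x == 0] <- 0  # normalise -0
    paste(sprintf("%.7f", x), collapse = ",")
  }
  seen <- new.env(hash = TRUE)
  assign(sig(diag(3L)), TRUE, envir = seen)
  queue <- gens
  while (length(queue)) {
    R <- queue[[1L]]; queue <- queue[-1L]
    s <- sig(R)
    if (exists(s, envir = seen)) next
    assign(s, TRUE, envir = seen)
    ops <- c(ops, list(R))
    for (g in c(gens, list(R)))
      for (P in list(R %*% g, g %*% R))
        if (!exists(sig(P), envir = seen)) queue <- c(queue, list(P))
    if (length(ops) > 200L) capsGeometryError("group closure did not converge")
  }
  ops
}

## Axes with folds from the non-identity operators: operators sharing an axis
## (antipodal directions merged) form a cyclic subgroup of order fold.
axesFromOperators <- function(ops) {
  keys <- character(); axes <- list(); counts <- integer()
  for (R in ops) {
    aa <- rotationAngleAxis(R)
    if (aa$angle < 1e-6) next
    ax <- round(aa$axis, 6L)
    ax[ax == 0] <- 0  # normalise -0
    ## antipodal dedup: first nonzero component positive (tie-stable)
    nz <- which(ax != 0)[1L]
    if (ax[nz] < 0) ax <- -ax
    key <- sprintf("%+.6f,%+.6f,%+.6f", ax[1L], ax[2L], ax[3L])
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key); axes <- c(axes, list(aa$axis))
      counts <- c(counts, 1L)
    } else counts[i] <- counts[i] + 1L
  }
  df <- data.frame(
    x = vapply(axes, `[`, 0, 1L), y = vapply(axes, `[`, 0, 2L),
    z = vapply(axes, `[`, 0, 3L), fold = counts + 1L)
  df <- df[order(-df$fold, round(df$x, 6L), round(df$y, 6L),
                 round(df$z, 6L)), ]
  rownames(df) <- NULL
  df
}

#' Symmetry axes of a point group
#'
#' @param group a \linkS4class{PointGroup}.
#' @return data.frame with unit-axis columns x, y, z and integer fold; for I
#'   there are 6 five-folds, 10 three-folds and 15 two-folds.
#' @export
symmetryAxes <- function(group) {
  if (nrow(group@axes)) group@axes else axesFromOperators(group@operators)
}

#' Expand an asymmetric unit under a point group
#'
#' Applies every operator to the input coordinates.  The output contains
#' order-of-group copies of the input; copy k keeps the input's residue
#' numbering and gets fresh chain ids drawn from a deterministic sequence
#' (single characters first, then two-character ids).  The identity copy
#' preserves the input coordinates bitwise.
#'
#' The caller is responsible for centring the particle at the origin (the
#' operators are pure rotations); see \code{\link{particleCentre}}.
#'
#' @param asu a \linkS4class{StructureModel} (the asymmetric unit).
#' @param group a \linkS4class{PointGroup}.
#' @return a \linkS4class{StructureModel} with \code{nAtoms(asu) *
#'   groupOrder(group)} atoms; the operator label of each copy is recorded in
#'   the "sym_op" attribute of the atom table.
#' @export
expandAssembly <- function(asu, group) {
  if (nAtoms(asu) == 0L) capsParamError("empty asymmetric unit")
  a <- asu@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  asuChains <- unique(a$chain_id)
  nops <- length(group@operators)
  ids <- chainIdSequence(length(asuChains) * nops)
  copies <- vector("list", nops)
  for (k in seq_len(nops)) {
    ak <- a
    if (k > 1L || max(abs(group@operators[[k]] - diag(3L))) > 0) {
      p <- xyz %*% t(group@operators[[k]])
      ak$x <- p[, 1L]; ak$y <- p[, 2L]; ak$z <- p[, 3L]
    }
    newIds <- ids[(k - 1L) * length(asuChains) + seq_along(asuChains)]
    ak$chain_id <- newIds[match(ak$chain_id, asuChains)]
    ak$sym_op <- group@labels[k]
    copies[[k]] <- ak
  }
  out <- do.call(rbind, copies)
  symOp <- out$sym_op
  out$sym_op <- NULL
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  res <- new("StructureModel", atoms = out, title = asu@title,
             format = "memory")
  attr(res@atoms, "sym_op") <- symOp
  res
}

#' Export operators as plain-text 4x4 matrices
#'
#' Writes the group's operators in the RELION/Chimera-style format: for each
#' operator a label line followed by four rows of a homogeneous 4x4 matrix
#' (rotation block plus zero translation).
#'
#' @param group a \linkS4class{PointGroup}.
#' @param path output file.
#' @return invisibly, \code{path}
#' @export
writeOperators <- function(group, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(group@operators)) {
    R <- group@operators[[k]]
    writeLines(sprintf("# operator %d %s", k, group@labels[k]), con)
    for (i in 1:3)
      writeLines(sprintf("%15.9f %15.9f %15.9f %15.9f",
                         R[i, 1L], R[i, 2L], R[i, 3L], 0), con)
    writeLines(sprintf("%15.9f %15.9f %15.9f %15.9f", 0, 0, 0, 1), con)
  }
  invisible(path)
}
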