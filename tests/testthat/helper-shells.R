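# Shared fixtures.  Shells are deterministic for a given recipe+seed and
# moderately expensive to build, so they are cached across test files.

.shellCache <- new.env(parent = emptyenv())

cachedShell <- function(class, sigma = 0, seed = 7L) {
  key <- paste(class, sigma, seed, sep = "|")
  if (is.null(.shellCache[[key]]))
    .shellCache[[key]] <- makeShell(shellRecipe(class, noiseSigma = sigma,
                                                seed = seed))
  .shellCache[[key]]
}

cachedAnalysis <- function(class, sigma = 0, seed = 7L, ...) {
  key <- paste("an", class, sigma, seed, sep = "|")
  if (is.null(.shellCache[[key]])) {
    s <- cachedShell(class, sigma, seed)
    axis <- if (class %in% c("D5", "D6")) c(0, 0, 1) else NULL
    .shellCache[[key]] <- analyzeShell(s$model, principalAxis = axis, ...)
  }
  .shellCache[[key]]
}

# Deterministic "random" proper rotation.
randomRotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  capsgeom:::axisAngleMatrix(ax / sqrt(sum(ax^2)), runif(1, 0, 2 * pi))
}

# Unordered chain-pair keys for comparing interface tables to manifests.
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Apply a rigid motion to a StructureModel.
rigidMove <- function(m, R, t = c(0, 0, 0)) {
  capsgeom:::transformStructure(m, R, t)
}

expect_ifaces_match_manifest <- function(an, manifest, angleTol, dispTol) {
  det <- pairKey(an$interfaces$chain_a, an$interfaces$chain_b)
  tru <- pairKey(manifest$interfaces$chain_a, manifest$interfaces$chain_b)
  expect_setequal(det, tru)
  m <- match(det, tru)
  expect_identical(an$interfaces$kind, manifest$interfaces$kind[m])
  expect_lt(max(abs(an$interfaces$angle - manifest$interfaces$angle[m])),
            angleTol)
  expect_lt(max(abs(an$interfaces$displacement -
                      manifest$interfaces$displacement[m])), dispTol)
  invisible(m)
}
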