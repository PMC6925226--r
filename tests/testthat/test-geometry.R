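# Helix vectors, crossing angles, displacements, superposition, domain
# motion and layer metrics.

test_that("helix vectors agree with a principal-axis fit and transform
           rigidly", {
  h <- makeIdealHelix(12)
  hv <- helixVector(h, c(1, 12))
  angTo <- function(v, u) acos(min(1, abs(sum(v * u)))) * 180 / pi
  expect_lt(angTo(hv@direction, c(0, 0, 1)), 0.5)
  # independent oracle: least-squares axis = first principal component
  pc <- prcomp(coords(h))$rotation[, 1]
  expect_lt(angTo(hv@direction, pc), 2)
  # equivariance: after a rigid motion the direction is R %*% old
  R <- randomRotation(11)
  h2 <- rigidMove(h, R, c(3, -7, 2))
  hv2 <- helixVector(h2, c(1, 12))
  expect_lt(max(abs(hv2@direction - as.vector(R %*% hv@direction))), 1e-6)
  # reversing residue order negates the direction
  a <- atomTable(h)
  a$res_seq <- 13L - a$res_seq
  hv3 <- helixVector(capsgeom:::newStructureModel(a), c(1, 12))
  expect_lt(max(abs(hv3@direction + hv@direction)), 1e-6)
  # short or incomplete helices are refused with informative errors
  expect_error(helixVector(h, c(1, 3)), "need >= 4")
  broken <- capsgeom:::newStructureModel(
    atomTable(h)[atomTable(h)$name != "N" | atomTable(h)$res_seq != 5, ])
  expect_error(helixVector(broken, c(1, 12)), "residue")
})

test_that("crossing angles and displacements match their constructions and
           are rigid-motion invariant", {
  iv <- markerInterval(domainScheme())
  same <- makeTwoHelixFixture(0, 0)
  a <- helixVector(same, iv, "A"); b <- helixVector(same, iv, "B")
  expect_equal(crossingAngle(a, b), 0, tolerance = 1e-9)
  expect_equal(centroidDisplacement(a, b), 0, tolerance = 1e-12)
  opp <- makeTwoHelixFixture(180, 5)
  expect_equal(crossingAngle(helixVector(opp, iv, "A"),
                             helixVector(opp, iv, "B")), 180,
               tolerance = 1e-6)
  # rotating one helix 65 degrees about the mutual perpendicular (oracle:
  # rotation-matrix construction)
  h1 <- makeIdealHelix(18, axis = c(1, 0, 0), resStart = iv[1])
  R65 <- capsgeom:::axisAngleMatrix(c(0, 0, 1), 65 * pi / 180)
  h2 <- rigidMove(h1, R65)
  h2@atoms$chain_id <- "B"
  both <- capsgeom:::newStructureModel(rbind(atomTable(h1), atomTable(h2)))
  expect_equal(crossingAngle(helixVector(both, iv, "A"),
                             helixVector(both, iv, "B")), 65,
               tolerance = 1e-6)
  # 3-4-5 displacement
  h3 <- rigidMove(h1, diag(3), c(3, 4, 0))
  h3@atoms$chain_id <- "B"
  both2 <- capsgeom:::newStructureModel(rbind(atomTable(h1), atomTable(h3)))
  expect_equal(centroidDisplacement(helixVector(both2, iv, "A"),
                                    helixVector(both2, iv, "B")), 5,
               tolerance = 1e-9)
  # fixtures at the three reference geometries recover exactly; both
  # quantities invariant under a common rigid motion and symmetric in order
  for (geo in list(c(20, 11), c(65, 12), c(95, 14))) {
    f <- makeTwoHelixFixture(geo[1], geo[2])
    va <- helixVector(f, iv, "A"); vb <- helixVector(f, iv, "B")
    expect_equal(crossingAngle(va, vb), geo[1], tolerance = 1e-6)
    expect_equal(centroidDisplacement(va, vb), geo[2], tolerance = 1e-6)
    expect_equal(crossingAngle(vb, va), crossingAngle(va, vb))
    g <- rigidMove(f, randomRotation(31), c(-4, 9, 1))
    expect_equal(crossingAngle(helixVector(g, iv, "A"),
                               helixVector(g, iv, "B")), geo[1],
                 tolerance = 1e-6)
    expect_equal(centroidDisplacement(helixVector(g, iv, "A"),
                                      helixVector(g, iv, "B")), geo[2],
                 tolerance = 1e-6)
  }
})

test_that("superposition recovers constructed transforms and expected noise
           residuals", {
  set.seed(42)
  fixed <- matrix(rnorm(60), 20, 3)
  expect_equal(superpose(fixed, fixed)@rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(fixed, fixed)@angle, 0, tolerance = 1e-9)
  R <- capsgeom:::axisAngleMatrix(c(1, 2, 2) / 3, 37 * pi / 180)
  moving <- fixed %*% t(R) + matrix(c(1, -2, 3), 20, 3, byrow = TRUE)
  sup <- superpose(fixed, moving)
  expect_equal(sup@angle, 37, tolerance = 1e-6)
  expect_lt(sup@rmsd, 1e-9)
  expect_equal(det(sup@rotation), 1, tolerance = 1e-9)
  # Monte-Carlo: expected residual sqrt(sigma^2 (3n-6)/n) within 10%
  n <- 500; sigma <- 0.3
  base <- matrix(rnorm(3 * n, sd = 10), n, 3)
  rmsds <- vapply(1:60, function(s) {
    set.seed(s)
    superpose(base, base + matrix(rnorm(3 * n, 0, sigma), n, 3))@rmsd
  }, 0)
  expect_equal(mean(rmsds), sigma * sqrt(3 - 6 / n), tolerance = 0.1)
  # global-optimality spot check: no random rigid transform beats the fit
  small <- matrix(rnorm(24), 8, 3)
  target <- small %*% t(randomRotation(5)) + 2
  best <- superpose(target, small)@rmsd
  trials <- vapply(1:100, function(s) {
    Rr <- randomRotation(1000 + s)
    moved <- small %*% t(Rr)
    moved <- moved + matrix(colMeans(target) - colMeans(moved), 8, 3,
                            byrow = TRUE)
    sqrt(mean(rowSums((moved - target)^2)))
  }, 0)
  expect_true(all(best <= trials + 1e-12))
  expect_error(superpose(fixed[1:2, ], fixed[1:2, ]),
               class = "capsgeomGeometryError")
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(superpose(line, line), "collinear")
})

test_that("relative domain motion isolates constructed CTD rotations and
           shifts", {
  ref <- makeToyMonomer("pentamer")
  expect_equal(unlist(relativeDomainMotion(ref, ref)[c("rotationAngle",
                                                       "ctdShift")]),
               c(rotationAngle = 0, ctdShift = 0), tolerance = 1e-9)
  sch <- domainScheme()
  a <- atomTable(ref)
  ctd <- a$res_seq >= sch@ctd[1]
  # 15-degree hinge rotation of the whole CTD about an axis through its centroid
  hinge <- capsgeom:::axisAngleMatrix(c(0, 1, 0), 15 * pi / 180)
  centre <- colMeans(as.matrix(a[ctd, c("x", "y", "z")]))
  rot <- as.matrix(a[ctd, c("x", "y", "z")])
  rot <- sweep(rot, 2, centre) %*% t(hinge) + matrix(centre, sum(ctd), 3,
                                                     byrow = TRUE)
  a2 <- a; a2[ctd, c("x", "y", "z")] <- rot
  other <- capsgeom:::newStructureModel(a2)
  expect_equal(relativeDomainMotion(ref, other)$rotationAngle, 15,
               tolerance = 0.1)
  # 3.6 Angstrom translation of the CTD
  a3 <- a; a3[ctd, c("x", "y", "z")] <- a3[ctd, c("x", "y", "z")] +
    matrix(c(3.6, 0, 0), sum(ctd), 3, byrow = TRUE)
  res <- relativeDomainMotion(ref, capsgeom:::newStructureModel(a3))
  expect_equal(res$ctdShift, 3.6, tolerance = 1e-6)
  expect_lt(res$rotationAngle, 1e-4)
})

test_that("layer metrics recover constructed radii and layer separation
           exactly", {
  for (fold in c(5L, 6L)) {
    ring <- makeRing(fold)
    lm <- layerMetrics(ring)
    expect_equal(lm@ntdRadius, 86.3, tolerance = 1e-6)
    expect_equal(lm@ctdRadius, 64.7, tolerance = 1e-6)
    expect_equal(lm@verticalDisplacement, 21.6, tolerance = 1e-6)
  }
  # translation covariance: moving the centre along the axis changes radii,
  # not the vertical displacement
  ring <- makeRing(5)
  d <- 12.5
  lm2 <- layerMetrics(ring, centre = c(0, 0, d))
  expect_equal(lm2@ntdRadius, 86.3 - d, tolerance = 1e-6)
  expect_equal(lm2@ctdRadius, 64.7 - d, tolerance = 1e-6)
  expect_equal(lm2@verticalDisplacement, 21.6, tolerance = 1e-6)
  expect_error(layerMetrics(makeTwoHelixFixture(65, 12),
                            scheme = domainScheme()),
               class = "capsgeomAnalysisError")
})
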