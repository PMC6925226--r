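# Whole-particle pipeline: centre, rings, interfaces, classification,
# radial profiles, fingerprints and reports.

test_that("particle centre is the heavy-atom centroid and tracks
           translations", {
  s <- cachedShell("T1")
  expect_lt(max(abs(particleCentre(s$model))), 1e-9)
  moved <- rigidMove(s$model, diag(3), c(10, 0, 0))
  expect_equal(particleCentre(moved), c(10, 0, 0), tolerance = 1e-9)
  mono <- makeToyMonomer("pentamer")
  expect_equal(particleCentre(mono), unname(colMeans(coords(mono))),
               tolerance = 1e-12)
})

test_that("ring detection recovers every shell census and refuses broken
           assemblies", {
  expected <- list(T1 = c(p = 12L, h = 0L), D5 = c(p = 12L, h = 5L),
                   D6 = c(p = 12L, h = 8L), T3 = c(p = 12L, h = 20L))
  for (cls in names(expected)) {
    an <- cachedAnalysis(cls)
    folds <- vapply(an$rings$rings, `[[`, 0L, "fold")
    expect_equal(sum(folds == 5L), expected[[cls]][["p"]], info = cls)
    expect_equal(sum(folds == 6L), expected[[cls]][["h"]], info = cls)
    # partition: every chain in exactly one ring
    allChains <- unlist(lapply(an$rings$rings, `[[`, "chains"))
    expect_equal(anyDuplicated(allChains), 0L)
    expect_setequal(allChains, chainIds(cachedShell(cls)$model))
    expect_equal(sum(folds), length(allChains))
  }
  # an absurd cutoff fragments the contact graph -> diagnostic error
  expect_error(detectRings(cachedShell("T1")$model, cutoff = 0.2),
               class = "capsgeomAnalysisError")
})

test_that("interface enumeration gives the closed-form counts and kinds", {
  counts <- list(T1 = 30L, D5 = 45L, D6 = 54L, T3 = 90L)
  kinds <- list(
    T1 = c("pentamer-pentamer" = 30L),
    D5 = c("hexamer-hexamer" = 5L, "pentamer-hexamer" = 20L,
           "pentamer-pentamer" = 20L),
    D6 = c("hexamer-hexamer" = 6L, "pentamer-hexamer" = 36L,
           "pentamer-pentamer" = 12L),
    T3 = c("hexamer-hexamer" = 30L, "pentamer-hexamer" = 60L))
  for (cls in names(counts)) {
    an <- cachedAnalysis(cls)
    expect_equal(nrow(an$interfaces), counts[[cls]], info = cls)
    tab <- table(an$interfaces$kind)
    expect_equal(as.integer(tab[names(kinds[[cls]])]),
                 unname(kinds[[cls]]), info = cls)
    # chains pair at most once and across different rings
    expect_true(all(an$interfaces$ring_a != an$interfaces$ring_b))
  }
})

test_that("group classification uses the documented fixed boundaries", {
  expect_equal(classifyInterface(20)$group, 1L)
  expect_equal(classifyInterface(65)$group, 2L)
  expect_equal(classifyInterface(95)$group, 3L)
  # boundary flips exactly at the midpoints 42.5 and 80
  expect_equal(classifyInterface(42.49)$group, 1L)
  expect_equal(classifyInterface(42.5)$group, 2L)
  expect_equal(classifyInterface(79.99)$group, 2L)
  expect_equal(classifyInterface(80)$group, 3L)
  # stability to +/- 5 degrees around each reference centre
  for (ref in c(20, 65, 95)) for (d in c(-5, 5))
    expect_equal(classifyInterface(ref + d)$group,
                 classifyInterface(ref)$group)
  expect_equal(classifyInterface(68)$refDistance, 3)
  g <- pairGeometry(helixVector(makeTwoHelixFixture(95, 14),
                                markerInterval(domainScheme()), "A"),
                    helixVector(makeTwoHelixFixture(95, 14),
                                markerInterval(domainScheme()), "B"))
  expect_equal(classifyInterface(g)$group, 3L)
  expect_error(classifyInterface(200), class = "capsgeomParamError")
})

test_that("radial profiles recover constructed ring radii and are invariant
           under rotation", {
  s <- cachedShell("T3")
  an <- cachedAnalysis("T3")
  prof <- an$profile
  expect_lt(max(abs(prof$radius[prof$fold == 5] - 143.9)), 1e-6)
  expect_lt(max(abs(prof$radius[prof$fold == 6] - 136.5)), 1e-6)
  an1 <- cachedAnalysis("T1")
  expect_lt(max(abs(an1$profile$radius - 75.5)), 1e-6)
  # global rotation leaves radii and interface geometry unchanged
  R <- randomRotation(99)
  rotated <- rigidMove(cachedShell("T1")$model, R, c(0, 0, 0))
  anR <- analyzeShell(rotated, fingerprints = FALSE)
  expect_equal(sort(anR$profile$radius), sort(an1$profile$radius),
               tolerance = 1e-6)
  expect_equal(sort(anR$interfaces$angle), sort(an1$interfaces$angle),
               tolerance = 1e-6)
  expect_equal(sort(anR$interfaces$displacement),
               sort(an1$interfaces$displacement), tolerance = 1e-6)
})

test_that("conformation fingerprints distinguish pentamer, hexamer and
           indeterminate placements", {
  ringP <- makeRing(5, state = "pentamer")
  fp <- conformationFingerprint(selectAtoms(ringP, chains = "A"),
                                selectAtoms(ringP, chains = "B"))
  expect_equal(fp$state, "pentamer-like")
  expect_equal(fp$r143_k182, 2.9, tolerance = 1e-9)
  expect_equal(fp$k229_d90, 2.9, tolerance = 1e-9)
  ringH <- makeRing(6, state = "hexamer")
  fpH <- conformationFingerprint(selectAtoms(ringH, chains = "A"),
                                 selectAtoms(ringH, chains = "B"))
  expect_equal(fpH$state, "hexamer-like")
  expect_equal(fpH$r143_q181, 2.9, tolerance = 1e-9)
  expect_gt(fpH$k229_d90, 3.5)
  ringI <- makeRing(5, state = "indeterminate")
  fpI <- conformationFingerprint(selectAtoms(ringI, chains = "A"),
                                 selectAtoms(ringI, chains = "B"))
  expect_equal(fpI$state, "indeterminate")
  expect_true(all(unlist(fpI[1:4]) > 5))
  # missing diagnostic atoms are named
  noNz <- selectAtoms(ringP, chains = "A")
  noNz@atoms <- noNz@atoms[noNz@atoms$name != "NZ", ]
  expect_error(conformationFingerprint(noNz,
                                       selectAtoms(ringP, chains = "B")),
               "229")
  # whole-assembly fingerprints follow ring fold in a shell
  anD6 <- cachedAnalysis("D6")
  fps <- anD6$fingerprints
  ringFold <- vapply(anD6$rings$rings, `[[`, 0L, "fold")
  names(ringFold) <- vapply(anD6$rings$rings, `[[`, "", "id")
  expect_true(all(fps$state[ringFold[fps$ring_id] == 5] == "pentamer-like"))
  expect_true(all(fps$state[ringFold[fps$ring_id] == 6] == "hexamer-like"))
})

test_that("reports are deterministic, sorted and complete", {
  an <- cachedAnalysis("T1")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeReports(an, d1)
  writeReports(an, d2)
  for (f in c("interfaces.csv", "rings.csv", "layers.csv",
              "fingerprints.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  iface <- read.csv(file.path(d1, "interfaces.csv"))
  expect_equal(nrow(iface), 30L)
  expect_false(is.unsorted(iface$ring_a))
  summ <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(summ$n_rings, 12L)
  expect_equal(summ$n_interfaces, 30L)
  expect_equal(summ$params$ringCutoff, 6)
  # empty interface table -> header-only CSV
  empty <- an
  empty$interfaces <- capsgeom:::emptyInterfaceTable()
  d3 <- withr::local_tempdir()
  writeReports(empty, d3)
  expect_length(readLines(file.path(d3, "interfaces.csv")), 1L)
  # unique mode collapses symmetric copies
  uniq <- uniqueInterfaces(an$interfaces)
  expect_equal(nrow(uniq), 1L)
  expect_equal(uniq$multiplicity, 30L)
})
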