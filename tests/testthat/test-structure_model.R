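# Reading, selecting and writing atomic models.

onePdbLine <- paste0(
  "ATOM      1  CA  ALA A   1      11.104  -2.500   3.751  1.00 20.00",
  "           C")

test_that("a one-atom PDB parses field for field", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(onePdbLine, "END"), tf)
  m <- readStructure(tf)
  a <- atomTable(m)
  expect_equal(nAtoms(m), 1L)
  expect_equal(a$name, "CA")
  expect_equal(a$res_name, "ALA")
  expect_equal(a$chain_id, "A")
  expect_equal(a$res_seq, 1L)
  expect_equal(unname(coords(m)[1, ]), c(11.104, -2.500, 3.751))
  expect_equal(a$occupancy, 1)
  expect_equal(a$b_iso, 20)
  expect_equal(a$element, "C")
})

test_that("multi-model files keep all models with equal atom counts", {
  h <- makeIdealHelix(8)
  a <- atomTable(h)
  models <- do.call(rbind, lapply(1:20, function(k) {
    ak <- a; ak$model_num <- k
    ak$x <- ak$x + k  # distinct coordinates per model
    ak
  }))
  m <- capsgeom:::newStructureModel(models)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, tf)
  m2 <- readStructure(tf)
  expect_length(modelNums(m2), 20L)
  counts <- table(atomTable(m2)$model_num)
  expect_true(all(counts == nAtoms(h)))
  # selecting one model returns one model's atoms
  one <- selectAtoms(m2, model = 1L)
  expect_equal(nAtoms(one), nAtoms(h))
})

test_that("write/read round-trips preserve order and coordinates to 1e-3", {
  shells <- list(pdb = cachedShell("T1"), cif = cachedShell("T3"))
  for (fmt in names(shells)) {
    m <- shells[[fmt]]$model
    tf <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeStructure(m, tf, fmt)
    m2 <- readStructure(tf)
    expect_equal(nAtoms(m2), nAtoms(m))
    expect_identical(atomTable(m2)$chain_id, atomTable(m)$chain_id)
    expect_identical(atomTable(m2)$name, atomTable(m)$name)
    expect_lt(max(abs(coords(m2) - coords(m))), 1e-3 + 1e-9)
  }
  expect_length(chainIds(readStructure({
    tf <- withr::local_tempfile(fileext = ".pdb")
    writeStructure(shells$pdb$model, tf); tf
  })), 60L)
})

test_that("selection filters compose, are idempotent, and refuse emptiness", {
  mono <- makeToyMonomer("pentamer")
  sch <- domainScheme()
  ntd <- selectAtoms(mono, residues = sch@ntd)
  expect_true(all(atomTable(ntd)$res_seq <= 153))
  # NTD/CTD partition residues 1-246 with no overlap
  expect_equal(sch@ntd[2L] + 1L, sch@ctd[1L])
  expect_equal(nAtoms(selectAtoms(mono, residues = sch@ntd)) +
                 nAtoms(selectAtoms(mono, residues = sch@ctd)),
               nAtoms(mono))
  bb <- selectAtoms(mono, atoms = c("N", "CA", "C"))
  twice <- selectAtoms(bb, atoms = c("N", "CA", "C"))
  expect_identical(atomTable(twice), atomTable(bb))
  expect_error(selectAtoms(mono, chains = "ZZ"), class = "capsgeomError")
  expect_equal(nAtoms(selectAtoms(mono, chains = "ZZ", allowEmpty = TRUE)), 0L)
})

test_that("alternate conformers resolve to the highest-occupancy atom", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  m <- readStructure(tf)
  expect_equal(nAtoms(m), 1L)
  expect_equal(atomTable(m)$alt_loc, "B")
  expect_equal(unname(coords(m)[1, "x"]), 5)
})

test_that("strict PDB refuses multi-character chains, advising mmCIF", {
  s <- cachedShell("T3")  # 180 chains -> two-character ids present
  tf <- withr::local_tempfile(fileext = ".pdb")
  expect_error(writeStructure(s$model, tf, "pdb"), "mmCIF")
  expect_error(readStructure(withr::local_tempfile(fileext = ".pdb")),
               class = "capsgeomIOError")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty), class = "capsgeomParseError")
})

test_that("domain schemes enforce their interval invariants", {
  expect_error(domainScheme(ntd = c(1, 160), ctd = c(154, 246)), "overlap")
  expect_error(domainScheme(helices = list(a8 = c(150, 160))), "one domain")
  expect_silent(domainScheme(helices = list(a8 = c(200, 210))))
})
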