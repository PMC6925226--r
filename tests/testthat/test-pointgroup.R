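# Finite rotation groups, assembly expansion and symmetry axes.

opKey <- function(R) {
  x <- round(R, 7)
  x[x == 0] <- 0
  paste(sprintf("%.7f", x), collapse = ",")
}

test_that("group orders and axioms hold for Cn, Dn and I", {
  cases <- list(C5 = 5L, C6 = 6L, D5 = 10L, D6 = 12L, I = 60L)
  for (nm in names(cases)) {
    g <- makePointGroup(nm)
    ops <- groupOperators(g)
    expect_equal(groupOrder(g), cases[[nm]], info = nm)
    keys <- vapply(ops, opKey, "")
    expect_equal(anyDuplicated(keys), 0L, info = nm)
    # closure: every pairwise product is a member (1e-9 via rounded keys)
    prods <- unlist(lapply(ops, function(A)
      vapply(ops, function(B) opKey(A %*% B), "")))
    expect_true(all(prods %in% keys), info = nm)
    # inverses: transpose of each member is a member
    expect_true(all(vapply(ops, function(A) opKey(t(A)) %in% keys, TRUE)),
                info = nm)
  }
  expect_error(makePointGroup("C1"), class = "capsgeomParamError")
  expect_error(makePointGroup("X7"), class = "capsgeomParamError")
})

test_that("symmetry axes have the expected folds", {
  axI <- symmetryAxes(makePointGroup("I"))
  expect_equal(as.vector(table(axI$fold)[c("2", "3", "5")]), c(15L, 10L, 6L))
  expect_equal(nrow(axI), 31L)
  axD5 <- symmetryAxes(makePointGroup("D5"))
  expect_equal(sum(axD5$fold == 5), 1L)
  expect_equal(sum(axD5$fold == 2), 5L)
  axC6 <- symmetryAxes(makePointGroup("C6"))
  expect_equal(nrow(axC6), 1L)
  expect_equal(axC6$fold, 6L)
  # all axes unit length
  expect_lt(max(abs(sqrt(axI$x^2 + axI$y^2 + axI$z^2) - 1)), 1e-9)
})

test_that("expandAssembly multiplies atoms, preserves the identity copy and
           applies each operator rigidly", {
  mono <- makeToyMonomer("pentamer")
  for (nm in c("D5", "I")) {
    g <- makePointGroup(nm)
    ex <- expandAssembly(mono, g)
    expect_equal(nAtoms(ex), nAtoms(mono) * groupOrder(g))
    expect_length(chainIds(ex), groupOrder(g))
    # identity copy preserves input coordinates bitwise
    first <- selectAtoms(ex, chains = chainIds(ex)[1L])
    expect_identical(coords(first), coords(mono))
    # copy k equals the operator-transformed original (oracle: apply R)
    xyz <- coords(mono)
    for (k in c(2L, groupOrder(g))) {
      copyK <- coords(selectAtoms(ex, chains = chainIds(ex)[k]))
      expect_lt(max(abs(copyK - xyz %*% t(g@operators[[k]]))), 1e-9)
      # rigid motion: interatomic distances conserved
      i <- c(1L, 5L, 50L); j <- c(20L, 90L, 130L)
      expect_lt(max(abs(
        sqrt(rowSums((copyK[i, ] - copyK[j, ])^2)) -
          sqrt(rowSums((xyz[i, ] - xyz[j, ])^2)))), 1e-9)
    }
  }
})

test_that("rotation about a reported five-fold axis permutes chains and
           rings", {
  ax <- symmetryAxes(makePointGroup("I"))
  five <- as.numeric(ax[ax$fold == 5, ][1L, c("x", "y", "z")])
  R <- capsgeom:::axisAngleMatrix(five, 2 * pi / 5)
  permutes <- function(cents, tol) {
    rotated <- cents %*% t(R)
    d2 <- outer(rowSums(rotated^2), rowSums(cents^2), "+") -
      2 * tcrossprod(rotated, cents)
    perm <- apply(d2, 1, which.min)
    expect_lt(sqrt(max(0, max(apply(d2, 1, min)))), tol)
    expect_true(all(sort(perm) == seq_len(nrow(cents))))
  }
  # chain-level on an exactly point-group-expanded assembly
  ex <- expandAssembly(makeToyMonomer("pentamer"), makePointGroup("I"))
  a <- atomTable(ex)
  cents <- t(vapply(split(seq_len(nrow(a)), a$chain_id), function(i)
    c(mean(a$x[i]), mean(a$y[i]), mean(a$z[i])), numeric(3)))
  permutes(cents, 1e-5)
  # ring-level on the synthetic T=1 shell (ring centroids sit on the
  # icosahedral vertex directions)
  an <- cachedAnalysis("T1")
  ringCents <- t(vapply(an$rings$rings, `[[`, numeric(3), "centroid"))
  permutes(ringCents, 1e-5)
})

test_that("operators export as parseable 4x4 matrix text", {
  g <- makePointGroup("D6")
  tf <- withr::local_tempfile(fileext = ".txt")
  writeOperators(g, tf)
  lines <- readLines(tf)
  expect_equal(sum(grepl("^# operator", lines)), 12L)
  nums <- scan(text = lines[!grepl("^#", lines)], quiet = TRUE)
  expect_length(nums, 12L * 16L)
})
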