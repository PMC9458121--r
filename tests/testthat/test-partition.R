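## deterministic random fragment scheme over n atoms with k user labels
randomScheme <- function(n, k, seed) {
  set.seed(seed)
  labs <- as.character(seq_len(k) - 1L)
  pick <- sample(c(labs, "rest"), n, replace = TRUE)
  sel <- lapply(labs, function(l) which(pick == l) - 1L)
  names(sel) <- labs
  assignFragments(sel[lengths(sel) > 0], n)
}

test_that("the 30-atom example yields remainder X and three fragments", {
  sc <- assignFragments(list("0" = 1:10, "1" = 15:25), 30)
  expect_equal(fragmentLabels(sc), c("0", "1", "X"))
  mem <- fragmentMembers(sc)
  expect_equal(mem[["0"]], 1:10)
  expect_equal(mem[["1"]], 15:25)
  expect_equal(mem[["X"]], c(0L, 11:14, 26:29))
})

test_that("fragment assignment enforces disjointness, range and the reserved label", {
  expect_error(assignFragments(list(a = c(1, 5), b = c(5, 9)), 10), "atom 5")
  expect_error(assignFragments(list(a = c(1, 30)), 10), "out of range")
  expect_error(assignFragments(list(X = 1:3), 10), "reserved")
  ## full coverage drops the remainder
  sc <- assignFragments(list(a = 0:4, b = 5:9), 10)
  expect_equal(fragmentLabels(sc), c("a", "b"))
  ## empty user fragments are dropped
  sc2 <- assignFragments(list(a = 0:4, b = integer()), 10)
  expect_equal(fragmentLabels(sc2), c("a", "X"))
})

test_that("bucket keys are sorted label sets sized by span", {
  sc <- assignFragments(list("0" = 0:3, "1" = 4:7), 12)
  expect_equal(bucketFor(c(0, 1), sc), "0")
  expect_equal(bucketFor(c(3, 4), sc), "0+1")
  expect_equal(bucketFor(c(4, 3), sc), "0+1")        # orientation-free
  expect_equal(bucketFor(c(0, 5, 9), sc), "0+1+X")
  expect_equal(bucketFor(c(8, 9), sc), "X")
})

test_that("a single-fragment scheme reproduces the class totals exactly", {
  sys <- makeFixture("random", 30, seed = 6)
  sc <- assignFragments(list(), nAtoms(sys))   # everything in X
  rep <- partitionedEnergy(sys, sc)
  e <- totalEnergy(sys)
  for (cl in c("Bonds", "Angles", "Torsions", "VDW", "Coulomb")) {
    b <- bucketEnergies(rep, cl)
    expect_equal(names(b), "X")
    expect_equal(unname(b), unname(e[cl]), tolerance = 1e-12)
  }
  expect_equal(reportTotals(rep)[["Total"]], e[["Total"]], tolerance = 1e-12)
})

test_that("two isolated molecules partition into self-energies plus nonbonded pair", {
  sys <- makeFixture("two-molecule", 10, seed = 3)
  sc <- assignFragments(list(A = 0:4, B = 5:9), 10)
  rep <- partitionedEnergy(sys, sc)
  ## no bonded term can span the molecules
  for (cl in c("Bonds", "Angles", "Torsions", "Out-of-Plane"))
    expect_true(all(names(bucketEnergies(rep, cl)) %in% c("A", "B")))
  expect_true("A+B" %in% names(bucketEnergies(rep, "VDW")))
  expect_true("A+B" %in% names(bucketEnergies(rep, "Coulomb")))
  ## each molecule's self energies equal the totals of that molecule alone
  subA <- totalEnergy(subsetFixture(sys, 0:4))
  for (cl in c("Bonds", "Angles", "Torsions"))
    expect_equal(unname(bucketEnergies(rep, cl)[["A"]]), unname(subA[[cl]]),
                 tolerance = 1e-9)
})

test_that("energy is conserved across 1, 2, 3 and many fragments", {
  sys <- makeFixture("random", 60, seed = 10)
  eTot <- totalEnergy(sys)[["Total"]]
  schemes <- list(
    assignFragments(list(), 60),
    assignFragments(list(a = 0:29), 60),
    assignFragments(list(a = 0:19, b = 20:39), 60),
    randomScheme(60, 17, seed = 60))
  for (sc in schemes) {
    rep <- partitionedEnergy(sys, sc)
    allBuckets <- sum(vapply(c("Bonds", "Angles", "Torsions", "Out-of-Plane",
                               "VDW", "Coulomb"),
                             function(cl) sum(bucketEnergies(rep, cl)),
                             numeric(1)))
    expect_lt(abs(eTot - allBuckets), 1e-9)
  }
})

test_that("single-atom fragments on a chain force triple and quadruple buckets", {
  sys <- makeFixture("chain", 6, seed = 1)
  sel <- as.list(0:4); names(sel) <- paste0("f", 0:4)
  sc <- assignFragments(sel, 6)
  rep <- partitionedEnergy(sys, sc)
  ## the torsion 0-1-2-3 spans four single-atom fragments
  expect_true("f0+f1+f2+f3" %in% names(bucketEnergies(rep, "Torsions")))
  expect_true("f0+f1+f2" %in% names(bucketEnergies(rep, "Angles")))
  expect_lt(abs(reportTotals(rep)[["Total"]] - totalEnergy(sys)[["Total"]]),
            1e-9)
})

test_that("relabelling fragments permutes keys but changes no value", {
  sys <- makeFixture("random", 40, seed = 12)
  sel <- list(a = 0:9, b = 10:19, c = 20:29)
  sc1 <- assignFragments(sel, 40)
  sc2 <- assignFragments(list(p = 0:9, q = 10:19, r = 20:29), 40)
  map <- c(a = "p", b = "q", c = "r", X = "X")
  r1 <- partitionedEnergy(sys, sc1); r2 <- partitionedEnergy(sys, sc2)
  for (cl in c("Bonds", "Angles", "Torsions", "VDW", "Coulomb")) {
    e1 <- bucketEnergies(r1, cl); e2 <- bucketEnergies(r2, cl)
    renamed <- vapply(strsplit(names(e1), "+", fixed = TRUE),
                      function(p) paste(map[p], collapse = "+"), character(1))
    expect_equal(sort(renamed), sort(names(e2)))
    expect_equal(unname(e1[order(renamed)]), unname(e2[order(names(e2))]),
                 tolerance = 1e-12)
  }
})

test_that("merging two fragments adds their selves plus their interaction", {
  sys <- makeFixture("random", 45, seed = 13)
  fine <- assignFragments(list(a = 0:14, b = 15:29), 45)
  merged <- assignFragments(list(m = 0:29), 45)
  rf <- partitionedEnergy(sys, fine); rm <- partitionedEnergy(sys, merged)
  pick <- function(e, k) if (k %in% names(e)) e[[k]] else 0
  for (cl in c("Bonds", "Angles", "Torsions", "VDW", "Coulomb")) {
    ef <- bucketEnergies(rf, cl); em <- bucketEnergies(rm, cl)
    expect_equal(pick(em, "m"),
                 pick(ef, "a") + pick(ef, "b") + pick(ef, "a+b"),
                 tolerance = 1e-9)
    ## triple buckets re-route into the pair bucket with X
    expect_equal(pick(em, "m+X"), pick(ef, "a+X") + pick(ef, "b+X") +
                   pick(ef, "a+b+X"), tolerance = 1e-9)
  }
  expect_equal(reportTotals(rm)[["Total"]], reportTotals(rf)[["Total"]],
               tolerance = 1e-9)
})

test_that("delta reports subtract bucket-wise between conformations", {
  sys <- makeFixture("chain", 10, seed = 2)
  sel <- list("0" = 0:2, "1" = 3:6)
  sc <- assignFragments(sel, 10)
  r1 <- partitionedEnergy(sys, sc)
  expect_equal(deltaReport(r1, r1)$Total, 0)
  expect_true(all(vapply(deltaReport(r1, r1)[1:6],
                         function(v) all(abs(v) < 1e-12), logical(1))))
  ## perturbed conformation
  sys2 <- sys
  pos <- coordinates(sys); pos[8:10, ] <- pos[8:10, ] + 0.2
  coordinates(sys2) <- pos
  r2 <- partitionedEnergy(sys2, sc)
  d <- deltaReport(r1, r2)
  for (cl in c("VDW", "Coulomb")) {
    e1 <- bucketEnergies(r1, cl); e2 <- bucketEnergies(r2, cl)
    for (k in names(e2))
      expect_equal(d[[cl]][[k]], e2[[k]] - (if (k %in% names(e1)) e1[[k]] else 0),
                   tolerance = 1e-12)
  }
  expect_equal(d$Total, reportTotals(r2)[["Total"]] - reportTotals(r1)[["Total"]])
  ## mismatched labels are an error
  r3 <- partitionedEnergy(sys, assignFragments(list(z = 0:3), 10))
  expect_error(deltaReport(r1, r3), "labels differ")
})
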