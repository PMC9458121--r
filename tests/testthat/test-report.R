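test_that("fragment spec grammar parses labels, singletons and spans", {
  expect_equal(parseFragmentSpec("0=1-10;1=15-25"),
               list("0" = 1:10, "1" = 15:25))
  expect_equal(parseFragmentSpec("A=0"), list(A = 0L))
  expect_equal(parseFragmentSpec("A=3,1,1,5-7"), list(A = c(1L, 3L, 5:7)))
  expect_error(parseFragmentSpec("X=1-3"), "reserved")
  expect_error(parseFragmentSpec("A=9-4"), "reversed span")
  expect_error(parseFragmentSpec("A=1..3"), "malformed")
  expect_error(parseFragmentSpec("A"), "missing '='")
  expect_error(parseFragmentSpec("A=1;A=2"), "duplicate")
})

test_that("text report has the sectioned structure in order", {
  sys <- makeFixture("random", 30, seed = 5)
  sc <- assignFragments(list("0" = 0:9, "1" = 10:19), 30)
  rep <- partitionedEnergy(sys, sc)
  txt <- writeReport(rep, "text")
  expect_match(txt[1], "^Workers: ")
  secAt <- function(s) which(txt == s)
  sections <- c("Fragments", "Bonds", "Angles", "Torsions", "Out-of-Plane",
                "VDW", "Coulomb", "Total Energy")
  pos <- vapply(sections, secAt, integer(1))
  expect_true(all(diff(pos) > 0))
  ## every fragment listed with its atoms
  expect_true(any(grepl("^Fragment 0: 0-9$", txt)))
  expect_true(any(grepl("^Fragment X: 20-29$", txt)))
  ## bucket lines render joined fragment names with 6-decimal energies
  expect_true(any(grepl("^Fragment 0 \\+ Fragment 1: -?[0-9]+\\.[0-9]{6}$", txt)))
})

test_that("printed section lines re-sum to the printed totals", {
  sys <- makeFixture("random", 40, seed = 21)
  sc <- assignFragments(list(a = 0:11, b = 12:23), 40)
  rep <- partitionedEnergy(sys, sc)
  txt <- writeReport(rep, "text")
  for (cl in c("Bonds", "VDW", "Coulomb")) {
    i0 <- which(txt == cl)
    block <- txt[(i0 + 1):(which(grepl("^Subtotal:", txt) & seq_along(txt) > i0)[1])]
    vals <- as.numeric(sub("^.*: ", "", grep("^Fragment", block, value = TRUE)))
    sub <- as.numeric(sub("^Subtotal: ", "", block[length(block)]))
    expect_lt(abs(sum(vals) - sub), 1e-6 * max(1, length(vals)))
  }
})

test_that("reports are byte-identical across repeated runs", {
  sys <- makeFixture("random", 25, seed = 9)
  sc <- assignFragments(list(a = 0:7, b = 8:15), 25)
  t1 <- writeReport(partitionedEnergy(sys, sc), "text")
  t2 <- writeReport(partitionedEnergy(sys, sc), "text")
  expect_identical(t1, t2)
})

test_that("json and csv renderings carry the same numbers as the report", {
  sys <- makeFixture("random", 25, seed = 14)
  sc <- assignFragments(list(a = 0:9), 25)
  rep <- partitionedEnergy(sys, sc)
  js <- jsonlite::fromJSON(writeReport(rep, "json"))
  expect_equal(js$totals$Total, reportTotals(rep)[["Total"]], tolerance = 1e-12)
  expect_equal(js$energies$VDW[["a+X"]], bucketEnergies(rep, "VDW")[["a+X"]],
               tolerance = 1e-12)
  csv <- writeReport(rep, "csv")
  tab <- utils::read.csv(textConnection(csv), stringsAsFactors = FALSE)
  vdw <- tab[tab$class == "VDW" & tab$bucket == "a+X", "energy_kcal_mol"]
  expect_equal(vdw, bucketEnergies(rep, "VDW")[["a+X"]], tolerance = 1e-12)
  expect_equal(tab[tab$class == "Total Energy", "energy_kcal_mol"],
               reportTotals(rep)[["Total"]], tolerance = 1e-12)
})

test_that("improper warnings surface in the Out-of-Plane section", {
  ## star centre with no matching improper record
  prm <- ParameterSet(
    vdw = data.frame(type = c("NX", "CT"), radius = c(1.8, 1.9),
                     eps = c(0.17, 0.11)),
    bonds = data.frame(t1 = "NX", t2 = "CT", kb = 300, l0 = 1.4),
    angles = data.frame(t1 = "CT", t2 = "NX", t3 = "CT", ka = 50,
                        theta0 = 120))
  pos <- rbind(c(0, 0, 0), diag(3) * 1.4)
  sys <- MolecularSystem(data.frame(type = c("NX", rep("CT", 3)), charge = 0,
                                    x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                         cbind(0, 1:3), prm)
  expect_length(calculationWarnings(sys), 1)
  rep <- partitionedEnergy(sys, assignFragments(list(), 4))
  txt <- writeReport(rep, "text")
  oop <- which(txt == "Out-of-Plane")
  expect_match(txt[oop + 1], "Warning:.*centre atom 0")
})

test_that("the run pipeline goes end to end from files and logs the residual", {
  d <- withr::local_tempdir()
  sys <- makeFixture("random", 30, seed = 30)
  top <- file.path(d, "s.prmtop"); crd <- file.path(d, "s.inpcrd")
  out <- file.path(d, "report.txt")
  writePrmtop(sys, top); writeInpcrd(sys, crd)
  msgs <- character()
  rep <- withCallingHandlers(
    runEnergyPartition(top, crd, "0=0-9;1=10-19", out = out, workers = 2),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m))
                            invokeRestart("muffleMessage") })
  expect_true(file.exists(out))
  expect_equal(fragmentLabels(rep), c("0", "1", "X"))
  resid <- as.numeric(sub(".*: ([-0-9.e+]+) kcal/mol\n?$", "\\1",
                          grep("residual", msgs, value = TRUE)))
  expect_lt(resid, 1e-9)
  expect_true(any(grepl("^Workers: 2", msgs)))
  ## fragment spec can come from a file
  specFile <- file.path(d, "frags.txt")
  writeLines("0=0-9;1=10-19", specFile)
  rep2 <- runEnergyPartition(top, crd, paste0("@", specFile), quiet = TRUE)
  expect_equal(reportTotals(rep2), reportTotals(rep))
})

test_that("pipeline errors are raised for bad inputs", {
  d <- withr::local_tempdir()
  sys <- makeFixture("chain", 5, seed = 1)
  top <- file.path(d, "c.prmtop"); crd <- file.path(d, "c.inpcrd")
  writePrmtop(sys, top); writeInpcrd(sys, crd)
  expect_error(runEnergyPartition(top, file.path(d, "nope.inpcrd"),
                                  "0=0-1", quiet = TRUE), "nope.inpcrd")
  expect_error(runEnergyPartition(top, crd, "0=0-999999", quiet = TRUE),
               "out of range")
})

test_that("an external parameter block overrides the prmtop tables", {
  d <- withr::local_tempdir()
  sys <- makeFixture("chain", 4, seed = 1)
  top <- file.path(d, "c.prmtop"); crd <- file.path(d, "c.inpcrd")
  writePrmtop(sys, top); writeInpcrd(sys, crd)
  ## double every bond force constant in the override block
  p <- parameters(sys)
  p@bonds$kb <- 2 * p@bonds$kb
  pf <- file.path(d, "params.txt")
  writeGaussianParams(p, file = pf)
  r0 <- runEnergyPartition(top, crd, "0=0-1", quiet = TRUE)
  r1 <- runEnergyPartition(top, crd, "0=0-1", params = pf, quiet = TRUE)
  expect_equal(reportTotals(r1)[["Bonds"]], 2 * reportTotals(r0)[["Bonds"]],
               tolerance = 1e-9)
})

test_that("convertParams writes a re-parseable block matching the prmtop", {
  d <- withr::local_tempdir()
  sys <- makeFixture("random", 20, seed = 17)
  top <- file.path(d, "r.prmtop"); out <- file.path(d, "r.params")
  writePrmtop(sys, top)
  convertParams(top, out)
  p <- parseGaussianParams(readLines(out))
  orig <- parameters(sys)
  for (tp in orig@vdw$type) {
    a <- combineLJ(p, tp, tp); b <- combineLJ(orig, tp, tp)
    expect_equal(a$eps, b$eps, tolerance = 1e-9)
    expect_equal(a$d, b$d, tolerance = 1e-9)
  }
})
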