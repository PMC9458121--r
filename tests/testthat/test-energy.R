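test_that("geometric kernels reproduce elementary cases", {
  expect_equal(pairDistance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(pairDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  ## independent componentwise computation on random pairs
  set.seed(1)
  for (k in 1:10) {
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(pairDistance(p, q),
                 sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2),
                 tolerance = 1e-12)
  }
  expect_equal(bendAngle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), pi)
  expect_equal(bendAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), pi / 2)
  expect_error(bendAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")
  ## near-collinear: cosine overshoot must clamp, not error
  p <- c(1, 1e-9, 0)
  expect_no_error(bendAngle(p, c(0, 0, 0), -p))
})

test_that("dihedral angle handles planar and staggered geometries", {
  ## planar cis: both end atoms on the same side
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  ## planar trans
  expect_equal(abs(dihedralAngle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                 c(1, 0, 0))), pi)
  ## butane-like staggered toy vs an explicit cross-product oracle
  pts <- list(c(0.2, 1.1, -0.3), c(0, 0, 0), c(1.4, 0.1, 0.2),
              c(1.9, -0.8, 1.1))
  b1 <- pts[[2]] - pts[[1]]; b2 <- pts[[3]] - pts[[2]]; b3 <- pts[[4]] - pts[[3]]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ref <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  expect_equal(dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]), ref,
               tolerance = 1e-10)
  ## rigid-motion invariance
  set.seed(2)
  ax <- rnorm(3); ang <- runif(1, 0, 2 * pi)
  R <- amberDecomp:::.rotationMatrix(ax, ang)
  mv <- lapply(pts, function(p) as.vector(R %*% p) + c(3, -2, 5))
  expect_equal(dihedralAngle(mv[[1]], mv[[2]], mv[[3]], mv[[4]]), ref,
               tolerance = 1e-10)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("bond and angle terms are harmonic about their equilibria", {
  expect_equal(bondEnergy(340, 1.09, 1.09), 0)
  expect_equal(bondEnergy(340, 1.09, 1.19), 3.40)
  expect_equal(bondEnergy(0, 1.09, 57), 0)
  th0 <- 120.0001
  expect_equal(angleEnergy(50, th0, th0 * pi / 180), 0)
  expect_equal(angleEnergy(50, th0, th0 * pi / 180 + 0.1), 0.5)
  expect_equal(angleEnergy(0, th0, 2), 0)
  ## evenness: E(x0 + d) == E(x0 - d)
  for (d in c(0.01, 0.3)) {
    expect_equal(bondEnergy(340, 1.09, 1.09 + d), bondEnergy(340, 1.09, 1.09 - d))
    expect_equal(angleEnergy(50, th0, th0 * pi / 180 + d),
                 angleEnergy(50, th0, th0 * pi / 180 - d))
  }
})

test_that("torsion series matches the reference record arithmetic", {
  kd <- c(0, 4.75, 0, 0); ad <- c(0, 180, 0, 0)
  ## at phi = 90 deg the periodicity-2 term peaks: 4.75 (1 + cos(180-180))
  expect_equal(torsionEnergy(kd, ad, 1, pi / 2), 9.5)
  expect_equal(torsionEnergy(c(0, 0, 0, 0), ad, 1, 0.7), 0)
  phis <- seq(-pi, pi, length.out = 17)
  expect_equal(torsionEnergy(kd, ad, 1, phis),
               torsionEnergy(kd, ad, 1, phis + 2 * pi), tolerance = 1e-12)
  ## path count divides the series
  expect_equal(torsionEnergy(kd, ad, 2, pi / 2), 4.75)
  expect_error(torsionEnergy(kd, ad, 0, 1), "positive")
})

test_that("improper term reproduces the reference record arithmetic", {
  expect_equal(improperEnergy(1.1, 180, 2, pi), 0)
  expect_equal(improperEnergy(1.1, 180, 2, pi / 2), 2.2)
  expect_equal(improperEnergy(0, 180, 2, 1), 0)
})

test_that("the LJ well sits at -eps_ij at r = D_ij", {
  p <- parseGaussianParams("VDW HP 1.1000 0.0157")
  c0 <- combineLJ(p, "HP", "HP")
  expect_equal(ljPairEnergy(c0$a, c0$b, 2.2), -0.0157)
  expect_equal(ljPairEnergy(c0$a, c0$b, 2.2, scale = 0), 0)
  expect_lt(abs(ljPairEnergy(c0$a, c0$b, 1e4)), 1e-20)
  ## numerical minimum over r for several type pairs
  p2 <- parseGaussianParams(c("VDW HP 1.1000 0.0157", "VDW CT 1.9080 0.1094"))
  for (pair in list(c("HP", "HP"), c("HP", "CT"), c("CT", "CT"))) {
    cc <- combineLJ(p2, pair[1], pair[2])
    opt <- optimize(function(r) ljPairEnergy(cc$a, cc$b, r), c(0.5, 10),
                    tol = 1e-10)
    expect_equal(opt$objective, -cc$eps, tolerance = 1e-6)
    expect_equal(opt$minimum, cc$d, tolerance = 1e-5)
  }
  expect_error(ljPairEnergy(1, 1, 0), "zero interatomic")
})

test_that("Coulomb term uses the fixed vacuum prefactor and symmetries", {
  expect_equal(coulombPairEnergy(1, -1, 1), -332.063712827427)
  expect_equal(coulombPairEnergy(0, 5, 2), 0)
  expect_equal(coulombPairEnergy(1, -1, 1, scale = 1 / 1.2),
               coulombPairEnergy(1, -1, 1) / 1.2)
  q <- 0.37
  expect_equal(coulombPairEnergy(q, q, 3), coulombPairEnergy(-q, -q, 3))
  expect_equal(coulombPairEnergy(q, -q, 3), -coulombPairEnergy(q, q, 3))
  expect_error(coulombPairEnergy(1, 1, 0), "zero interatomic")
})

test_that("scale factors map classifications to the AMBER constants", {
  expect_equal(scaleFactors("excluded_12"), c(lj = 0, coulomb = 0))
  expect_equal(scaleFactors("excluded_13"), c(lj = 0, coulomb = 0))
  expect_equal(scaleFactors("scaled_14"), c(lj = 0.5, coulomb = 1 / 1.2))
  expect_equal(scaleFactors("full"), c(lj = 1, coulomb = 1))
  expect_error(scaleFactors("bogus"), "unknown")
})

test_that("trivial systems have zero energy", {
  ## two uncharged, LJ-null bonded atoms at the equilibrium length
  prm <- ParameterSet(vdw = data.frame(type = "Z0", radius = 0, eps = 0),
                      bonds = data.frame(t1 = "Z0", t2 = "Z0", kb = 340,
                                         l0 = 1.09))
  sys <- MolecularSystem(data.frame(type = c("Z0", "Z0"), charge = 0,
                                    x = c(0, 1.09), y = 0, z = 0),
                         rbind(c(0, 1)), prm)
  expect_equal(unname(totalEnergy(sys)["Total"]), 0)
  ## a single isolated charged atom has no pairs
  solo <- MolecularSystem(data.frame(type = "Z0", charge = 1,
                                     x = 0, y = 0, z = 0),
                          matrix(integer(), 0, 2), prm)
  expect_equal(unname(totalEnergy(solo)["Total"]), 0)
})

test_that("total energy is invariant under rigid motion", {
  for (rec in c("chain", "star", "random")) {
    sys <- makeFixture(rec, if (rec == "random") 30 else 7, seed = 5)
    e0 <- totalEnergy(sys)
    set.seed(99)
    R <- amberDecomp:::.rotationMatrix(rnorm(3), runif(1, 0, 2 * pi))
    moved <- sys
    coordinates(moved) <- coordinates(sys) %*% t(R) +
      matrix(c(10, -4, 7), nAtoms(sys), 3, byrow = TRUE)
    expect_lt(max(abs(totalEnergy(moved) - e0)), 1e-9)
  }
})

test_that("torsion term energies are reversal-invariant for 0/180 phases", {
  sys <- makeFixture("chain", 6, seed = 1)
  pos <- coordinates(sys)
  prm <- parameters(sys)
  types <- atoms(sys)$type
  for (r in seq_len(nrow(sys@torsions))) {
    q <- sys@torsions[r, ]
    rec <- lookupBonded(prm, "torsion", types[q])
    kd <- c(rec$kd1, rec$kd2, rec$kd3, rec$kd4)
    ad <- c(rec$a1, rec$a2, rec$a3, rec$a4)
    fwd <- torsionEnergy(kd, ad, rec$npaths,
                         dihedralAngle(pos[q[1], ], pos[q[2], ], pos[q[3], ],
                                       pos[q[4], ]))
    rev <- torsionEnergy(kd, ad, rec$npaths,
                         dihedralAngle(pos[q[4], ], pos[q[3], ], pos[q[2], ],
                                       pos[q[1], ]))
    expect_equal(fwd, rev, tolerance = 1e-12)
  }
})

test_that("missing bonded parameters fail naming the type sequence", {
  prm <- ParameterSet(vdw = data.frame(type = c("AA", "BB"),
                                       radius = c(1, 1), eps = c(0.1, 0.1)))
  sys <- MolecularSystem(data.frame(type = c("AA", "BB"), charge = 0,
                                    x = c(0, 1.2), y = 0, z = 0),
                         rbind(c(0, 1)), prm)
  expect_error(totalEnergy(sys), "AA-BB")
})
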