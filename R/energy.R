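## Geometric kernels and the six AMBER energy terms. Positions are in
## Angstrom, charges in elementary-charge units, energies in kcal/mol.
## Parameter tables carry angles in degrees; conversion to radians happens
## here, exactly once.

#' Euclidean distance between two points
#'
#' @param p,q numeric length-3 positions in Angstrom
#' @return distance in Angstrom
#' @examples
#' pairDistance(c(0, 0, 0), c(3, 4, 0))
#' @export
pairDistance <- function(p, q) {
  d <- q - p
  sqrt(sum(d * d))
}

#' Bending angle at the central atom of an i-j-k triple
#'
#' The angle between the j->i and j->k arms, from the normalized dot
#' product. The cosine is clamped to [-1, 1] before the inverse cosine so
#' that floating-point overshoot on near-collinear geometries cannot raise
#' a domain error.
#'
#' @param pi_,pj,pk numeric length-3 positions; pj is the central atom
#' @return angle in radians, in [0, pi]
#' @export
bendAngle <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("zero-length arm in angle: coincident atom positions")
  costh <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, costh)))
}

#' Signed dihedral angle of an i-j-k-l quadruple
#'
#' The angle between the ijk and jkl planes, via their cross-product
#' normals, signed by the orientation about the j->k axis. Invariant under
#' rigid motion of all four points; reversing the quadruple flips the sign,
#' which leaves the cosine-series energies unchanged for phase offsets of
#' 0 or 180 degrees.
#'
#' @param pi_,pj,pk,pl numeric length-3 positions
#' @return signed angle in radians, in (-pi, pi]
#' @export
dihedralAngle <- function(pi_, pj, pk, pl) {
  b1 <- pj - pi_; b2 <- pk - pj; b3 <- pl - pk
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nn1 <- sqrt(sum(n1 * n1)); nn2 <- sqrt(sum(n2 * n2))
  if (nn1 == 0 || nn2 == 0)
    stop("collinear atoms in dihedral: plane normal undefined")
  cosphi <- min(1, max(-1, sum(n1 * n2) / (nn1 * nn2)))
  phi <- acos(cosphi)
  if (sum(.cross3(n1, n2) * b2) < 0) phi <- -phi
  phi
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Harmonic bond energy
#'
#' kb (l - l0)^2 for a bond of current length `l`.
#'
#' @param kb force constant, kcal/mol/A^2
#' @param l0 equilibrium length, Angstrom
#' @param l current length, Angstrom (vectorized)
#' @return energy in kcal/mol
#' @examples
#' bondEnergy(340, 1.09, 1.19)   # 3.4
#' @export
bondEnergy <- function(kb, l0, l) kb * (l - l0)^2

#' Harmonic angle energy
#'
#' ka (theta - theta0)^2 with the equilibrium angle given in degrees (as
#' stored in parameter tables) and the current angle in radians.
#'
#' @param ka force constant, kcal/mol/rad^2
#' @param theta0deg equilibrium angle, degrees
#' @param theta current angle, radians (vectorized)
#' @return energy in kcal/mol
#' @export
angleEnergy <- function(ka, theta0deg, theta) {
  ka * (theta - .deg2rad(theta0deg))^2
}

#' Cosine-series torsion energy
#'
#' Sum over periodicities i = 1..4 of kd_i (1 + cos(i phi - A_i)) / N,
#' with the phase offsets A_i given in degrees and the path count N
#' dividing the whole series. 2 pi periodic in phi.
#'
#' @param kd numeric length-4 magnitudes, kcal/mol (slot i = periodicity i)
#' @param adeg numeric length-4 phase offsets, degrees
#' @param npaths path count N (> 0)
#' @param phi dihedral angle, radians (vectorized)
#' @return energy in kcal/mol
#' @export
torsionEnergy <- function(kd, adeg, npaths, phi) {
  if (npaths <= 0) stop("torsion path count must be positive")
  arad <- .deg2rad(adeg)
  e <- 0
  for (i in 1:4) e <- e + kd[i] * (1 + cos(i * phi - arad[i]))
  e / npaths
}

#' Improper (out-of-plane) torsion energy
#'
#' ki (1 - cos(P (sigma - A))) with the phase A in degrees and the
#' out-of-plane angle sigma in radians.
#'
#' @param ki magnitude, kcal/mol
#' @param adeg phase offset, degrees
#' @param period periodicity P
#' @param sigma improper dihedral angle, radians (vectorized)
#' @return energy in kcal/mol
#' @export
improperEnergy <- function(ki, adeg, period, sigma) {
  ki * (1 - cos(period * (sigma - .deg2rad(adeg))))
}

#' Lennard-Jones pair energy
#'
#' scale (A/r^12 - B/r^6). With coefficients from [combineLJ()] the
#' unscaled minimum is -eps_ij, attained at r = D_ij.
#'
#' @param a,b pair coefficients A_ij (kcal A^12/mol), B_ij (kcal A^6/mol)
#' @param r separation, Angstrom (vectorized)
#' @param scale 0, 0.5 or 1 (the 1-4 scale is 0.5)
#' @return energy in kcal/mol
#' @export
ljPairEnergy <- function(a, b, r, scale = 1) {
  if (any(r == 0 & (a != 0 | b != 0)))
    stop("zero interatomic distance with nonzero Lennard-Jones coefficients")
  r6 <- r^6
  scale * (a / (r6 * r6) - b / r6)
}

#' Coulomb pair energy
#'
#' scale * 332.063712827427 * qi qj / r, the vacuum electrostatic
#' interaction of two point charges in kcal/mol.
#'
#' @param qi,qj charges in elementary-charge units
#' @param r separation, Angstrom (vectorized)
#' @param scale 0, 1/1.2 or 1 (the 1-4 scale is 1/1.2)
#' @return energy in kcal/mol
#' @examples
#' coulombPairEnergy(1, -1, 1)   # -332.063712827427
#' @export
coulombPairEnergy <- function(qi, qj, r, scale = 1) {
  if (any(r == 0 & qi * qj != 0))
    stop("zero interatomic distance between charged atoms")
  scale * .COULOMB * qi * qj / r
}

#' Nonbonded scale factors for a pair classification
#'
#' Pairs one or two bonds apart are excluded (their interaction is carried
#' by the bond and angle terms); pairs three bonds apart are scaled by 0.5
#' (Lennard-Jones) and 1/1.2 (Coulomb); all others are full strength.
#'
#' @param classification character, one or more of "excluded_12",
#'   "excluded_13", "scaled_14", "full" (or integer codes from
#'   [classifyPairs()])
#' @return for a single classification, named numeric c(lj, coulomb); for
#'   several, a two-column matrix
#' @examples
#' scaleFactors("scaled_14")
#' @export
scaleFactors <- function(classification) {
  if (is.numeric(classification)) classification <- pairClassLabel(classification)
  code <- match(classification, .PAIR_CLASSES)
  if (anyNA(code)) stop("unknown pair classification: ",
                        paste(classification[is.na(code)], collapse = ", "))
  lj <- c(0, 0, 0.5, 1)[code]
  coul <- c(0, 0, 1 / 1.2, 1)[code]
  if (length(code) == 1L) c(lj = lj, coulomb = coul)
  else cbind(lj = lj, coulomb = coul)
}

## ---- whole-system evaluation ----------------------------------------------

.requirePositions <- function(system) {
  if (anyNA(system@atoms$x) || anyNA(system@atoms$y) || anyNA(system@atoms$z))
    stop("system has no coordinates attached; read coordinates first")
}

## Evaluate every term instance once. Returns per-term energies together
## with the participating atom rows, the shared currency of totalEnergy()
## and partitionedEnergy() (so the partition is conservative by
## construction, up to summation order).
.evaluateTerms <- function(system) {
  .requirePositions(system)
  at <- system@atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  prm <- system@params
  types <- at$type

  bondE <- numeric(nrow(system@bonds))
  if (nrow(system@bonds)) {
    for (r in seq_len(nrow(system@bonds))) {
      i <- system@bonds[r, 1]; j <- system@bonds[r, 2]
      rec <- lookupBonded(prm, "bond", c(types[i], types[j]))
      if (is.null(rec))
        stop(sprintf("missing bond parameters for type pair %s-%s (atoms %d-%d)",
                     types[i], types[j], i - 1L, j - 1L))
      bondE[r] <- bondEnergy(rec$kb, rec$l0, pairDistance(pos[i, ], pos[j, ]))
    }
  }

  angleE <- numeric(nrow(system@angles))
  if (nrow(system@angles)) {
    for (r in seq_len(nrow(system@angles))) {
      ijk <- system@angles[r, ]
      rec <- lookupBonded(prm, "angle", types[ijk])
      if (is.null(rec))
        stop(sprintf("missing angle parameters for type triple %s (atoms %s)",
                     paste(types[ijk], collapse = "-"),
                     paste(ijk - 1L, collapse = "-")))
      angleE[r] <- angleEnergy(rec$ka, rec$theta0,
                               bendAngle(pos[ijk[1], ], pos[ijk[2], ],
                                         pos[ijk[3], ]))
    }
  }

  torsionE <- numeric(nrow(system@torsions))
  if (nrow(system@torsions)) {
    for (r in seq_len(nrow(system@torsions))) {
      q <- system@torsions[r, ]
      rec <- lookupBonded(prm, "torsion", types[q])
      if (is.null(rec))
        stop(sprintf("missing torsion parameters for type quadruple %s (atoms %s)",
                     paste(types[q], collapse = "-"),
                     paste(q - 1L, collapse = "-")))
      phi <- dihedralAngle(pos[q[1], ], pos[q[2], ], pos[q[3], ], pos[q[4], ])
      torsionE[r] <- torsionEnergy(c(rec$kd1, rec$kd2, rec$kd3, rec$kd4),
                                   c(rec$a1, rec$a2, rec$a3, rec$a4),
                                   rec$npaths, phi)
    }
  }

  improperE <- numeric(nrow(system@impropers))
  if (nrow(system@impropers)) {
    for (r in seq_len(nrow(system@impropers))) {
      q <- system@impropers[r, ]
      rec <- lookupBonded(prm, "improper", types[q])
      ## candidates were filtered against the table at enumeration
      sigma <- dihedralAngle(pos[q[1], ], pos[q[2], ], pos[q[3], ], pos[q[4], ])
      improperE[r] <- improperEnergy(rec$ki, rec$phase, rec$period, sigma)
    }
  }

  ## nonbonded: all pairs i < j, no cutoff, vectorized in index order
  n <- nrow(at)
  if (n >= 2) {
    pr <- .pairIndexes(n)
    i <- pr[, 1]; j <- pr[, 2]
    dx <- pos[j, 1] - pos[i, 1]
    dy <- pos[j, 2] - pos[i, 2]
    dz <- pos[j, 3] - pos[i, 3]
    rij <- sqrt(dx * dx + dy * dy + dz * dz)
    cls <- classifyPairs(system@adjacency)
    code <- cls[cbind(i, j)]
    sLJ <- c(0, 0, 0.5, 1)[code]
    sC <- c(0, 0, 1 / 1.2, 1)[code]
    ljc <- .pairLJCoefs(prm, types, i, j)
    vdwE <- ljPairEnergy(ljc$a, ljc$b, rij, sLJ)
    coulE <- coulombPairEnergy(at$charge[i], at$charge[j], rij, sC)
  } else {
    pr <- matrix(integer(), 0, 2)
    vdwE <- numeric(); coulE <- numeric()
  }

  list(bonds = list(atoms = system@bonds, energy = bondE),
       angles = list(atoms = system@angles, energy = angleE),
       torsions = list(atoms = system@torsions, energy = torsionE),
       impropers = list(atoms = system@impropers, energy = improperE),
       vdw = list(atoms = pr, energy = vdwE),
       coulomb = list(atoms = pr, energy = coulE),
       warnings = system@improperWarnings)
}

.pairIndexes <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i, j)
}

## A/B coefficients per pair via a precomputed type-by-type matrix
.pairLJCoefs <- function(params, types, i, j) {
  v <- params@vdw
  ti <- match(types, v$type)
  if (anyNA(ti))
    stop("missing vdw parameters for type(s): ",
         paste(unique(types[is.na(ti)]), collapse = ", "))
  eps <- sqrt(outer(v$eps, v$eps))
  d <- outer(v$radius, v$radius, "+")
  A <- eps * d^12
  B <- 2 * eps * d^6
  idx <- cbind(ti[i], ti[j])
  list(a = A[idx], b = B[idx])
}

#' Total AMBER energy of a system
#'
#' Evaluates every bond, angle, proper-torsion and improper-torsion term
#' instance plus the Lennard-Jones and Coulomb interactions over all atom
#' pairs (no cutoff, plain Euclidean distances, 1-2/1-3 exclusions and 1-4
#' scaling from the covalent connectivity) and returns the six class
#' subtotals and their sum. Accumulation order is fixed (ascending index),
#' so results are reproducible on a platform.
#'
#' Missing bond/angle/torsion parameters are errors naming the type
#' sequence; improper candidates without parameters were already dropped
#' with a warning at enumeration.
#'
#' @param system a [MolecularSystem-class] with coordinates attached
#' @return named numeric: Bonds, Angles, Torsions, Out-of-Plane, VDW,
#'   Coulomb, Total (kcal/mol)
#' @export
totalEnergy <- function(system) {
  stopifnot(is(system, "MolecularSystem"))
  ev <- .evaluateTerms(system)
  out <- c(Bonds = sum(ev$bonds$energy),
           Angles = sum(ev$angles$energy),
           Torsions = sum(ev$torsions$energy),
           "Out-of-Plane" = sum(ev$impropers$energy),
           VDW = sum(ev$vdw$energy),
           Coulomb = sum(ev$coulomb$energy))
  c(out, Total = sum(out))
}
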