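## Synthetic fully-parameterized systems for testing and validation.
## Recipes build small molecules with realistic covalent geometry (helical
## chains with 1.5 A bonds, rings, stars) and synthesize a complete
## parameter table for exactly the type sequences that occur, using the
## reference record values as templates (bond kb 340 kcal/mol/A^2,
## l0 1.09 A; angle ka 50 kcal/mol/rad^2, theta0 120.0001 deg; torsion
## slot-2 magnitude 4.75 kcal/mol with 180 deg phase, N = 1; improper
## ki 1.1, phase 180, period 2; vdW R 1.1 A, eps 0.0157). The random
## recipe draws parameter values and charges from seeded distributions.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.FIXTURE_TYPES <- c("CT", "HC", "N3")

## helical chain geometry: 1.5 A bonds, non-collinear, non-planar
.chainPositions <- function(n, b = 1.09) {
  om <- 1.2; r <- 0.8
  cc <- sqrt(b^2 - 2 * r^2 * (1 - cos(om)))
  i <- seq_len(n) - 1
  cbind(r * cos(om * i), r * sin(om * i), cc * i)
}

.ringPositions <- function(n, b = 1.09) {
  R <- b / (2 * sin(pi / n))
  i <- seq_len(n) - 1
  cbind(R * cos(2 * pi * i / n), R * sin(2 * pi * i / n), 0)
}

## complete parameter set for whatever type sequences the bonded terms use
.paletteFor <- function(types, adj, randomize = FALSE) {
  vdwTypes <- unique(types)
  if (randomize) {
    vdw <- data.frame(type = vdwTypes,
                      radius = round(stats::runif(length(vdwTypes), 0.9, 1.6), 4),
                      eps = round(stats::runif(length(vdwTypes), 0.01, 0.2), 4),
                      stringsAsFactors = FALSE)
  } else {
    vdw <- data.frame(type = vdwTypes, radius = 1.1, eps = 0.0157,
                      stringsAsFactors = FALSE)
  }

  bondsM <- .bondsFromAdjacency(adj)
  bondKeys <- unique(.bondKey(types[bondsM[, 1]], types[bondsM[, 2]]))
  bonds <- if (length(bondKeys)) {
    parts <- do.call(rbind, strsplit(bondKeys, "|", fixed = TRUE))
    data.frame(t1 = parts[, 1], t2 = parts[, 2],
               kb = if (randomize) round(stats::runif(length(bondKeys), 200, 500), 2) else 340,
               l0 = if (randomize) round(stats::runif(length(bondKeys), 1.3, 1.6), 4) else 1.09,
               stringsAsFactors = FALSE)
  } else .emptyBonds()

  angM <- enumerateAngles(adj)
  angKeys <- unique(.angleKey(types[angM[, 1]], types[angM[, 2]],
                              types[angM[, 3]]))
  angles <- if (length(angKeys)) {
    parts <- do.call(rbind, strsplit(angKeys, "|", fixed = TRUE))
    data.frame(t1 = parts[, 1], t2 = parts[, 2], t3 = parts[, 3],
               ka = if (randomize) round(stats::runif(length(angKeys), 30, 80), 2) else 50,
               theta0 = if (randomize) round(stats::runif(length(angKeys), 100, 130), 4) else 120.0001,
               stringsAsFactors = FALSE)
  } else .emptyAngles()

  torM <- enumerateTorsions(adj)
  torKeys <- unique(.torsionKey(types[torM[, 1]], types[torM[, 2]],
                                types[torM[, 3]], types[torM[, 4]]))
  torsions <- if (length(torKeys)) {
    parts <- do.call(rbind, strsplit(torKeys, "|", fixed = TRUE))
    k <- length(torKeys)
    d <- data.frame(t1 = parts[, 1], t2 = parts[, 2], t3 = parts[, 3],
                    t4 = parts[, 4], stringsAsFactors = FALSE)
    d$a1 <- 0; d$a2 <- 180; d$a3 <- 0; d$a4 <- 0
    d$kd1 <- if (randomize) round(stats::runif(k, 0, 2), 3) else 0
    d$kd2 <- if (randomize) round(stats::runif(k, 0, 5), 3) else 4.75
    d$kd3 <- if (randomize) round(stats::runif(k, 0, 1), 3) else 0
    d$kd4 <- 0
    d$npaths <- 1
    d[names(.emptyTorsions())]
  } else .emptyTorsions()

  ## impropers: one record per 3-coordinated centre's type environment
  centres <- which(lengths(adj) == 3)
  impropers <- .emptyImpropers()
  if (length(centres)) {
    seen <- character()
    for (c0 in centres) {
      nb <- sort(adj[[c0]])
      key <- .improperKey(types[nb[1]], types[nb[2]], types[c0], types[nb[3]])
      if (key %in% seen) next
      seen <- c(seen, key)
      impropers <- rbind(impropers, data.frame(
        t1 = types[nb[1]], t2 = types[nb[2]], t3 = types[c0],
        t4 = types[nb[3]],
        ki = if (randomize) round(stats::runif(1, 0.5, 2), 3) else 1.1,
        phase = 180, period = 2, stringsAsFactors = FALSE))
    }
  }

  ParameterSet(vdw = vdw, bonds = bonds, angles = angles,
               torsions = torsions, impropers = impropers,
               chargeSource = "fixture")
}

.rotationMatrix <- function(ax, ang) {
  ax <- ax / sqrt(sum(ax^2))
  c0 <- cos(ang); s <- sin(ang); C <- 1 - c0
  matrix(c(ax[1]^2 * C + c0, ax[1] * ax[2] * C - ax[3] * s, ax[1] * ax[3] * C + ax[2] * s,
           ax[1] * ax[2] * C + ax[3] * s, ax[2]^2 * C + c0, ax[2] * ax[3] * C - ax[1] * s,
           ax[1] * ax[3] * C - ax[2] * s, ax[2] * ax[3] * C + ax[1] * s, ax[3]^2 * C + c0),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic, fully parameterized molecular system
#'
#' Recipes:
#' \describe{
#'   \item{chain}{a single helical n-atom chain: the canonical
#'     1-2/1-3/1-4 ladder with n-1 bonds, n-2 angles, n-3 torsions.}
#'   \item{star}{atom 0 bonded to all others; with exactly three arms the
#'     centre is an improper-torsion candidate.}
#'   \item{ring}{an n-cycle (n >= 3), planar regular polygon.}
#'   \item{two-molecule}{two disconnected chains (sizes n %/% 2 and the
#'     remainder) offset by 6 Angstrom; all inter-molecular pairs are
#'     full-strength nonbonded.}
#'   \item{random}{several chain molecules of seeded random sizes placed
#'     in a 20 Angstrom box with minimum pair separation 0.8 Angstrom
#'     (bounded retries, then error), charges uniform in [-1, 1] e,
#'     randomized parameter tables.}
#' }
#' Identical recipe, size and seed reproduce the identical system.
#' Non-random recipes carry alternating charges of +/- 0.3 e and the
#' reference parameter values on every type sequence.
#'
#' @param recipe one of "chain", "star", "ring", "two-molecule", "random"
#' @param nAtoms atom count (recipe minimum applies)
#' @param seed integer seed controlling every random draw
#' @return a [MolecularSystem-class] with positions set
#' @examples
#' sys <- makeFixture("chain", 4)
#' totalEnergy(sys)
#' @export
makeFixture <- function(recipe = c("chain", "star", "ring", "two-molecule",
                                   "random"),
                        nAtoms, seed = 1L) {
  recipe <- match.arg(recipe)
  n <- as.integer(nAtoms)
  .withSeed(as.integer(seed), {
    if (recipe == "random") {
      .randomFixture(n)
    } else {
      .regularFixture(recipe, n)
    }
  })
}

.regularFixture <- function(recipe, n) {
    if (recipe == "chain") {
      if (n < 2) stop("chain recipe needs at least 2 atoms")
      bonds <- cbind(0:(n - 2), 1:(n - 1))
      pos <- .chainPositions(n)
    } else if (recipe == "star") {
      if (n < 3) stop("star recipe needs at least 3 atoms")
      bonds <- cbind(0L, 1:(n - 1))
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      if (n - 1 > 4) {
        extra <- matrix(stats::rnorm(3 * (n - 5)), ncol = 3)
        dirs <- rbind(dirs, extra / sqrt(rowSums(extra^2)) * sqrt(3))
      }
      pos <- rbind(c(0, 0, 0), 1.09 * dirs[1:(n - 1), , drop = FALSE] / sqrt(3))
    } else if (recipe == "ring") {
      if (n < 3) stop("ring recipe needs at least 3 atoms")
      bonds <- cbind(0:(n - 1), c(1:(n - 1), 0))
      pos <- .ringPositions(n)
    } else {
      if (n < 2) stop("two-molecule recipe needs at least 2 atoms")
      na <- max(1L, n %/% 2); nb <- n - na
      bonds <- rbind(
        if (na > 1) cbind(0:(na - 2), 1:(na - 1)) else NULL,
        if (nb > 1) cbind(na + 0:(nb - 2), na + 1:(nb - 1)) else NULL)
      if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
      pos <- rbind(.chainPositions(na),
                   sweep(.chainPositions(max(nb, 1)), 2, c(6, 0, 0), "+")[seq_len(nb), , drop = FALSE])
    }
    ## 7-decimal positions are exactly representable in fixed-width
    ## coordinate files, so write -> read round trips are lossless
    pos <- round(pos, 7)
    types <- .FIXTURE_TYPES[(seq_len(n) - 1L) %% 3L + 1L]
    charges <- ifelse(seq_len(n) %% 2 == 1, 0.3, -0.3)
    adj <- .adjacencyFromBonds(matrix(as.integer(bonds) + 1L, ncol = 2), n)
    params <- .paletteFor(types, adj, randomize = FALSE)
    resid <- if (recipe == "two-molecule")
      rep(c(1L, 2L), c(na, nb)) else rep(1L, n)
    atoms <- data.frame(type = types, charge = charges,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        resid = resid, resname = "FIX",
                        stringsAsFactors = FALSE)
    MolecularSystem(atoms, bonds, params)
}

.randomFixture <- function(n) {
  ## split atoms into chain molecules of random sizes 1..6
  sizes <- integer(); left <- n
  while (left > 0) {
    s <- min(left, sample.int(6, 1))
    sizes <- c(sizes, s); left <- left - s
  }
  placed <- matrix(numeric(), 0, 3)
  bonds <- matrix(integer(), 0, 2)
  offset <- 0L
  resid <- integer()
  for (mi in seq_along(sizes)) {
    s <- sizes[mi]
    base <- .chainPositions(s, b = 1.45)
    ok <- FALSE
    for (try in 1:50) {
      rot <- .rotationMatrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      shift <- stats::runif(3, 2, 18)
      cand <- sweep(base %*% t(rot), 2, shift, "+")
      if (any(cand < 0 | cand > 20)) next
      if (!nrow(placed)) { ok <- TRUE; break }
      dmin <- min(vapply(seq_len(nrow(cand)), function(r)
        min(sqrt(rowSums(sweep(placed, 2, cand[r, ], "-")^2))), numeric(1)))
      if (dmin >= 0.8) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place molecule ", mi,
                  " with 0.8 A minimum separation after 50 attempts")
    placed <- rbind(placed, cand)
    if (s > 1)
      bonds <- rbind(bonds, cbind(offset + 0:(s - 2), offset + 1:(s - 1)))
    resid <- c(resid, rep(mi, s))
    offset <- offset + s
  }
  placed <- round(placed, 7)
  types <- sample(.FIXTURE_TYPES, n, replace = TRUE)
  charges <- stats::runif(n, -1, 1)
  adj <- .adjacencyFromBonds(matrix(as.integer(bonds) + 1L, ncol = 2), n)
  params <- .paletteFor(types, adj, randomize = TRUE)
  atoms <- data.frame(type = types, charge = charges,
                      x = placed[, 1], y = placed[, 2], z = placed[, 3],
                      resid = resid, resname = "RND",
                      stringsAsFactors = FALSE)
  MolecularSystem(atoms, bonds, params)
}
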