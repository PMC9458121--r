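## Independent brute-force energy oracle. Deliberately shares no geometry,
## lookup, classification or accumulation code with the energy engine:
## terms are re-enumerated with its own loops, angles come from the law of
## cosines, dihedrals from the atan2 formulation, pair separations from
## igraph shortest paths, and parameter matching scans the tables trying
## both orientations. Used to validate totalEnergy() on synthetic systems.

.oracleCross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .oracleCross(b1, b2); n2 <- .oracleCross(b2, b3)
  m1 <- .oracleCross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.oracleFindBond <- function(tab, ta, tb) {
  for (r in seq_len(nrow(tab)))
    if ((tab$t1[r] == ta && tab$t2[r] == tb) ||
        (tab$t1[r] == tb && tab$t2[r] == ta)) return(tab[r, ])
  NULL
}

.oracleFindAngle <- function(tab, ts) {
  for (r in seq_len(nrow(tab))) {
    row <- c(tab$t1[r], tab$t2[r], tab$t3[r])
    if (all(row == ts) || all(rev(row) == ts)) return(tab[r, ])
  }
  NULL
}

.oracleFindTorsion <- function(tab, ts) {
  for (r in seq_len(nrow(tab))) {
    row <- c(tab$t1[r], tab$t2[r], tab$t3[r], tab$t4[r])
    if (all(row == ts) || all(rev(row) == ts)) return(tab[r, ])
  }
  NULL
}

.oracleFindImproper <- function(tab, ts) {
  for (r in seq_len(nrow(tab))) {
    if (tab$t3[r] != ts[3]) next
    if (identical(sort(c(tab$t1[r], tab$t2[r], tab$t4[r])),
                  sort(ts[c(1, 2, 4)]))) return(tab[r, ])
  }
  NULL
}

#' Brute-force reference energy of a system
#'
#' Maximally naive re-computation of the full energy function, implemented
#' independently of [totalEnergy()] (separate term enumeration, separate
#' geometry formulas, igraph shortest paths for the nonbonded pair
#' classification, naive double loops). Intended as the in-repo oracle for
#' validating the engine; quadratic-plus cost, use on small systems.
#'
#' @param system a [MolecularSystem-class] with positions set
#' @return named numeric: Bonds, Angles, Torsions, Out-of-Plane, VDW,
#'   Coulomb, Total (kcal/mol)
#' @export
bruteForceEnergy <- function(system) {
  stopifnot(is(system, "MolecularSystem"))
  at <- system@atoms
  if (anyNA(at$x)) stop("system has no coordinates attached")
  n <- nrow(at)
  P <- lapply(seq_len(n), function(i) c(at$x[i], at$y[i], at$z[i]))
  prm <- system@params
  edges <- .bondsFromAdjacency(system@adjacency)
  nbr <- lapply(seq_len(n), function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  })

  eBond <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    rec <- .oracleFindBond(prm@bonds, at$type[i], at$type[j])
    if (is.null(rec)) stop("oracle: missing bond parameters ",
                           at$type[i], "-", at$type[j])
    l <- sqrt((at$x[j] - at$x[i])^2 + (at$y[j] - at$y[i])^2 +
              (at$z[j] - at$z[i])^2)
    eBond <- eBond + rec$kb * (l - rec$l0)^2
  }

  eAngle <- 0
  for (j in seq_len(n)) {
    nb <- sort(nbr[[j]])
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[b]
      rec <- .oracleFindAngle(prm@angles, at$type[c(i, j, k)])
      if (is.null(rec)) stop("oracle: missing angle parameters ",
                             paste(at$type[c(i, j, k)], collapse = "-"))
      ## law of cosines
      dij <- sqrt(sum((P[[i]] - P[[j]])^2))
      djk <- sqrt(sum((P[[k]] - P[[j]])^2))
      dik <- sqrt(sum((P[[k]] - P[[i]])^2))
      costh <- (dij^2 + djk^2 - dik^2) / (2 * dij * djk)
      th <- acos(max(-1, min(1, costh)))
      eAngle <- eAngle + rec$ka * (th - rec$theta0 * pi / 180)^2
    }
  }

  eTor <- 0
  seenTor <- character()
  for (j in seq_len(n)) for (k in nbr[[j]]) {
    for (i in nbr[[j]]) {
      if (i == k) next
      for (l in nbr[[k]]) {
        if (l == j || l == i) next
        key <- paste(min(paste(c(i, j, k, l), collapse = ","),
                         paste(c(l, k, j, i), collapse = ",")))
        if (key %in% seenTor) next
        seenTor <- c(seenTor, key)
        rec <- .oracleFindTorsion(prm@torsions, at$type[c(i, j, k, l)])
        if (is.null(rec)) stop("oracle: missing torsion parameters ",
                               paste(at$type[c(i, j, k, l)], collapse = "-"))
        phi <- .oracleDihedral(P[[i]], P[[j]], P[[k]], P[[l]])
        kd <- c(rec$kd1, rec$kd2, rec$kd3, rec$kd4)
        ad <- c(rec$a1, rec$a2, rec$a3, rec$a4) * pi / 180
        for (m in 1:4)
          eTor <- eTor + kd[m] * (1 + cos(m * phi - ad[m])) / rec$npaths
      }
    }
  }

  eImp <- 0
  for (c0 in seq_len(n)) {
    nb <- sort(nbr[[c0]])
    if (length(nb) != 3) next
    rec <- .oracleFindImproper(prm@impropers,
                               at$type[c(nb[1], nb[2], c0, nb[3])])
    if (is.null(rec)) next     # unparameterized candidates are skipped
    sig <- .oracleDihedral(P[[nb[1]]], P[[nb[2]]], P[[c0]], P[[nb[3]]])
    eImp <- eImp + rec$ki * (1 - cos(rec$period * (sig - rec$phase * pi / 180)))
  }

  ## nonbonded via igraph shortest bond-path lengths
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  sp <- igraph::distances(g)
  eVdw <- 0; eCoul <- 0
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sp[i, j]
    if (d <= 2) next
    sLJ <- if (d == 3) 0.5 else 1
    sC <- if (d == 3) 1 / 1.2 else 1
    r <- sqrt(sum((P[[i]] - P[[j]])^2))
    vi <- prm@vdw[prm@vdw$type == at$type[i], ]
    vj <- prm@vdw[prm@vdw$type == at$type[j], ]
    eps <- sqrt(vi$eps * vj$eps); D <- vi$radius + vj$radius
    A <- eps * D^12; B <- 2 * eps * D^6
    eVdw <- eVdw + sLJ * (A / r^12 - B / r^6)
    eCoul <- eCoul + sC * 332.063712827427 * at$charge[i] * at$charge[j] / r
  }

  out <- c(Bonds = eBond, Angles = eAngle, Torsions = eTor,
           "Out-of-Plane" = eImp, VDW = eVdw, Coulomb = eCoul)
  c(out, Total = sum(out))
}
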