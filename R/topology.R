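## All user-facing atom indexes are 0-based; internal atom-table rows and
## adjacency entries are 1-based R rows. Conversion happens at the API edge.

.adjacencyFromBonds <- function(bonds, n) {
  adj <- rep(list(integer()), n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      if (i == j) stop("self-bond on atom ", i - 1L)
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

.bondsFromAdjacency <- function(adj) {
  out <- list()
  for (i in seq_along(adj)) {
    nb <- adj[[i]]
    nb <- nb[nb > i]
    if (length(nb)) out[[length(out) + 1]] <- cbind(i, nb)
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    dimnames(m) <- NULL
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  } else matrix(integer(), 0, 2)
}

#' Enumerate angle terms from connectivity
#'
#' One angle per unordered bonded path i-j-k of length two, centred on j,
#' in canonical orientation i < k.
#'
#' @param adjacency list of integer vectors (1-based neighbour rows), e.g.
#'   the `adjacency` slot of a [MolecularSystem-class]
#' @return integer matrix with columns (i, j, k), 1-based rows
#' @export
enumerateAngles <- function(adjacency) {
  out <- list()
  for (j in seq_along(adjacency)) {
    nb <- sort(adjacency[[j]])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out[[length(out) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    dimnames(m) <- NULL
    m[order(m[, 2], m[, 1], m[, 3]), , drop = FALSE]
  } else matrix(integer(), 0, 3)
}

#' Enumerate proper torsion terms from connectivity
#'
#' One torsion per simple path i-j-k-l of length three (no repeated atoms),
#' deduplicated under reversal. Ring-closing 4-paths are included.
#'
#' @inheritParams enumerateAngles
#' @return integer matrix with columns (i, j, k, l), 1-based rows
#' @export
enumerateTorsions <- function(adjacency) {
  out <- list()
  for (j in seq_along(adjacency)) {
    for (k in adjacency[[j]]) {
      if (k < j) next                 # central bond j-k taken once, j < k
      for (i in adjacency[[j]]) {
        if (i == k) next
        for (l in adjacency[[k]]) {
          if (l == j || l == i) next
          out[[length(out) + 1]] <- c(i, j, k, l)
        }
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 4))
  m <- do.call(rbind, out)
  ## canonical orientation: lexicographically smaller of (ijkl) and (lkji)
  flip <- (m[, 2] > m[, 3]) | (m[, 2] == m[, 3] & m[, 1] > m[, 4])
  m[flip, ] <- m[flip, c(4, 3, 2, 1), drop = FALSE]
  m <- unique(m)
  dimnames(m) <- NULL
  m[order(m[, 2], m[, 3], m[, 1], m[, 4]), , drop = FALSE]
}

#' Enumerate improper torsion candidates against a parameter table
#'
#' Every atom bonded to exactly three others is an improper-torsion
#' candidate centre. Its neighbours, sorted by atom index, give the
#' peripheral type sequence tried against the improper table (which is
#' insensitive to permutation of the peripheral positions); on a match the
#' term (n1, n2, centre, n3) is emitted with the centre third. Candidates
#' with no matching parameters produce a warning naming the centre atom,
#' never an error.
#'
#' @inheritParams enumerateAngles
#' @param types character vector of per-atom type labels
#' @param params a [ParameterSet-class]
#' @return list with `terms` (integer matrix, columns (i, j, centre, k))
#'   and `warnings` (character)
#' @export
enumerateImpropers <- function(adjacency, types, params) {
  out <- list(); warn <- character()
  for (c0 in seq_along(adjacency)) {
    nb <- sort(adjacency[[c0]])
    if (length(nb) != 3) next
    rec <- lookupBonded(params, "improper",
                        c(types[nb[1]], types[nb[2]], types[c0], types[nb[3]]))
    if (is.null(rec)) {
      warn <- c(warn, sprintf(
        "no improper-torsion parameters for centre atom %d (%s; neighbours %s)",
        c0 - 1L, types[c0], paste(types[nb], collapse = " ")))
      next
    }
    out[[length(out) + 1]] <- c(nb[1], nb[2], c0, nb[3])
  }
  terms <- if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 4)
  dimnames(terms) <- NULL
  list(terms = terms, warnings = warn)
}

#' Classify all atom pairs by minimal bond-path length
#'
#' Breadth-first search from each atom, truncated at depth three, assigns
#' every unordered pair its minimal covalent-bond separation: 1 bond ->
#' `excluded_12`, 2 -> `excluded_13`, 3 -> `scaled_14`, four or more (or
#' disconnected) -> `full`. Ring-closure pairs take the shorter path.
#'
#' @inheritParams enumerateAngles
#' @return n x n integer matrix of codes 1..4 into
#'   `c("excluded_12", "excluded_13", "scaled_14", "full")`; symmetric,
#'   diagonal 0.
#' @export
classifyPairs <- function(adjacency) {
  n <- length(adjacency)
  cls <- matrix(4L, n, n)
  diag(cls) <- 0L
  for (s in seq_len(n)) {
    depth <- rep(NA_integer_, n)
    depth[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adjacency[[v]]) {
          if (is.na(depth[w])) { depth[w] <- d; nxt <- c(nxt, w) }
        }
      }
      if (!length(nxt)) break
      cls[s, nxt] <- pmin(cls[s, nxt], d)
      frontier <- nxt
    }
  }
  ## BFS already yields minimal depths; symmetrize defensively
  pmin(cls, t(cls))
}

#' Pair classification labels
#'
#' Decode the integer codes of [classifyPairs()] into their labels.
#' @param code integer codes 1..4
#' @return character labels
#' @export
pairClassLabel <- function(code) .PAIR_CLASSES[code]

#' Assemble a MolecularSystem
#'
#' Builds the system object from an atom table, a bond list and a
#' [ParameterSet-class]: derives the symmetric adjacency, enumerates all
#' angle, proper-torsion and improper-torsion term instances from
#' connectivity, and records improper-parameter warnings.
#'
#' @param atoms data.frame with columns type, charge and optionally x, y, z
#'   (Angstrom), resid, resname. Row order defines atom indexes 0..n-1.
#' @param bonds two-column matrix/data.frame of 0-based bonded atom index
#'   pairs
#' @param params a [ParameterSet-class]
#' @return a [MolecularSystem-class]
#' @export
MolecularSystem <- function(atoms, bonds, params) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$x)) { atoms$x <- NA_real_; atoms$y <- NA_real_; atoms$z <- NA_real_ }
  if (is.null(atoms$resid)) atoms$resid <- 1L
  if (is.null(atoms$resname)) atoms$resname <- "MOL"
  atoms <- atoms[, c("type", "charge", "x", "y", "z", "resid", "resname")]
  rownames(atoms) <- NULL
  bonds <- as.matrix(bonds)
  if (length(bonds) && ncol(bonds) != 2) stop("bonds must have two columns")
  if (length(bonds) && (min(bonds) < 0 || max(bonds) >= n))
    stop("bond atom index out of range [0, ", n, ")")
  b1 <- matrix(as.integer(bonds) + 1L, ncol = 2)    # to 1-based rows
  adj <- .adjacencyFromBonds(b1, n)
  bondTab <- .bondsFromAdjacency(adj)
  imp <- enumerateImpropers(adj, atoms$type, params)
  new("MolecularSystem", atoms = atoms, adjacency = adj,
      bonds = bondTab, angles = enumerateAngles(adj),
      torsions = enumerateTorsions(adj),
      impropers = imp$terms, improperWarnings = imp$warnings,
      params = params)
}
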