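#' @import methods
NULL

## ---- ParameterSet ----------------------------------------------------------

.emptyVdw <- function() data.frame(type = character(), radius = numeric(),
                                   eps = numeric(), stringsAsFactors = FALSE)
.emptyBonds <- function() data.frame(t1 = character(), t2 = character(),
                                     kb = numeric(), l0 = numeric(),
                                     stringsAsFactors = FALSE)
.emptyAngles <- function() data.frame(t1 = character(), t2 = character(),
                                      t3 = character(), ka = numeric(),
                                      theta0 = numeric(),
                                      stringsAsFactors = FALSE)
.emptyTorsions <- function() {
  d <- data.frame(t1 = character(), t2 = character(), t3 = character(),
                  t4 = character(), stringsAsFactors = FALSE)
  for (i in 1:4) d[[paste0("a", i)]] <- numeric()
  for (i in 1:4) d[[paste0("kd", i)]] <- numeric()
  d$npaths <- numeric()
  d
}
.emptyImpropers <- function() data.frame(t1 = character(), t2 = character(),
                                         t3 = character(), t4 = character(),
                                         ki = numeric(), phase = numeric(),
                                         period = numeric(),
                                         stringsAsFactors = FALSE)

#' ParameterSet: AMBER force-field parameter tables
#'
#' Holds the van der Waals (per-type radius R in Angstrom and well depth
#' epsilon in kcal/mol), bond (kb kcal/mol/A^2, l0 A), angle
#' (ka kcal/mol/rad^2, theta0 degrees), torsion (four phase-offset /
#' magnitude slots, slot i belonging to periodicity i, plus a path count N)
#' and improper-torsion (magnitude ki, phase A degrees, period P; central
#' atom type third) tables, keyed by atom-type labels. Angles and phases are
#' stored in degrees exactly as they appear in parameter files; conversion
#' to radians happens once, at energy evaluation.
#'
#' Lookup of bonds, angles and torsions is symmetric under reversal of the
#' type sequence; improper lookup keeps the central (third) type fixed and
#' is insensitive to permutation of the other three.
#'
#' @slot vdw data.frame with columns type, radius, eps.
#' @slot bonds data.frame with columns t1, t2, kb, l0.
#' @slot angles data.frame with columns t1..t3, ka, theta0.
#' @slot torsions data.frame with columns t1..t4, a1..a4, kd1..kd4, npaths.
#' @slot impropers data.frame with columns t1..t4, ki, phase, period.
#' @slot chargeSource character note: where atomic charges come from.
#' @exportClass ParameterSet
setClass("ParameterSet",
         representation(vdw = "data.frame", bonds = "data.frame",
                        angles = "data.frame", torsions = "data.frame",
                        impropers = "data.frame", chargeSource = "character"),
         prototype(vdw = .emptyVdw(), bonds = .emptyBonds(),
                   angles = .emptyAngles(), torsions = .emptyTorsions(),
                   impropers = .emptyImpropers(), chargeSource = "none"))

setValidity("ParameterSet", function(object) {
  msgs <- character()
  v <- object@vdw
  if (nrow(v)) {
    if (any(!nzchar(v$type))) msgs <- c(msgs, "empty vdw type name")
    if (any(v$radius < 0)) msgs <- c(msgs, "negative vdw radius")
    if (any(v$eps < 0)) msgs <- c(msgs, "negative vdw well depth")
    if (anyDuplicated(v$type)) msgs <- c(msgs, "duplicate vdw type")
  }
  b <- object@bonds
  if (nrow(b)) {
    if (any(b$kb < 0)) msgs <- c(msgs, "negative bond force constant")
    if (any(b$l0 <= 0)) msgs <- c(msgs, "non-positive equilibrium length")
    if (anyDuplicated(.bondKey(b$t1, b$t2)))
      msgs <- c(msgs, "duplicate bond record after canonicalization")
  }
  a <- object@angles
  if (nrow(a)) {
    if (any(a$ka < 0)) msgs <- c(msgs, "negative angle force constant")
    if (any(a$theta0 <= 0 | a$theta0 > 180))
      msgs <- c(msgs, "equilibrium angle outside (0, 180] degrees")
    if (anyDuplicated(.angleKey(a$t1, a$t2, a$t3)))
      msgs <- c(msgs, "duplicate angle record after canonicalization")
  }
  t <- object@torsions
  if (nrow(t)) {
    if (any(t$npaths <= 0)) msgs <- c(msgs, "non-positive torsion path count")
    if (anyDuplicated(.torsionKey(t$t1, t$t2, t$t3, t$t4)))
      msgs <- c(msgs, "duplicate torsion record after canonicalization")
  }
  im <- object@impropers
  if (nrow(im)) {
    if (any(im$period <= 0)) msgs <- c(msgs, "non-positive improper period")
    if (anyDuplicated(.improperKey(im$t1, im$t2, im$t3, im$t4)))
      msgs <- c(msgs, "duplicate improper record after canonicalization")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- MolecularSystem -------------------------------------------------------

#' MolecularSystem: atoms, connectivity and bonded-term instances
#'
#' Atoms are 0-based indexed in all user-facing interfaces (matching AMBER
#' tooling conventions); internally rows of the atom table are 1-based. The
#' adjacency list is symmetric with no self loops. The term table holds one
#' instance per bond (i<j), angle (central atom second, i<k), proper torsion
#' (deduplicated under reversal) and improper torsion (central atom third).
#'
#' @slot atoms data.frame with columns type, charge (e), x, y, z (Angstrom;
#'   NA until coordinates are attached), resid, resname.
#' @slot adjacency list of integer vectors, 1-based neighbour rows.
#' @slot bonds,angles,torsions,impropers integer matrices of 1-based atom
#'   rows, one term per row.
#' @slot improperWarnings character: unparameterized improper centres.
#' @slot params ParameterSet.
#' @exportClass MolecularSystem
setClass("MolecularSystem",
         representation(atoms = "data.frame", adjacency = "list",
                        bonds = "matrix", angles = "matrix",
                        torsions = "matrix", impropers = "matrix",
                        improperWarnings = "character",
                        params = "ParameterSet"))

setValidity("MolecularSystem", function(object) {
  msgs <- character()
  n <- nrow(object@atoms)
  need <- c("type", "charge", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, "atom table must have type, charge, x, y, z")
  if (length(object@adjacency) != n)
    msgs <- c(msgs, "adjacency length != atom count")
  for (i in seq_len(n)) {
    nb <- object@adjacency[[i]]
    if (any(nb == i)) { msgs <- c(msgs, "self loop in adjacency"); break }
    if (any(nb < 1 | nb > n)) { msgs <- c(msgs, "adjacency out of range"); break }
    if (!all(vapply(nb, function(j) i %in% object@adjacency[[j]], logical(1)))) {
      msgs <- c(msgs, "adjacency not symmetric"); break
    }
  }
  if (nrow(object@bonds) && ncol(object@bonds) != 2)
    msgs <- c(msgs, "bond matrix must have 2 columns")
  if (nrow(object@angles) && ncol(object@angles) != 3)
    msgs <- c(msgs, "angle matrix must have 3 columns")
  if (nrow(object@torsions) && ncol(object@torsions) != 4)
    msgs <- c(msgs, "torsion matrix must have 4 columns")
  if (nrow(object@impropers) && ncol(object@impropers) != 4)
    msgs <- c(msgs, "improper matrix must have 4 columns")
  if (length(msgs)) msgs else TRUE
})

## ---- FragmentScheme --------------------------------------------------------

#' FragmentScheme: total assignment of atoms to fragment labels
#'
#' Every atom carries exactly one label. User selections must be disjoint;
#' atoms in no user selection fall into the reserved remainder fragment
#' \code{"X"}. Fragments that would be empty are dropped. Label order is the
#' user's order followed by \code{"X"}.
#'
#' @slot labels character, ordered fragment labels present in the scheme.
#' @slot assignment character of length nAtoms, label per atom (1-based row).
#' @exportClass FragmentScheme
setClass("FragmentScheme",
         representation(labels = "character", assignment = "character"))

setValidity("FragmentScheme", function(object) {
  msgs <- character()
  if (any(!object@assignment %in% object@labels))
    msgs <- c(msgs, "assignment uses a label not in labels")
  if (any(!object@labels %in% object@assignment))
    msgs <- c(msgs, "empty fragment retained in labels")
  if (anyDuplicated(object@labels)) msgs <- c(msgs, "duplicate labels")
  if (length(msgs)) msgs else TRUE
})

## ---- EnergyReport ----------------------------------------------------------

#' EnergyReport: per-class, per-bucket partitioned energies
#'
#' For each energy class (Bonds, Angles, Torsions, Out-of-Plane, VDW,
#' Coulomb) a named numeric vector maps bucket keys to kcal/mol. A bucket
#' key is the sorted set of fragment labels spanned by a term, joined with
#' \code{"+"}: one label is a fragment self-energy, two to four labels are
#' pair/triple/quadruple interaction terms. Buckets with no routed term are
#' omitted. The class totals and the grand total reconstruct the
#' unpartitioned energy exactly (to accumulation roundoff).
#'
#' @slot energies named list, one numeric vector per class.
#' @slot totals named numeric: the six class totals plus \code{Total}.
#' @slot fragments named list: label -> 0-based atom indexes.
#' @slot warnings character, improper-parameter warnings.
#' @slot metadata list (worker count, frame, paths, ...).
#' @exportClass EnergyReport
setClass("EnergyReport",
         representation(energies = "list", totals = "numeric",
                        fragments = "list", warnings = "character",
                        metadata = "list"))

setValidity("EnergyReport", function(object) {
  msgs <- character()
  if (!all(.TERM_CLASSES %in% names(object@energies)))
    msgs <- c(msgs, "energies must contain all six term classes")
  if (!all(c(.TERM_CLASSES, "Total") %in% names(object@totals)))
    msgs <- c(msgs, "totals must contain the six classes and Total")
  for (cl in intersect(.TERM_CLASSES, names(object@energies))) {
    e <- object@energies[[cl]]
    if (length(e) && is.null(names(e))) {
      msgs <- c(msgs, sprintf("class %s has unnamed buckets", cl))
      next
    }
    if (abs(sum(e) - object@totals[[cl]]) > 1e-9)
      msgs <- c(msgs, sprintf("class %s buckets do not sum to its total", cl))
  }
  if (length(msgs)) msgs else TRUE
})
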