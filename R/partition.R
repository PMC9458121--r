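## Fragment assignment and the routing of every energy term into its
## fragment self-energy or inter-fragment interaction bucket. Bucket keys
## are sorted sets of fragment labels joined with "+", so the 1-2 and 2-1
## interactions are one bucket. Sorting follows the scheme's label order
## (user order, then "X"), which also fixes the report ordering.

#' Reserved remainder fragment label
#' @return the string "X"
#' @export
remainderLabel <- function() "X"

#' Assign atoms to fragments
#'
#' Builds a total [FragmentScheme-class] from user selections. Atoms not in
#' any selection form the reserved remainder fragment `"X"`. Selections
#' must be disjoint; empty fragments (including an empty remainder) are
#' dropped. Fragment order is the order of `selections`, then `"X"`.
#'
#' @param selections named list: fragment label -> vector of 0-based atom
#'   indexes
#' @param nAtoms total atom count of the system
#' @return a [FragmentScheme-class]
#' @examples
#' sc <- assignFragments(list("0" = 1:10, "1" = 15:25), 30)
#' fragmentMembers(sc)$X
#' @export
assignFragments <- function(selections, nAtoms) {
  nAtoms <- as.integer(nAtoms)
  if (is.null(names(selections)) && length(selections))
    stop("selections must be a named list of atom-index sets")
  labels <- names(selections)
  if (anyDuplicated(labels)) stop("duplicate fragment labels")
  if (remainderLabel() %in% labels)
    stop("fragment label \"X\" is reserved for the remainder fragment")
  assignment <- rep(NA_character_, nAtoms)
  for (lab in labels) {
    idx <- sort(unique(as.integer(selections[[lab]])))
    if (length(idx) && (min(idx) < 0 || max(idx) >= nAtoms))
      stop(sprintf("fragment %s: atom index out of range [0, %d)", lab, nAtoms))
    taken <- !is.na(assignment[idx + 1L])
    if (any(taken)) {
      clash <- idx[taken][1]
      stop(sprintf("atom %d appears in fragments %s and %s",
                   clash, assignment[clash + 1L], lab))
    }
    assignment[idx + 1L] <- lab
  }
  assignment[is.na(assignment)] <- remainderLabel()
  present <- labels[labels %in% assignment]
  if (remainderLabel() %in% assignment)
    present <- c(present, remainderLabel())
  new("FragmentScheme", labels = present, assignment = assignment)
}

#' Interaction bucket of a set of atoms
#'
#' The bucket key is the set of distinct fragment labels among the
#' participating atoms, sorted in scheme label order and joined with "+".
#' One label is a fragment self-energy; two to four labels are the
#' pair/triple/quadruple interaction buckets.
#'
#' @param atomIndexes 0-based atom indexes of one term
#' @param scheme a [FragmentScheme-class]
#' @return bucket key string, e.g. `"0"` or `"0+1+X"`
#' @export
bucketFor <- function(atomIndexes, scheme) {
  stopifnot(is(scheme, "FragmentScheme"))
  labs <- unique(scheme@assignment[as.integer(atomIndexes) + 1L])
  paste(labs[order(match(labs, scheme@labels))], collapse = "+")
}

## vectorized bucket keys for a matrix of term atom rows (1-based)
.bucketKeys <- function(atomRows, scheme) {
  if (!nrow(atomRows)) return(character())
  ord <- match(scheme@assignment, scheme@labels)
  lab <- matrix(ord[atomRows], nrow = nrow(atomRows))
  apply(lab, 1L, function(v) {
    v <- sort(unique(v))
    paste(scheme@labels[v], collapse = "+")
  })
}

#' Fragment-partitioned AMBER energy
#'
#' Evaluates every term instance and every nonbonded pair exactly once and
#' routes its energy into the bucket of the fragment labels its atoms span.
#' The bucket sums of each class reconstruct the class totals of
#' [totalEnergy()], and the grand sum reconstructs the system energy, to
#' accumulation roundoff; empty buckets are omitted. Improper-parameter
#' warnings are carried into the report.
#'
#' @param system a [MolecularSystem-class] with coordinates attached
#' @param scheme a [FragmentScheme-class] covering the system's atoms
#' @return an [EnergyReport-class]
#' @export
partitionedEnergy <- function(system, scheme) {
  stopifnot(is(system, "MolecularSystem"), is(scheme, "FragmentScheme"))
  if (length(scheme@assignment) != nrow(system@atoms))
    stop("fragment scheme covers ", length(scheme@assignment),
         " atoms but the system has ", nrow(system@atoms))
  ev <- .evaluateTerms(system)
  route <- function(part) {
    keys <- .bucketKeys(part$atoms, scheme)
    if (!length(keys)) return(setNames(numeric(), character()))
    sums <- tapply(part$energy, keys, sum)
    out <- as.numeric(sums); names(out) <- names(sums)
    out[.orderBuckets(names(out), scheme)]
  }
  energies <- list(Bonds = route(ev$bonds), Angles = route(ev$angles),
                   Torsions = route(ev$torsions),
                   "Out-of-Plane" = route(ev$impropers),
                   VDW = route(ev$vdw), Coulomb = route(ev$coulomb))
  totals <- vapply(energies, sum, numeric(1))
  names(totals) <- names(energies)
  totals <- c(totals, Total = sum(totals))
  new("EnergyReport", energies = energies, totals = totals,
      fragments = fragmentMembers(scheme), warnings = ev$warnings,
      metadata = list(nAtoms = nrow(system@atoms), workers = 1L))
}

## deterministic bucket ordering: by bucket size, then scheme label order
.orderBuckets <- function(keys, scheme) {
  parts <- strsplit(keys, "+", fixed = TRUE)
  size <- lengths(parts)
  rank <- vapply(parts, function(p) {
    idx <- match(p, scheme@labels)
    sum(idx * (length(scheme@labels) + 1)^rev(seq_along(idx) - 1))
  }, numeric(1))
  order(size, rank)
}

#' Bucket-wise difference of two energy reports
#'
#' Computes per-class, per-bucket differences `b - a` between two reports
#' sharing the same fragment labels, e.g. between two conformations of one
#' system to locate which fragments drive an energy change. Buckets absent
#' from one report are treated as zero there.
#'
#' @param a,b [EnergyReport-class] objects with identical fragment labels
#' @return named list per term class (plus `Total`) of named numeric
#'   bucket differences in kcal/mol
#' @export
deltaReport <- function(a, b) {
  stopifnot(is(a, "EnergyReport"), is(b, "EnergyReport"))
  la <- names(a@fragments); lb <- names(b@fragments)
  if (!identical(sort(la), sort(lb)))
    stop("fragment labels differ between reports: ",
         paste(setdiff(union(la, lb), intersect(la, lb)), collapse = ", "))
  out <- lapply(.TERM_CLASSES, function(cl) {
    ea <- a@energies[[cl]]; eb <- b@energies[[cl]]
    keys <- union(names(eb), names(ea))
    d <- setNames(numeric(length(keys)), keys)
    d[names(eb)] <- eb
    d[names(ea)] <- d[names(ea)] - ea
    d
  })
  names(out) <- .TERM_CLASSES
  out$Total <- b@totals[["Total"]] - a@totals[["Total"]]
  out
}
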