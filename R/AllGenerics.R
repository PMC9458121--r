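#' Number of atoms in a system
#' @param x a MolecularSystem
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' Atom table of a system
#'
#' @param x a MolecularSystem
#' @return data.frame with one row per atom (columns type, charge, x, y, z,
#'   resid, resname) and an `index` column of 0-based atom indexes.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "MolecularSystem", function(x) {
  cbind(index = seq_len(nrow(x@atoms)) - 1L, x@atoms)
})

#' Force-field parameters attached to an object
#' @param x a MolecularSystem
#' @return ParameterSet
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' @rdname parameters
#' @export
setMethod("parameters", "MolecularSystem", function(x) x@params)

#' Atom coordinates
#' @param x a MolecularSystem
#' @return numeric matrix n x 3 (Angstrom), NA where unset
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname coordinates
#' @export
setMethod("coordinates", "MolecularSystem", function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})

#' Replace atom coordinates
#' @param x a MolecularSystem
#' @param value numeric n x 3 matrix in Angstrom
#' @return the modified system
#' @export
setGeneric("coordinates<-", function(x, value) standardGeneric("coordinates<-"))

#' @rdname coordinates-set
#' @export
setMethod("coordinates<-", "MolecularSystem", function(x, value) {
  value <- as.matrix(value)
  if (!all(dim(value) == c(nrow(x@atoms), 3L)))
    stop("coordinates must be a ", nrow(x@atoms), " x 3 matrix")
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' Fragment labels of a scheme or report
#' @param x a FragmentScheme or EnergyReport
#' @return character vector of labels in presentation order
#' @export
setGeneric("fragmentLabels", function(x) standardGeneric("fragmentLabels"))

#' @rdname fragmentLabels
#' @export
setMethod("fragmentLabels", "FragmentScheme", function(x) x@labels)

#' @rdname fragmentLabels
#' @export
setMethod("fragmentLabels", "EnergyReport", function(x) names(x@fragments))

#' Atom membership of a fragment scheme
#' @param x a FragmentScheme
#' @return named list: label -> sorted 0-based atom indexes
#' @export
setGeneric("fragmentMembers", function(x) standardGeneric("fragmentMembers"))

#' @rdname fragmentMembers
#' @export
setMethod("fragmentMembers", "FragmentScheme", function(x) {
  out <- lapply(x@labels, function(l) which(x@assignment == l) - 1L)
  names(out) <- x@labels
  out
})

#' Per-bucket energies of one term class
#' @param x an EnergyReport
#' @param class one of "Bonds", "Angles", "Torsions", "Out-of-Plane",
#'   "VDW", "Coulomb"
#' @return named numeric vector, bucket key -> kcal/mol
#' @export
setGeneric("bucketEnergies", function(x, class) standardGeneric("bucketEnergies"))

#' @rdname bucketEnergies
#' @export
setMethod("bucketEnergies", "EnergyReport", function(x, class) {
  class <- match.arg(class, .TERM_CLASSES)
  x@energies[[class]]
})

#' Class totals and grand total of a report
#' @param x an EnergyReport
#' @return named numeric: six class totals plus Total, kcal/mol
#' @export
setGeneric("reportTotals", function(x) standardGeneric("reportTotals"))

#' @rdname reportTotals
#' @export
setMethod("reportTotals", "EnergyReport", function(x) x@totals)

#' Warnings accumulated during a calculation
#' @param x an EnergyReport or MolecularSystem
#' @return character vector (possibly empty)
#' @export
setGeneric("calculationWarnings",
           function(x) standardGeneric("calculationWarnings"))

#' @rdname calculationWarnings
#' @export
setMethod("calculationWarnings", "EnergyReport", function(x) x@warnings)

#' @rdname calculationWarnings
#' @export
setMethod("calculationWarnings", "MolecularSystem",
          function(x) x@improperWarnings)

## ---- show methods ----------------------------------------------------------

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet\n")
  cat(sprintf("  vdw types: %d | bonds: %d | angles: %d | torsions: %d | impropers: %d\n",
              nrow(object@vdw), nrow(object@bonds), nrow(object@angles),
              nrow(object@torsions), nrow(object@impropers)))
  cat("  charge source:", object@chargeSource, "\n")
})

setMethod("show", "MolecularSystem", function(object) {
  hasPos <- !anyNA(object@atoms$x)
  cat("MolecularSystem\n")
  cat(sprintf("  atoms: %d (%s) | bonds: %d | angles: %d | torsions: %d | impropers: %d\n",
              nrow(object@atoms),
              if (hasPos) "positions set" else "positions unset",
              nrow(object@bonds), nrow(object@angles),
              nrow(object@torsions), nrow(object@impropers)))
  if (length(object@improperWarnings))
    cat("  improper warnings:", length(object@improperWarnings), "\n")
})

setMethod("show", "FragmentScheme", function(object) {
  cat("FragmentScheme of", length(object@assignment), "atoms\n")
  mem <- fragmentMembers(object)
  for (l in object@labels)
    cat(sprintf("  Fragment %s: %d atoms\n", l, length(mem[[l]])))
})

setMethod("show", "EnergyReport", function(object) {
  cat("EnergyReport |", length(object@fragments), "fragments\n")
  for (cl in .TERM_CLASSES)
    cat(sprintf("  %-12s %16.6f kcal/mol (%d buckets)\n", cl,
                object@totals[[cl]], length(object@energies[[cl]])))
  cat(sprintf("  %-12s %16.6f kcal/mol\n", "Total", object@totals[["Total"]]))
  if (length(object@warnings))
    cat("  warnings:", length(object@warnings), "\n")
})
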