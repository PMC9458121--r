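## Canonical keys: bond/angle/torsion lookups are symmetric under reversal
## of the type sequence; impropers keep the central (third) type fixed and
## sort the peripheral three.

.bondKey <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = "|")
}

.angleKey <- function(t1, t2, t3) {
  ifelse(t1 <= t3, paste(t1, t2, t3, sep = "|"), paste(t3, t2, t1, sep = "|"))
}

.torsionKey <- function(t1, t2, t3, t4) {
  fwd <- paste(t1, t2, t3, t4, sep = "|")
  rev <- paste(t4, t3, t2, t1, sep = "|")
  ifelse(fwd <= rev, fwd, rev)
}

.improperKey <- function(t1, t2, t3, t4) {
  vapply(seq_along(t1), function(i) {
    per <- sort(c(t1[i], t2[i], t4[i]))
    paste(per[1], per[2], t3[i], per[3], sep = "|")
  }, character(1))
}

#' Construct a ParameterSet
#'
#' Low-level constructor assembling a [ParameterSet-class] from its tables.
#' Most users obtain one from [parseGaussianParams()] or [paramsFromPrmtop()].
#'
#' @param vdw data.frame(type, radius, eps)
#' @param bonds data.frame(t1, t2, kb, l0)
#' @param angles data.frame(t1, t2, t3, ka, theta0) (theta0 in degrees)
#' @param torsions data.frame(t1..t4, a1..a4, kd1..kd4, npaths)
#'   (phases in degrees, magnitudes kcal/mol, slot i = periodicity i)
#' @param impropers data.frame(t1..t4, ki, phase, period) (central type third)
#' @param chargeSource character note on charge provenance
#' @return a ParameterSet
#' @export
ParameterSet <- function(vdw = .emptyVdw(), bonds = .emptyBonds(),
                         angles = .emptyAngles(), torsions = .emptyTorsions(),
                         impropers = .emptyImpropers(),
                         chargeSource = "none") {
  fix <- function(d, proto) {
    if (!nrow(d)) return(proto)
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    rownames(d) <- NULL
    d[names(proto)]
  }
  new("ParameterSet",
      vdw = fix(vdw, .emptyVdw()), bonds = fix(bonds, .emptyBonds()),
      angles = fix(angles, .emptyAngles()),
      torsions = fix(torsions, .emptyTorsions()),
      impropers = fix(impropers, .emptyImpropers()),
      chargeSource = chargeSource)
}

.parseNum <- function(tok, lineno, line) {
  x <- suppressWarnings(as.numeric(tok))
  if (anyNA(x))
    stop(sprintf("line %d: non-numeric field in parameter record: '%s'",
                 lineno, line), call. = FALSE)
  x
}

.badFields <- function(lineno, line, want) {
  stop(sprintf("line %d: expected %s fields: '%s'", lineno, want, line),
       call. = FALSE)
}

#' Parse a Gaussian-style MM parameter block
#'
#' Reads whitespace-delimited records of the five kinds used in Gaussian
#' AMBER inputs: `VDW type R eps`, `HrmStr1 t1 t2 kb l0`,
#' `HrmBnd1 t1 t2 t3 ka theta0`,
#' `AmbTrs t1 t2 t3 t4 A1 A2 A3 A4 kd1 kd2 kd3 kd4 N` and
#' `ImpTrs t1 t2 t3 t4 ki A P`. Units are preserved as printed (Angstrom,
#' kcal/mol, degrees). Blank lines are ignored; any other leading keyword
#' is an error.
#'
#' @param text character: a single multi-line string or a vector of lines.
#' @return a [ParameterSet-class]
#' @examples
#' p <- parseGaussianParams("VDW HP 1.1000 0.0157")
#' @export
parseGaussianParams <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  vdw <- list(); bonds <- list(); angles <- list()
  torsions <- list(); impropers <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    kw <- tok[1]
    if (kw == "VDW") {
      if (length(tok) != 4) .badFields(ln, line, "VDW type R eps (4)")
      vdw[[length(vdw) + 1]] <- data.frame(
        type = tok[2], radius = .parseNum(tok[3], ln, line),
        eps = .parseNum(tok[4], ln, line), stringsAsFactors = FALSE)
    } else if (kw == "HrmStr1") {
      if (length(tok) != 5) .badFields(ln, line, "HrmStr1 t1 t2 kb l0 (5)")
      bonds[[length(bonds) + 1]] <- data.frame(
        t1 = tok[2], t2 = tok[3], kb = .parseNum(tok[4], ln, line),
        l0 = .parseNum(tok[5], ln, line), stringsAsFactors = FALSE)
    } else if (kw == "HrmBnd1") {
      if (length(tok) != 6) .badFields(ln, line, "HrmBnd1 t1 t2 t3 ka theta0 (6)")
      angles[[length(angles) + 1]] <- data.frame(
        t1 = tok[2], t2 = tok[3], t3 = tok[4],
        ka = .parseNum(tok[5], ln, line),
        theta0 = .parseNum(tok[6], ln, line), stringsAsFactors = FALSE)
    } else if (kw == "AmbTrs") {
      if (length(tok) != 14)
        .badFields(ln, line, "AmbTrs t1..t4 A1..A4 kd1..kd4 N (14)")
      vals <- .parseNum(tok[6:14], ln, line)
      d <- data.frame(t1 = tok[2], t2 = tok[3], t3 = tok[4], t4 = tok[5],
                      stringsAsFactors = FALSE)
      d[paste0("a", 1:4)] <- as.list(vals[1:4])
      d[paste0("kd", 1:4)] <- as.list(vals[5:8])
      d$npaths <- vals[9]
      torsions[[length(torsions) + 1]] <- d
    } else if (kw == "ImpTrs") {
      if (length(tok) != 8) .badFields(ln, line, "ImpTrs t1..t4 ki A P (8)")
      impropers[[length(impropers) + 1]] <- data.frame(
        t1 = tok[2], t2 = tok[3], t3 = tok[4], t4 = tok[5],
        ki = .parseNum(tok[6], ln, line),
        phase = .parseNum(tok[7], ln, line),
        period = .parseNum(tok[8], ln, line), stringsAsFactors = FALSE)
    } else {
      stop(sprintf("line %d: unknown parameter record keyword '%s'", ln, kw),
           call. = FALSE)
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  ParameterSet(vdw = bind(vdw, .emptyVdw()),
               bonds = bind(bonds, .emptyBonds()),
               angles = bind(angles, .emptyAngles()),
               torsions = bind(torsions, .emptyTorsions()),
               impropers = bind(impropers, .emptyImpropers()),
               chargeSource = "external")
}

## fixed-point with 4 decimals when exact at that precision (the convention
## of printed parameter tables), full precision otherwise so that
## write -> parse round-trips are lossless
.fmtParamNum <- function(x) {
  vapply(x, function(v) {
    r <- round(v, 4)
    if (isTRUE(all.equal(v, r, tolerance = 0)) || abs(v - r) < 1e-13)
      sprintf("%.4f", v)
    else sprintf("%.17g", v)
  }, character(1))
}

#' Write a ParameterSet as a Gaussian-style MM parameter block
#'
#' Inverse of [parseGaussianParams()]: the output re-parses to an equal
#' ParameterSet. Records are emitted in a deterministic order (VDW,
#' HrmStr1, HrmBnd1, AmbTrs, ImpTrs; each sorted by type labels).
#'
#' @param params a [ParameterSet-class]
#' @param file optional path; when given the block is also written there.
#' @return character vector of record lines, invisibly when `file` is given.
#' @export
writeGaussianParams <- function(params, file = NULL) {
  stopifnot(is(params, "ParameterSet"))
  out <- character()
  v <- params@vdw
  if (nrow(v)) {
    v <- v[order(v$type), , drop = FALSE]
    out <- c(out, sprintf("VDW %s %s %s", v$type,
                          .fmtParamNum(v$radius), .fmtParamNum(v$eps)))
  }
  b <- params@bonds
  if (nrow(b)) {
    b <- b[order(b$t1, b$t2), , drop = FALSE]
    out <- c(out, sprintf("HrmStr1 %s %s %s %s", b$t1, b$t2,
                          .fmtParamNum(b$kb), .fmtParamNum(b$l0)))
  }
  a <- params@angles
  if (nrow(a)) {
    a <- a[order(a$t1, a$t2, a$t3), , drop = FALSE]
    out <- c(out, sprintf("HrmBnd1 %s %s %s %s %s", a$t1, a$t2, a$t3,
                          .fmtParamNum(a$ka), .fmtParamNum(a$theta0)))
  }
  t <- params@torsions
  if (nrow(t)) {
    t <- t[order(t$t1, t$t2, t$t3, t$t4), , drop = FALSE]
    out <- c(out, sprintf("AmbTrs %s %s %s %s %s %s %s %s %s %s %s %s %s",
                          t$t1, t$t2, t$t3, t$t4,
                          .fmtParamNum(t$a1), .fmtParamNum(t$a2),
                          .fmtParamNum(t$a3), .fmtParamNum(t$a4),
                          .fmtParamNum(t$kd1), .fmtParamNum(t$kd2),
                          .fmtParamNum(t$kd3), .fmtParamNum(t$kd4),
                          .fmtParamNum(t$npaths)))
  }
  im <- params@impropers
  if (nrow(im)) {
    im <- im[order(im$t1, im$t2, im$t3, im$t4), , drop = FALSE]
    out <- c(out, sprintf("ImpTrs %s %s %s %s %s %s %s", im$t1, im$t2,
                          im$t3, im$t4, .fmtParamNum(im$ki),
                          .fmtParamNum(im$phase), .fmtParamNum(im$period)))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Look up a bonded parameter record
#'
#' Bond, angle and torsion lookups succeed for either orientation of the
#' label sequence. Improper lookup keeps the central atom type (third
#' position) fixed but is insensitive to permutation of the other three.
#' A missing record is a normal `NULL` return, not an error.
#'
#' @param params a [ParameterSet-class]
#' @param kind one of "bond", "angle", "torsion", "improper"
#' @param types character vector of atom-type labels (2, 3 or 4 depending
#'   on `kind`)
#' @return a one-row data.frame of the matching record, or `NULL`
#' @examples
#' p <- parseGaussianParams("HrmStr1 CT HC 340.00 1.0900")
#' lookupBonded(p, "bond", c("HC", "CT"))$kb
#' @export
lookupBonded <- function(params, kind = c("bond", "angle", "torsion",
                                          "improper"), types) {
  stopifnot(is(params, "ParameterSet"))
  kind <- match.arg(kind)
  nwant <- c(bond = 2L, angle = 3L, torsion = 4L, improper = 4L)[[kind]]
  if (length(types) != nwant)
    stop(sprintf("%s lookup needs %d type labels, got %d", kind, nwant,
                 length(types)))
  tab <- slot(params, c(bond = "bonds", angle = "angles",
                        torsion = "torsions", improper = "impropers")[[kind]])
  if (!nrow(tab)) return(NULL)
  key <- switch(kind,
                bond = .bondKey(types[1], types[2]),
                angle = .angleKey(types[1], types[2], types[3]),
                torsion = .torsionKey(types[1], types[2], types[3], types[4]),
                improper = .improperKey(types[1], types[2], types[3], types[4]))
  keys <- switch(kind,
                 bond = .bondKey(tab$t1, tab$t2),
                 angle = .angleKey(tab$t1, tab$t2, tab$t3),
                 torsion = .torsionKey(tab$t1, tab$t2, tab$t3, tab$t4),
                 improper = .improperKey(tab$t1, tab$t2, tab$t3, tab$t4))
  hit <- match(key, keys)
  if (is.na(hit)) NULL else tab[hit, , drop = FALSE]
}

#' Lennard-Jones pair coefficients by Lorentz-Berthelot combination
#'
#' Combines two per-type records into pair coefficients:
#' eps_ij = sqrt(eps_i eps_j), D_ij = R_i + R_j, A_ij = eps_ij D_ij^12,
#' B_ij = 2 eps_ij D_ij^6. Symmetric in its two type arguments; a zero-eps
#' type annihilates the pair (A = B = 0).
#'
#' @param params a [ParameterSet-class]
#' @param typeA,typeB atom-type labels present in the vdw table
#' @return list with a (kcal A^12/mol), b (kcal A^6/mol), eps (kcal/mol),
#'   d (A)
#' @examples
#' p <- parseGaussianParams("VDW HP 1.1000 0.0157")
#' combineLJ(p, "HP", "HP")$eps
#' @export
combineLJ <- function(params, typeA, typeB) {
  stopifnot(is(params, "ParameterSet"))
  v <- params@vdw
  ia <- match(typeA, v$type); ib <- match(typeB, v$type)
  if (is.na(ia)) stop("unknown vdw type: ", typeA)
  if (is.na(ib)) stop("unknown vdw type: ", typeB)
  eps <- sqrt(v$eps[ia] * v$eps[ib])
  d <- v$radius[ia] + v$radius[ib]
  list(a = eps * d^12, b = 2 * eps * d^6, eps = eps, d = d)
}

#' Reference MM parameter records
#'
#' The small Gaussian-style parameter block shipped with the package
#' (one record of each kind for common AMBER atom types), used as the
#' default parameter palette of the fixture generator and in examples.
#'
#' @return character vector of parameter record lines
#' @export
referenceParamBlock <- function() {
  readLines(system.file("extdata", "reference_params.txt",
                        package = "amberDecomp"))
}
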