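## AMBER PRMTOP/PARM7 sectioned ASCII format. No installed R package reads
## it, so parsing is done here: %VERSION header, then %FLAG NAME /
## %FORMAT(spec) / data blocks. Numeric sections are whitespace-delimited;
## a-format sections (atom/residue names, types) are fixed-width.

.POINTER_NAMES <- c("NATOM", "NTYPES", "NBONH", "MBONA", "NTHETH", "MTHETA",
                    "NPHIH", "MPHIA", "NHPARM", "NPARM", "NNB", "NRES",
                    "NBONA", "NTHETA", "NPHIA", "NUMBND", "NUMANG", "NPTRA",
                    "NATYP", "NPHB", "IFPERT", "NBPER", "NGPER", "NDPER",
                    "MBPER", "MGPER", "MDPER", "IFBOX", "NMXRS", "IFCAP",
                    "NUMEXTRA")

#' Read the raw sections of a PRMTOP/PARM7 file
#'
#' Parses the %FLAG-sectioned ASCII topology into a named list, one
#' element per section: numeric vectors for I/E/F formats, character
#' vectors (fixed-width, trimmed) for a formats. The POINTERS section
#' additionally gets pointer names.
#'
#' @param path file path
#' @return named list of sections, with attribute `formats`
#' @export
readPrmtop <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  flagAt <- grep("^%FLAG", lines)
  if (!length(flagAt))
    stop("not a PRMTOP file (no %FLAG sections): ", path)
  sections <- list(); formats <- character()
  bounds <- c(flagAt, length(lines) + 1L)
  for (k in seq_along(flagAt)) {
    name <- trimws(sub("^%FLAG", "", lines[flagAt[k]]))
    body <- lines[seq(flagAt[k] + 1L, bounds[k + 1L] - 1L)]
    fmtLine <- grep("^%FORMAT", body, value = TRUE)
    if (!length(fmtLine))
      stop("PRMTOP section ", name, " has no %FORMAT line")
    fmt <- sub("^%FORMAT\\((.*)\\).*$", "\\1", fmtLine[1])
    data <- body[!grepl("^%", body)]
    if (grepl("a", fmt, ignore.case = TRUE)) {
      width <- as.integer(sub("^[0-9]*[aA]([0-9]+).*$", "\\1", fmt))
      vals <- unlist(lapply(data, function(l) {
        if (!nzchar(l)) return(character())
        starts <- seq(1L, nchar(l), by = width)
        trimws(substring(l, starts, pmin(starts + width - 1L, nchar(l))))
      }))
      vals <- vals[nzchar(vals)]
    } else {
      toks <- unlist(strsplit(trimws(data[nzchar(trimws(data))]), "[[:space:]]+"))
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals))
        stop("PRMTOP section ", name, ": non-numeric field")
    }
    sections[[name]] <- vals
    formats[[name]] <- fmt
  }
  if (!is.null(sections$POINTERS)) {
    p <- sections$POINTERS
    names(p) <- .POINTER_NAMES[seq_along(p)]
    sections$POINTERS <- p
  }
  attr(sections, "formats") <- formats
  sections
}

.needSection <- function(prmtop, name) {
  if (is.null(prmtop[[name]]))
    stop("PRMTOP is missing mandatory section ", name)
  prmtop[[name]]
}

#' Build a ParameterSet from parsed PRMTOP content
#'
#' Per-type van der Waals radii and well depths are recovered from the
#' diagonal Lennard-Jones coefficients by inverting the A/B definitions
#' (eps = B^2/(4A), D = (2A/B)^(1/6), R = D/2); a type whose diagonal has
#' exactly one of A, B zero gets R = eps = 0 with a warning (as does an
#' all-zero row, silently typical of lone-pair-like types). Bond, angle
#' and torsion tables are keyed by atom-type labels via the bonded-term
#' instance lists; torsion records of one type quadruple with distinct
#' periodicities merge into the four slots of one record. Equilibrium
#' angles and phases are converted from the file's radians to degrees.
#' Duplicate records for the same key and periodicity with different
#' values keep the first occurrence and warn.
#'
#' @param prmtop parsed content from [readPrmtop()]
#' @return a [ParameterSet-class]
#' @export
paramsFromPrmtop <- function(prmtop) {
  ptr <- .needSection(prmtop, "POINTERS")
  natom <- ptr[["NATOM"]]; ntypes <- ptr[["NTYPES"]]
  types <- .needSection(prmtop, "AMBER_ATOM_TYPE")
  tidx <- .needSection(prmtop, "ATOM_TYPE_INDEX")
  ico <- .needSection(prmtop, "NONBONDED_PARM_INDEX")
  acoef <- .needSection(prmtop, "LENNARD_JONES_ACOEF")
  bcoef <- .needSection(prmtop, "LENNARD_JONES_BCOEF")
  if (length(types) != natom || length(tidx) != natom)
    stop("PRMTOP pointer NATOM inconsistent with atom-type sections")

  ## one vdw record per distinct atom-type label
  uniq <- !duplicated(types)
  vdw <- data.frame(type = types[uniq], radius = NA_real_, eps = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(vdw))) {
    t <- tidx[match(vdw$type[r], types)]
    k <- ico[ntypes * (t - 1) + t]
    A <- acoef[k]; B <- bcoef[k]
    if (A > 0 && B > 0) {
      vdw$eps[r] <- B^2 / (4 * A)
      vdw$radius[r] <- (2 * A / B)^(1 / 6) / 2
    } else {
      if (xor(A == 0, B == 0))
        warning("type ", vdw$type[r],
                ": inconsistent Lennard-Jones diagonal (one of A, B zero); ",
                "setting R = eps = 0")
      vdw$eps[r] <- 0; vdw$radius[r] <- 0
    }
  }

  dedupe <- function(df, keys, what) {
    if (!nrow(df)) return(df)
    first <- !duplicated(keys)
    if (any(!first)) {
      dup <- which(!first)
      for (d in dup) {
        orig <- which(keys == keys[d])[1]
        if (!isTRUE(all.equal(as.numeric(df[d, sapply(df, is.numeric)]),
                              as.numeric(df[orig, sapply(df, is.numeric)]))))
          warning("conflicting duplicate ", what, " record for ", keys[d],
                  "; keeping first")
      }
    }
    df[first, , drop = FALSE]
  }

  ## bonds
  bi <- c(.needSection(prmtop, "BONDS_INC_HYDROGEN"),
          .needSection(prmtop, "BONDS_WITHOUT_HYDROGEN"))
  bonds <- .emptyBonds()
  if (length(bi)) {
    m <- matrix(bi, ncol = 3, byrow = TRUE)
    kb <- .needSection(prmtop, "BOND_FORCE_CONSTANT")
    l0 <- .needSection(prmtop, "BOND_EQUIL_VALUE")
    i <- abs(m[, 1]) / 3 + 1; j <- abs(m[, 2]) / 3 + 1
    bonds <- data.frame(t1 = types[i], t2 = types[j],
                        kb = kb[m[, 3]], l0 = l0[m[, 3]],
                        stringsAsFactors = FALSE)
    bonds <- dedupe(bonds, .bondKey(bonds$t1, bonds$t2), "bond")
  }

  ## angles
  ai <- c(if (!is.null(prmtop$ANGLES_INC_HYDROGEN)) prmtop$ANGLES_INC_HYDROGEN,
          if (!is.null(prmtop$ANGLES_WITHOUT_HYDROGEN)) prmtop$ANGLES_WITHOUT_HYDROGEN)
  angles <- .emptyAngles()
  if (length(ai)) {
    m <- matrix(ai, ncol = 4, byrow = TRUE)
    ka <- .needSection(prmtop, "ANGLE_FORCE_CONSTANT")
    th <- .needSection(prmtop, "ANGLE_EQUIL_VALUE")
    i <- abs(m[, 1]) / 3 + 1; j <- abs(m[, 2]) / 3 + 1; k <- abs(m[, 3]) / 3 + 1
    angles <- data.frame(t1 = types[i], t2 = types[j], t3 = types[k],
                         ka = ka[m[, 4]], theta0 = th[m[, 4]] * 180 / pi,
                         stringsAsFactors = FALSE)
    angles <- dedupe(angles, .angleKey(angles$t1, angles$t2, angles$t3),
                     "angle")
  }

  ## dihedrals: negative 4th index marks an improper; negative 3rd marks a
  ## suppressed 1-4 (multi-term/ring) - irrelevant here since exclusions are
  ## derived from connectivity
  di <- c(if (!is.null(prmtop$DIHEDRALS_INC_HYDROGEN)) prmtop$DIHEDRALS_INC_HYDROGEN,
          if (!is.null(prmtop$DIHEDRALS_WITHOUT_HYDROGEN)) prmtop$DIHEDRALS_WITHOUT_HYDROGEN)
  torsions <- .emptyTorsions(); impropers <- .emptyImpropers()
  if (length(di)) {
    m <- matrix(di, ncol = 5, byrow = TRUE)
    pk <- .needSection(prmtop, "DIHEDRAL_FORCE_CONSTANT")
    pn <- .needSection(prmtop, "DIHEDRAL_PERIODICITY")
    ph <- .needSection(prmtop, "DIHEDRAL_PHASE")
    isImp <- m[, 4] < 0
    idx <- function(col) abs(m[, col]) / 3 + 1
    i <- idx(1); j <- idx(2); k <- idx(3); l <- idx(4)
    if (any(isImp)) {
      t5 <- m[isImp, 5]
      impropers <- data.frame(t1 = types[i[isImp]], t2 = types[j[isImp]],
                              t3 = types[k[isImp]], t4 = types[l[isImp]],
                              ki = pk[t5], phase = ph[t5] * 180 / pi,
                              period = pn[t5], stringsAsFactors = FALSE)
      impropers <- dedupe(impropers, .improperKey(impropers$t1, impropers$t2,
                                                  impropers$t3, impropers$t4),
                          "improper")
    }
    if (any(!isImp)) {
      pr <- which(!isImp)
      key <- .torsionKey(types[i[pr]], types[j[pr]], types[k[pr]], types[l[pr]])
      torsions <- .emptyTorsions()
      slotSeen <- list()
      for (q in seq_along(pr)) {
        t5 <- m[pr[q], 5]
        per <- as.integer(round(pn[t5]))
        if (per < 1 || per > 4) {
          warning("torsion periodicity ", pn[t5],
                  " outside slots 1-4; record skipped")
          next
        }
        row <- match(key[q], rownames(torsions))
        if (is.na(row)) {
          newRow <- data.frame(t1 = types[i[pr[q]]], t2 = types[j[pr[q]]],
                               t3 = types[k[pr[q]]], t4 = types[l[pr[q]]],
                               a1 = 0, a2 = 0, a3 = 0, a4 = 0,
                               kd1 = 0, kd2 = 0, kd3 = 0, kd4 = 0,
                               npaths = 1, stringsAsFactors = FALSE)
          torsions <- rbind(torsions, newRow)
          rownames(torsions)[nrow(torsions)] <- key[q]
          row <- nrow(torsions)
          slotSeen[[key[q]]] <- integer()
        }
        if (per %in% slotSeen[[key[q]]]) {
          if (!isTRUE(all.equal(c(torsions[row, paste0("kd", per)],
                                  torsions[row, paste0("a", per)]),
                                c(pk[t5], ph[t5] * 180 / pi),
                                check.attributes = FALSE)))
            warning("conflicting duplicate torsion record for ", key[q],
                    " periodicity ", per, "; keeping first")
          next
        }
        slotSeen[[key[q]]] <- c(slotSeen[[key[q]]], per)
        torsions[row, paste0("kd", per)] <- pk[t5]
        torsions[row, paste0("a", per)] <- ph[t5] * 180 / pi
      }
      rownames(torsions) <- NULL
    }
  }

  ParameterSet(vdw = vdw, bonds = bonds, angles = angles,
               torsions = torsions, impropers = impropers,
               chargeSource = "prmtop")
}

#' Read a PRMTOP topology into a MolecularSystem
#'
#' Atoms (type labels, charges converted from the file's premultiplied
#' units to elementary charges), covalent connectivity from both bond
#' sections (coordinate-style indices divided by 3, 0-based), residue
#' metadata, and a [ParameterSet-class] extracted with
#' [paramsFromPrmtop()]. Positions are unset; attach them with
#' [readCoordinates()].
#'
#' @param path PRMTOP/PARM7 file path
#' @return a [MolecularSystem-class] (positions unset)
#' @export
readPrmtopTopology <- function(path) {
  prmtop <- readPrmtop(path)
  ptr <- .needSection(prmtop, "POINTERS")
  natom <- ptr[["NATOM"]]
  types <- .needSection(prmtop, "AMBER_ATOM_TYPE")
  charges <- .needSection(prmtop, "CHARGE") / .PRMTOP_CHARGE_SCALE
  if (length(types) != natom)
    stop("PRMTOP pointer NATOM (", natom, ") inconsistent with ",
         length(types), " atom types")
  if (length(charges) != natom)
    stop("PRMTOP pointer NATOM (", natom, ") inconsistent with ",
         length(charges), " charges")

  resid <- rep(1L, natom); resname <- rep("MOL", natom)
  if (!is.null(prmtop$RESIDUE_POINTER) && !is.null(prmtop$RESIDUE_LABEL)) {
    rp <- as.integer(prmtop$RESIDUE_POINTER)
    ends <- c(rp[-1] - 1L, natom)
    for (r in seq_along(rp)) {
      resid[rp[r]:ends[r]] <- r
      resname[rp[r]:ends[r]] <- prmtop$RESIDUE_LABEL[r]
    }
  }

  bi <- c(.needSection(prmtop, "BONDS_INC_HYDROGEN"),
          .needSection(prmtop, "BONDS_WITHOUT_HYDROGEN"))
  bonds <- if (length(bi)) {
    m <- matrix(bi, ncol = 3, byrow = TRUE)
    cbind(abs(m[, 1]) / 3, abs(m[, 2]) / 3)   # 0-based atom indexes
  } else matrix(integer(), 0, 2)

  if (ptr[["NBONH"]] + ptr[["NBONA"]] != nrow(bonds))
    stop("PRMTOP bond pointers (NBONH + NBONA = ",
         ptr[["NBONH"]] + ptr[["NBONA"]], ") inconsistent with ",
         nrow(bonds), " bond records")

  atoms <- data.frame(type = types, charge = charges,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      resid = resid, resname = resname,
                      stringsAsFactors = FALSE)
  MolecularSystem(atoms, bonds, paramsFromPrmtop(prmtop))
}

## ---- writer ---------------------------------------------------------------

.fmtI8 <- function(x) {
  if (!length(x)) return("")
  lines <- split(x, ceiling(seq_along(x) / 10))
  vapply(lines, function(v) paste(sprintf("%8d", as.integer(v)), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

## full double precision (17 significant digits), declared by the
## %FORMAT(3E24.16) line, so parameter and charge values survive the
## write -> read round trip exactly
.fmtE24 <- function(x) {
  if (!length(x)) return("")
  lines <- split(x, ceiling(seq_along(x) / 3))
  vapply(lines, function(v) paste(sprintf("%24.16E", v), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

.fmtA4 <- function(x) {
  if (!length(x)) return("")
  x <- sprintf("%-4s", x)
  lines <- split(x, ceiling(seq_along(x) / 20))
  vapply(lines, function(v) paste(v, collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Write a MolecularSystem as a PRMTOP/PARM7 file
#'
#' Emits the standard sections (pointers, charges in premultiplied units,
#' atom types, Lennard-Jones coefficient tables from the Lorentz-Berthelot
#' combination of the per-type parameters, bonded-term instance lists with
#' their parameter arrays, exclusion lists) so the file round-trips through
#' [readPrmtopTopology()]. All bonded instances go to the without-hydrogen
#' sections. Proper-torsion records are expanded one file entry per active
#' periodicity slot (magnitude divided by the path count, which the file
#' format has no slot for); improper entries are flagged by a negative
#' fourth index.
#'
#' @param system a [MolecularSystem-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writePrmtop <- function(system, path) {
  stopifnot(is(system, "MolecularSystem"))
  at <- system@atoms
  n <- nrow(at)
  prm <- system@params
  typeLabels <- unique(at$type)
  ntypes <- length(typeLabels)
  tindex <- match(at$type, typeLabels)

  ## per-type R/eps (must all be present in the vdw table)
  vr <- prm@vdw$radius[match(typeLabels, prm@vdw$type)]
  ve <- prm@vdw$eps[match(typeLabels, prm@vdw$type)]
  if (anyNA(vr))
    stop("missing vdw parameters for type(s): ",
         paste(typeLabels[is.na(vr)], collapse = ", "))
  ntri <- ntypes * (ntypes + 1) / 2
  acoef <- numeric(ntri); bcoef <- numeric(ntri)
  ico <- integer(ntypes * ntypes)
  for (jj in seq_len(ntypes)) for (ii in seq_len(jj)) {
    k <- jj * (jj - 1) / 2 + ii
    eps <- sqrt(ve[ii] * ve[jj]); d <- vr[ii] + vr[jj]
    acoef[k] <- eps * d^12; bcoef[k] <- 2 * eps * d^6
    ico[ntypes * (ii - 1) + jj] <- k
    ico[ntypes * (jj - 1) + ii] <- k
  }

  ## bond types
  bondTerms <- system@bonds
  bKeys <- character(); bKb <- numeric(); bL0 <- numeric()
  bondEntries <- integer()
  if (nrow(bondTerms)) {
    for (r in seq_len(nrow(bondTerms))) {
      i <- bondTerms[r, 1]; j <- bondTerms[r, 2]
      rec <- lookupBonded(prm, "bond", c(at$type[i], at$type[j]))
      if (is.null(rec))
        stop("missing bond parameters for type pair ",
             at$type[i], "-", at$type[j])
      key <- .bondKey(at$type[i], at$type[j])
      t <- match(key, bKeys)
      if (is.na(t)) {
        bKeys <- c(bKeys, key); bKb <- c(bKb, rec$kb); bL0 <- c(bL0, rec$l0)
        t <- length(bKeys)
      }
      bondEntries <- c(bondEntries, 3L * (i - 1L), 3L * (j - 1L), t)
    }
  }

  ## angle types
  angTerms <- system@angles
  aKeys <- character(); aKa <- numeric(); aTh <- numeric()
  angEntries <- integer()
  if (nrow(angTerms)) {
    for (r in seq_len(nrow(angTerms))) {
      ijk <- angTerms[r, ]
      rec <- lookupBonded(prm, "angle", at$type[ijk])
      if (is.null(rec))
        stop("missing angle parameters for type triple ",
             paste(at$type[ijk], collapse = "-"))
      key <- .angleKey(at$type[ijk[1]], at$type[ijk[2]], at$type[ijk[3]])
      t <- match(key, aKeys)
      if (is.na(t)) {
        aKeys <- c(aKeys, key); aKa <- c(aKa, rec$ka)
        aTh <- c(aTh, rec$theta0 * pi / 180)
        t <- length(aKeys)
      }
      angEntries <- c(angEntries, 3L * (ijk - 1L), t)
    }
  }

  ## dihedral types: propers expanded per active periodicity slot,
  ## impropers flagged by negative fourth index
  dKeys <- character(); dPk <- numeric(); dPn <- numeric(); dPh <- numeric()
  dihEntries <- integer()
  dType <- function(key, pk, pn, ph) {
    t <- match(key, dKeys)
    if (is.na(t)) {
      dKeys <<- c(dKeys, key); dPk <<- c(dPk, pk)
      dPn <<- c(dPn, pn); dPh <<- c(dPh, ph)
      t <- length(dKeys)
    }
    t
  }
  torTerms <- system@torsions
  if (nrow(torTerms)) {
    for (r in seq_len(nrow(torTerms))) {
      q <- torTerms[r, ]
      rec <- lookupBonded(prm, "torsion", at$type[q])
      if (is.null(rec))
        stop("missing torsion parameters for type quadruple ",
             paste(at$type[q], collapse = "-"))
      kd <- c(rec$kd1, rec$kd2, rec$kd3, rec$kd4)
      ad <- c(rec$a1, rec$a2, rec$a3, rec$a4)
      slots <- which(kd != 0)
      if (!length(slots)) slots <- 1L
      first <- TRUE
      for (s in slots) {
        key <- paste(.torsionKey(at$type[q[1]], at$type[q[2]],
                                 at$type[q[3]], at$type[q[4]]), s,
                     sep = "#")
        t <- dType(key, kd[s] / rec$npaths, s, ad[s] * pi / 180)
        qq <- q
        if (!first && qq[3] == 1L) qq <- rev(qq)  # atom 0 cannot carry a flag
        kIdx <- 3L * (qq[3] - 1L)
        if (!first) kIdx <- -kIdx
        dihEntries <- c(dihEntries, 3L * (qq[1] - 1L), 3L * (qq[2] - 1L),
                        kIdx, 3L * (qq[4] - 1L), t)
        first <- FALSE
      }
    }
  }
  impTerms <- system@impropers
  if (nrow(impTerms)) {
    for (r in seq_len(nrow(impTerms))) {
      q <- impTerms[r, ]
      rec <- lookupBonded(prm, "improper", at$type[q])
      key <- paste("imp", .improperKey(at$type[q[1]], at$type[q[2]],
                                       at$type[q[3]], at$type[q[4]]),
                   sep = "#")
      t <- dType(key, rec$ki, rec$period, rec$phase * pi / 180)
      ## peripheral positions may be permuted freely; keep atom 0 out of
      ## the sign-carrying fourth slot
      if (q[4] == 1L) { tmp <- q[1]; q[1] <- q[4]; q[4] <- tmp }
      dihEntries <- c(dihEntries, 3L * (q[1] - 1L), 3L * (q[2] - 1L),
                      3L * (q[3] - 1L), -(3L * (q[4] - 1L)), t)
    }
  }

  ## exclusion list: 1-2/1-3/1-4 partners with higher index, AMBER style
  cls <- classifyPairs(system@adjacency)
  numex <- integer(n); exlist <- integer()
  for (i in seq_len(n)) {
    ex <- which(cls[i, ] %in% 1:3)
    ex <- ex[ex > i]
    if (length(ex)) {
      numex[i] <- length(ex)
      exlist <- c(exlist, ex)           # 1-based atom numbers
    } else {
      numex[i] <- 1L
      exlist <- c(exlist, 0L)
    }
  }

  resBreaks <- which(!duplicated(at$resid))
  nres <- length(resBreaks)
  ndih <- length(dihEntries) / 5

  ptr <- integer(31)
  names(ptr) <- .POINTER_NAMES
  ptr["NATOM"] <- n; ptr["NTYPES"] <- ntypes
  ptr["MBONA"] <- ptr["NBONA"] <- length(bondEntries) / 3
  ptr["MTHETA"] <- ptr["NTHETA"] <- length(angEntries) / 4
  ptr["MPHIA"] <- ptr["NPHIA"] <- ndih
  ptr["NNB"] <- length(exlist); ptr["NRES"] <- nres
  ptr["NUMBND"] <- length(bKeys); ptr["NUMANG"] <- length(aKeys)
  ptr["NPTRA"] <- length(dKeys); ptr["NATYP"] <- ntypes
  ptr["NMXRS"] <- max(table(at$resid))

  out <- c("%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/00  00:00:00",
           "%FLAG TITLE", "%FORMAT(20a4)", "generated topology")
  sec <- function(name, fmt, lines) c(paste0("%FLAG ", name),
                                      paste0("%FORMAT(", fmt, ")"),
                                      if (length(lines) && any(nzchar(lines))) lines else "")
  out <- c(out,
    sec("POINTERS", "10I8", .fmtI8(unname(ptr))),
    sec("ATOM_NAME", "20a4", .fmtA4(substr(at$type, 1, 4))),
    sec("CHARGE", "3E24.16", .fmtE24(at$charge * .PRMTOP_CHARGE_SCALE)),
    sec("MASS", "3E24.16", .fmtE24(rep(1, n))),
    sec("ATOM_TYPE_INDEX", "10I8", .fmtI8(tindex)),
    sec("NUMBER_EXCLUDED_ATOMS", "10I8", .fmtI8(numex)),
    sec("NONBONDED_PARM_INDEX", "10I8", .fmtI8(ico)),
    sec("RESIDUE_LABEL", "20a4", .fmtA4(at$resname[resBreaks])),
    sec("RESIDUE_POINTER", "10I8", .fmtI8(resBreaks)),
    sec("BOND_FORCE_CONSTANT", "3E24.16", .fmtE24(bKb)),
    sec("BOND_EQUIL_VALUE", "3E24.16", .fmtE24(bL0)),
    sec("ANGLE_FORCE_CONSTANT", "3E24.16", .fmtE24(aKa)),
    sec("ANGLE_EQUIL_VALUE", "3E24.16", .fmtE24(aTh)),
    sec("DIHEDRAL_FORCE_CONSTANT", "3E24.16", .fmtE24(dPk)),
    sec("DIHEDRAL_PERIODICITY", "3E24.16", .fmtE24(dPn)),
    sec("DIHEDRAL_PHASE", "3E24.16", .fmtE24(dPh)),
    sec("SOLTY", "3E24.16", .fmtE24(rep(0, ntypes))),
    sec("LENNARD_JONES_ACOEF", "3E24.16", .fmtE24(acoef)),
    sec("LENNARD_JONES_BCOEF", "3E24.16", .fmtE24(bcoef)),
    sec("BONDS_INC_HYDROGEN", "10I8", .fmtI8(integer())),
    sec("BONDS_WITHOUT_HYDROGEN", "10I8", .fmtI8(bondEntries)),
    sec("ANGLES_INC_HYDROGEN", "10I8", .fmtI8(integer())),
    sec("ANGLES_WITHOUT_HYDROGEN", "10I8", .fmtI8(angEntries)),
    sec("DIHEDRALS_INC_HYDROGEN", "10I8", .fmtI8(integer())),
    sec("DIHEDRALS_WITHOUT_HYDROGEN", "10I8", .fmtI8(dihEntries)),
    sec("EXCLUDED_ATOMS_LIST", "10I8", .fmtI8(exlist)),
    sec("AMBER_ATOM_TYPE", "20a4", .fmtA4(at$type)))
  writeLines(out, path)
  invisible(path)
}
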