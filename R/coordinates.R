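## Coordinate readers/writers. AMBER inpcrd/restrt ASCII is parsed here;
## PDB goes through bio3d.

#' Attach coordinates from an inpcrd/restart or PDB file
#'
#' The file's atom count must equal the system's. For AMBER ASCII
#' coordinate files carrying more than one 3N-number block (e.g. appended
#' frames), `frame` selects the 0-based block; the default is the first.
#' PDB files are read with bio3d; only ATOM/HETATM coordinates are used.
#'
#' @param path coordinate file path
#' @param system a [MolecularSystem-class]
#' @param format "inpcrd" or "pdb"; by default inferred from the file
#'   extension (.pdb -> pdb, everything else inpcrd)
#' @param frame 0-based frame index for multi-frame inpcrd files
#' @return the system with positions set
#' @export
readCoordinates <- function(path, system, format = c("auto", "inpcrd", "pdb"),
                            frame = 0L) {
  stopifnot(is(system, "MolecularSystem"))
  if (!file.exists(path)) stop("coordinates file not found: ", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "inpcrd"
  n <- nrow(system@atoms)
  if (format == "inpcrd") {
    xyz <- .readInpcrd(path, n, frame)
  } else {
    pdb <- bio3d::read.pdb(path)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
    if (nrow(xyz) != n)
      stop("coordinate file has ", nrow(xyz), " atoms but the system has ", n)
  }
  coordinates(system) <- xyz
  system
}

.readInpcrd <- function(path, n, frame = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated inpcrd file: ", path)
  cnt <- suppressWarnings(as.integer(strsplit(trimws(lines[2]),
                                              "[[:space:]]+")[[1]][1]))
  if (is.na(cnt))
    stop("inpcrd line 2: cannot parse atom count in ", path)
  if (cnt != n)
    stop("coordinate file has ", cnt, " atoms but the system has ", n)
  body <- lines[-(1:2)]
  toks <- unlist(strsplit(trimws(body[nzchar(trimws(body))]), "[[:space:]]+"))
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("inpcrd: non-numeric coordinate field (token ", bad, ") in ", path)
  }
  lo <- frame * 3L * n
  if (length(vals) < lo + 3L * n)
    stop("inpcrd holds ", floor(length(vals) / (3 * n)),
         " frame(s); frame ", frame, " requested")
  matrix(vals[(lo + 1):(lo + 3 * n)], ncol = 3, byrow = TRUE)
}

#' Write coordinates as an AMBER inpcrd file
#'
#' @param system a [MolecularSystem-class] with positions set
#' @param path output path
#' @return invisibly, the path
#' @export
writeInpcrd <- function(system, path) {
  stopifnot(is(system, "MolecularSystem"))
  .requirePositions(system)
  xyz <- as.vector(t(coordinates(system)))
  lines <- c("generated coordinates", sprintf("%5d", nrow(system@atoms)))
  chunks <- split(xyz, ceiling(seq_along(xyz) / 6))
  lines <- c(lines, vapply(chunks, function(v)
    paste(sprintf("%12.7f", v), collapse = ""), character(1),
    USE.NAMES = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Write coordinates as a PDB file
#'
#' Thin wrapper over bio3d's PDB writer carrying the system's residue
#' metadata and atom types as element/atom names.
#'
#' @param system a [MolecularSystem-class] with positions set
#' @param path output path
#' @return invisibly, the path
#' @export
writePdbFile <- function(system, path) {
  stopifnot(is(system, "MolecularSystem"))
  .requirePositions(system)
  at <- system@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coordinates(system))),
                   resno = at$resid, resid = at$resname,
                   elety = substr(at$type, 1, 4),
                   eleno = seq_len(nrow(at)))
  invisible(path)
}
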