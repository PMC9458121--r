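## Sectioned calculation output: a fixed-order text report (Fragments,
## Bonds, Angles, Torsions, Out-of-Plane, VDW, Coulomb, Total Energy),
## plus JSON and CSV renderings carrying identical numbers.

.fmtIndexRuns <- function(idx) {
  if (!length(idx)) return("")
  idx <- sort(idx)
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  runs <- vapply(seq_len(length(breaks) - 1L), function(k) {
    a <- idx[breaks[k] + 1L]; b <- idx[breaks[k + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  paste(runs, collapse = ", ")
}

.bucketTitle <- function(key) {
  paste(paste("Fragment", strsplit(key, "+", fixed = TRUE)[[1]]),
        collapse = " + ")
}

#' Serialize an EnergyReport
#'
#' Text format: a worker-count header; a "Fragments" section listing each
#' fragment with its 0-based atom indexes; one section per energy class
#' (Bonds, Angles, Torsions, Out-of-Plane, VDW, Coulomb) with one line per
#' non-empty bucket, rendered "Fragment N" / "Fragment N + Fragment M"
#' (further "+"-joined for triples and quadruples); improper warnings
#' inside the Out-of-Plane section; "Total Energy" last. Energies are
#' kcal/mol with six fixed decimals. The json and csv formats carry the
#' identical numbers at full precision.
#'
#' @param report an [EnergyReport-class]
#' @param format "text", "json" or "csv"
#' @param file optional output path; when given the serialization is
#'   written there and returned invisibly
#' @return character vector of lines (text/csv) or JSON string
#' @export
writeReport <- function(report, format = c("text", "json", "csv"),
                        file = NULL) {
  stopifnot(is(report, "EnergyReport"))
  format <- match.arg(format)
  out <- switch(format,
                text = .reportText(report),
                json = .reportJson(report),
                csv = .reportCsv(report))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.reportText <- function(report) {
  md <- report@metadata
  lines <- c(sprintf("Workers: %d", if (is.null(md$workers)) 1L else md$workers),
             "", "Fragments")
  for (lab in names(report@fragments))
    lines <- c(lines, sprintf("Fragment %s: %s", lab,
                              .fmtIndexRuns(report@fragments[[lab]])))
  for (cl in .TERM_CLASSES) {
    lines <- c(lines, "", cl)
    if (cl == "Out-of-Plane" && length(report@warnings))
      lines <- c(lines, paste("Warning:", report@warnings))
    e <- report@energies[[cl]]
    for (k in names(e))
      lines <- c(lines, sprintf("%s: %.6f", .bucketTitle(k), e[[k]]))
    lines <- c(lines, sprintf("Subtotal: %.6f", report@totals[[cl]]))
  }
  c(lines, "", "Total Energy", sprintf("%.6f", report@totals[["Total"]]))
}

.reportJson <- function(report) {
  obj <- list(
    workers = if (is.null(report@metadata$workers)) 1L else report@metadata$workers,
    fragments = lapply(report@fragments, as.integer),
    energies = lapply(report@energies, as.list),
    totals = as.list(report@totals),
    warnings = report@warnings)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.reportCsv <- function(report) {
  rows <- list()
  for (cl in .TERM_CLASSES) {
    e <- report@energies[[cl]]
    if (length(e))
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, bucket = names(e), energy_kcal_mol = as.numeric(e),
        stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    class = "Total Energy", bucket = "all",
    energy_kcal_mol = report@totals[["Total"]], stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  c("class,bucket,energy_kcal_mol",
    sprintf("%s,%s,%.15g", tab$class, tab$bucket, tab$energy_kcal_mol))
}
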