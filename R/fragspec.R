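#' Parse a fragment-selection specification string
#'
#' Grammar: `label=ranges(;label=ranges)*` where `ranges` is a
#' comma-separated list of 0-based atom indexes or inclusive `a-b` spans.
#' Duplicated indexes within a label are de-duplicated. The remainder
#' label `"X"` is reserved and may not be assigned explicitly.
#'
#' @param spec specification string, e.g. `"0=1-10;1=15-25"`
#' @return named list: label -> sorted integer vector of 0-based indexes
#' @examples
#' parseFragmentSpec("0=1-10;1=15-25")
#' @export
parseFragmentSpec <- function(spec) {
  spec <- trimws(spec)
  if (!nzchar(spec)) stop("empty fragment specification")
  groups <- strsplit(spec, ";", fixed = TRUE)[[1]]
  out <- list()
  for (gi in seq_along(groups)) {
    g <- trimws(groups[[gi]])
    if (!nzchar(g)) next
    eq <- regexpr("=", g, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("fragment group %d ('%s'): missing '='", gi, g))
    lab <- trimws(substr(g, 1, eq - 1))
    if (!nzchar(lab))
      stop(sprintf("fragment group %d ('%s'): empty label", gi, g))
    if (lab == remainderLabel())
      stop(sprintf("fragment group %d: label \"X\" is reserved for the remainder",
                   gi))
    if (lab %in% names(out))
      stop(sprintf("fragment group %d: duplicate label '%s'", gi, lab))
    body <- trimws(substr(g, eq + 1, nchar(g)))
    if (!nzchar(body))
      stop(sprintf("fragment group %d ('%s'): empty index list", gi, g))
    idx <- integer()
    for (piece in trimws(strsplit(body, ",", fixed = TRUE)[[1]])) {
      if (grepl("^[0-9]+$", piece)) {
        idx <- c(idx, as.integer(piece))
      } else if (grepl("^[0-9]+-[0-9]+$", piece)) {
        ab <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
        if (ab[2] < ab[1])
          stop(sprintf("fragment %s: reversed span '%s'", lab, piece))
        idx <- c(idx, ab[1]:ab[2])
      } else {
        stop(sprintf("fragment %s: malformed range '%s'", lab, piece))
      }
    }
    out[[lab]] <- sort(unique(idx))
  }
  if (!length(out)) stop("empty fragment specification")
  out
}
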