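## test helper: induced sub-system on a 0-based atom index set, keeping the
## parent's parameter tables (used to check per-molecule self-energies)
subsetFixture <- function(sys, idx0) {
  rows <- sort(as.integer(idx0)) + 1L
  at <- sys@atoms[rows, , drop = FALSE]
  allBonds <- amberDecomp:::.bondsFromAdjacency(sys@adjacency)
  keep <- allBonds[, 1] %in% rows & allBonds[, 2] %in% rows
  b <- allBonds[keep, , drop = FALSE]
  b0 <- cbind(match(b[, 1], rows), match(b[, 2], rows)) - 1L
  MolecularSystem(at, b0, sys@params)
}
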