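# shared fixtures, built in code at test time

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# small two-family alignment with hand-readable sequences
toyAlignment <- function() {
  DomainAlignment(
    ids = c("a1", "a2", "b1", "b2"),
    sequences = c("ARNDW", "ARNEW", "WNDRA", "WNERA"),
    family = c("famA", "famA", "famB", "famB"),
    group = c("g1", "g1", "g2", "g2"))
}

# deterministic profiles keyed to toyAlignment()
toyProfiles <- function(nPos = 3) {
  ids <- c("a1", "a2", "b1", "b2")
  out <- lapply(seq_along(ids), function(k) {
    M <- matrix(0, nPos, 20)
    M[1, k] <- 1          # distinct, hand-computable matrices
    M[2, 20 - k] <- 0.5
    SpecificityProfile(ids[k], M,
                       positions = paste0("P", seq_len(nPos)), aas = AA20)
  })
  names(out) <- ids
  out
}

# a small planted-determinant set, cheaper than fixtureA(), cached per session
.smallSynthEnv <- new.env()
smallSynth <- function() {
  if (is.null(.smallSynthEnv$x)) {
    spec <- syntheticSpec(nFamilies = 4, kinasesPerFamily = 3, L = 20,
                          plantedColumns = c(4L, 11L), nPeptidePositions = 5,
                          noiseSd = 0.05, conservedColumns = c(2L, 17L),
                          seed = 3L)
    .smallSynthEnv$x <- c(generateSyntheticKinome(spec), list(spec = spec))
  }
  .smallSynthEnv$x
}

# write a minimal PDB file from a data.frame with columns
# chain, resno, resname, atom, x, y, z and optional alt, occ, elem
writeToyPDB <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    alt <- if (!is.null(atoms$alt)) a$alt else ""
    occ <- if (!is.null(atoms$occ)) a$occ else 1
    elem <- if (!is.null(atoms$elem)) a$elem else substr(trimws(a$atom), 1, 1)
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$atom, alt, a$resname, a$chain, a$resno,
            a$x, a$y, a$z, occ, 0, elem)
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# independent brute-force Frobenius distance (elementwise double loop)
bruteFrobenius <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + (A[i, j] - B[i, j])^2
  sqrt(s)
}
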