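#' @include AllClasses.R
NULL

## residues a planted column may take: a small alphabet shared across families
## so leave-family-out donors still carry the planted signal
.PLANT_ALPHABET <- c("A", "R", "D", "W")

## deterministic residue -> preferred peptide amino acid (index into .AA20)
.plantTarget <- function(residue) {
  ri <- match(residue, .AA20)
  ((ri * 7L) %% 20L) + 1L
}

#' Generate a synthetic kinome with planted determinants
#'
#' Builds a family-structured alignment and matching specificity profiles in
#' which designated ("planted") columns deterministically drive the PSSMs:
#' each kinase's residue at the k-th planted column (drawn i.i.d. from a
#' 4-letter alphabet shared across families) adds +1 preference for a
#' residue-keyed amino acid at the k-th peptide position. All other sequence
#' positions follow a per-family consensus with a 10% per-site substitution
#' rate and have no effect on the profiles; `conservedColumns` are invariant
#' kinome-wide (a pure-conservation decoy). Gaussian noise of sd
#' `spec@noiseSd` is added to every PSSM entry. Fully reproducible from
#' `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `alignment` (a [DomainAlignment-class]) and `profiles`
#'   (named list of [SpecificityProfile-class], one per record).
#' @export
generateSyntheticKinome <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  nFam <- spec@nFamilies; perFam <- spec@kinasesPerFamily
  L <- spec@L; nPep <- spec@nPeptidePositions
  planted <- spec@plantedColumns
  conserved <- spec@conservedColumns

  conservedResidues <- sample(.AA20, length(conserved), replace = TRUE)
  ids <- character(0); fams <- character(0); seqs <- character(0)
  seqMat <- matrix("", 0, L)
  for (f in seq_len(nFam)) {
    consensus <- sample(.AA20, L, replace = TRUE)
    for (k in seq_len(perFam)) {
      s <- consensus
      sub <- stats::runif(L) < 0.10
      if (any(sub)) s[sub] <- sample(.AA20, sum(sub), replace = TRUE)
      s[planted] <- sample(.PLANT_ALPHABET, length(planted), replace = TRUE)
      s[conserved] <- conservedResidues
      seqMat <- rbind(seqMat, s)
      ids <- c(ids, sprintf("fam%02d_kin%02d", f, k))
      fams <- c(fams, sprintf("fam%02d", f))
    }
  }
  seqs <- apply(seqMat, 1L, paste, collapse = "")
  aln <- DomainAlignment(ids, seqs, fams,
                         group = rep("synthetic", length(ids)))

  offsets <- seq_len(nPep) - (nPep + 1L) %/% 2L
  posLabels <- ifelse(offsets > 0, paste0("P+", offsets),
                      ifelse(offsets == 0, "P0", paste0("P", offsets)))
  profiles <- lapply(seq_along(ids), function(r) {
    M <- matrix(0, nPep, 20L)
    for (k in seq_along(planted))
      M[k, .plantTarget(seqMat[r, planted[k]])] <-
        M[k, .plantTarget(seqMat[r, planted[k]])] + 1
    if (spec@noiseSd > 0)
      M <- M + matrix(stats::rnorm(nPep * 20L, 0, spec@noiseSd), nPep, 20L)
    SpecificityProfile(ids[r], M, positions = posLabels, aas = .AA20)
  })
  names(profiles) <- ids
  list(alignment = aln, profiles = profiles)
}

#' Uniform-profile control set
#'
#' Replaces every profile by the same constant matrix, removing all signal.
#' Any convex combination of identical matrices reproduces them exactly, so
#' mask fitness is 0 for every mask and the search has nothing to optimise.
#'
#' @param profiles named list of [SpecificityProfile-class].
#' @param value the constant (default 0).
#' @return named list of the same length.
#' @export
makeUniformControl <- function(profiles, value = 0) {
  lapply(profiles, function(p)
    SpecificityProfile(p@domainId,
                       matrix(value, nrow(p@values), 20L),
                       positions = p@positions, aas = p@aas))
}

#' Label-shuffled control set
#'
#' Randomly permutes the profile matrices across kinase ids, breaking the
#' sequence-to-specificity linkage while preserving the multiset of matrices.
#' If the identity permutation is drawn it is redrawn, so at least one id
#' changes its matrix.
#'
#' @param profiles named list of >= 2 [SpecificityProfile-class].
#' @param seed RNG seed.
#' @return named list: same names, permuted matrices.
#' @export
makeShuffledControl <- function(profiles, seed = 1L) {
  n <- length(profiles)
  if (n < 2L) stop("need >= 2 profiles to shuffle")
  set.seed(seed)
  perm <- sample.int(n)
  while (all(perm == seq_len(n))) perm <- sample.int(n)
  out <- lapply(seq_len(n), function(i) {
    src <- profiles[[perm[i]]]
    SpecificityProfile(profiles[[i]]@domainId, src@values,
                       positions = src@positions, aas = src@aas)
  })
  names(out) <- names(profiles)
  out
}

#' Recovery of planted determinants from aggregated DoS scores
#'
#' Ranks all columns by descending aggregated score (average-rank ties) and
#' reports the ranks of the planted columns plus the fraction of them found in
#' the top `k = 2 * n_planted`.
#'
#' @param scores a [DoSScoreVector-class] or numeric per-column scores.
#' @param spec the [SyntheticSpec-class] that generated the data.
#' @return list with `ranks` (named by planted column), `k`, and
#'   `topKHitFraction`.
#' @export
plantedRecovery <- function(scores, spec) {
  s <- if (is(scores, "DoSScoreVector")) dosScores(scores) else as.numeric(scores)
  if (length(s) != spec@L)
    stop("score vector length does not match spec L")
  rk <- rank(-s, ties.method = "average")
  planted <- spec@plantedColumns
  k <- 2L * length(planted)
  pr <- stats::setNames(rk[planted], as.character(planted))
  list(ranks = pr, k = k, topKHitFraction = mean(pr <= k))
}

#' The standard desk-scale fixture (FIX-A)
#'
#' 8 families x 4 kinases, 60 alignment columns, 3 planted determinant columns
#' (7, 23, 41), 6 invariant conservation-decoy columns (3, 15, 30, 36, 50,
#' 58), 9 peptide positions, profile noise sd 0.05, seed 7. The planted
#' columns should be recovered in the top 6 aggregated DoS scores while every
#' decoy scores below the lowest planted column.
#'
#' @return a [SyntheticSpec-class].
#' @export
fixtureA <- function() {
  syntheticSpec(nFamilies = 8, kinasesPerFamily = 4, L = 60,
                plantedColumns = c(7L, 23L, 41L), nPeptidePositions = 9,
                noiseSd = 0.05,
                conservedColumns = c(3L, 15L, 30L, 36L, 50L, 58L), seed = 7L)
}
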