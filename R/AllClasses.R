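#' @import methods
NULL

## Alphabet used throughout: the 20 standard amino acids in the row order of
## the BLOSUM62 matrix shipped with Biostrings, plus '-' as the only gap symbol.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.GAP <- "-"

#' Aligned protein-domain set
#'
#' Holds a multiple alignment of domain sequences together with per-record
#' family and group annotations. The alignment columns are the coordinate
#' system for specificity masks, determinant-of-specificity (DoS) scores,
#' conservation and structure-distance annotations. Columns are 1-based.
#'
#' @slot ids unique record identifiers, in alignment order.
#' @slot sequences gapped amino-acid strings, all of identical length.
#' @slot family non-empty family label per record (used for leave-family-out
#'   prediction).
#' @slot group coarser group label per record (may be empty).
#'
#' @export
setClass("DomainAlignment",
  representation(ids = "character", sequences = "character",
                 family = "character", group = "character"))

setValidity("DomainAlignment", function(object) {
  n <- length(object@ids)
  if (n == 0L) return("alignment has no records")
  if (length(object@sequences) != n || length(object@family) != n ||
      length(object@group) != n)
    return("ids, sequences, family and group must have equal length")
  if (anyDuplicated(object@ids))
    return(paste0("duplicated record ids: ",
                  paste(unique(object@ids[duplicated(object@ids)]),
                        collapse = ", ")))
  lens <- nchar(object@sequences)
  if (lens[1] < 1L) return("alignment length must be >= 1")
  if (length(unique(lens)) != 1L) {
    bad <- object@ids[lens != stats::median(lens)][1]
    return(paste0("ragged alignment: record '", bad, "' has length ",
                  nchar(object@sequences[object@ids == bad]),
                  " but others have ", stats::median(lens)))
  }
  chars <- unique(strsplit(paste(object@sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(.AA20, .GAP))
  if (length(bad) > 0L)
    return(paste0("unknown residue character(s): ",
                  paste(bad, collapse = ", "),
                  " (only the 20 standard amino acids and '-' are allowed)"))
  if (any(!nzchar(object@family)))
    return(paste0("empty family label for record(s): ",
                  paste(object@ids[!nzchar(object@family)], collapse = ", ")))
  TRUE
})

#' Construct a DomainAlignment
#'
#' @param ids character vector of unique record ids.
#' @param sequences gapped sequences (upper-cased on construction).
#' @param family family label per record.
#' @param group optional group label per record.
#' @return a validated [DomainAlignment-class] object.
#' @examples
#' aln <- DomainAlignment(c("k1", "k2"), c("ARND-", "ARNDC"),
#'                        family = c("famA", "famB"))
#' alignmentLength(aln)
#' @export
DomainAlignment <- function(ids, sequences, family, group = rep("", length(ids))) {
  new("DomainAlignment", ids = as.character(ids),
      sequences = toupper(as.character(sequences)),
      family = as.character(family), group = as.character(group))
}

#' Peptide-specificity profile (PSSM)
#'
#' One position-specific scoring matrix for one domain: preference scores for
#' each of the 20 amino acids at each substrate-peptide position. Values are
#' kept exactly as loaded; no renormalisation is applied.
#'
#' @slot domainId alignment record id the profile belongs to.
#' @slot positions peptide-position labels (e.g. "P-4" ... "P+4"), read
#'   verbatim and never reinterpreted.
#' @slot aas the 20 amino-acid column labels.
#' @slot values numeric matrix, `length(positions)` x 20, all entries finite.
#' @export
setClass("SpecificityProfile",
  representation(domainId = "character", positions = "character",
                 aas = "character", values = "matrix"))

setValidity("SpecificityProfile", function(object) {
  if (length(object@positions) == 0L) return("positions must be non-empty")
  if (anyDuplicated(object@positions)) return("duplicated position labels")
  if (length(object@aas) != 20L) return("exactly 20 amino-acid columns required")
  if (!identical(dim(object@values),
                 c(length(object@positions), 20L)))
    return("values must be a positions x 20 matrix")
  if (!all(is.finite(object@values))) return("non-finite PSSM entries")
  TRUE
})

#' Construct a SpecificityProfile
#' @param domainId record id.
#' @param values numeric matrix of preference scores (positions x 20 amino acids).
#' @param positions peptide-position labels; defaults to rownames of `values`.
#' @param aas amino-acid labels; defaults to colnames of `values`.
#' @return a validated [SpecificityProfile-class].
#' @export
SpecificityProfile <- function(domainId, values, positions = rownames(values),
                               aas = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(positions)) positions <- paste0("pos", seq_len(nrow(values)))
  if (is.null(aas)) aas <- .AA20
  dimnames(values) <- list(positions, aas)
  new("SpecificityProfile", domainId = as.character(domainId),
      positions = as.character(positions), aas = as.character(aas),
      values = values)
}

#' Specificity mask
#'
#' A score in \[0, 1\] per alignment column, expressing how much that column
#' contributes to substrate specificity. Masks are the individuals the
#' genetic-algorithm search evolves; high-scoring columns of converged masks
#' are candidate determinants of specificity.
#'
#' @slot scores numeric vector, one entry per alignment column, each in \[0, 1\].
#' @export
setClass("SpecificityMask", representation(scores = "numeric"))

setValidity("SpecificityMask", function(object) {
  if (length(object@scores) == 0L) return("empty mask")
  if (any(!is.finite(object@scores))) return("non-finite mask scores")
  if (any(object@scores < 0 | object@scores > 1))
    return("mask scores must lie in [0, 1]")
  TRUE
})

#' @rdname SpecificityMask-class
#' @param scores numeric vector in \[0, 1\].
#' @return a validated [SpecificityMask-class].
#' @export
SpecificityMask <- function(scores) new("SpecificityMask", scores = as.numeric(scores))

#' Prediction configuration
#'
#' Parameters of mask-weighted, leave-family-out PSSM prediction.
#'
#' @slot alpha similarity-sharpening exponent applied to donor weights; larger
#'   values concentrate the prediction on the most similar donors. The scan
#'   over candidate values (see [selectAlpha()]) picked 3 for the kinase
#'   domain, which is the default.
#' @slot excludeSameFamily exclude donors from the query's own family
#'   (on by default, to avoid overfitting to close homologs).
#' @slot gapSimilarity per-column similarity assigned when either symbol is a
#'   gap, in \[0, 1\] (default 0: gapped columns count as dissimilar).
#' @export
setClass("PredictionConfig",
  representation(alpha = "numeric", excludeSameFamily = "logical",
                 gapSimilarity = "numeric"),
  prototype(alpha = 3, excludeSameFamily = TRUE, gapSimilarity = 0))

setValidity("PredictionConfig", function(object) {
  if (!is.finite(object@alpha) || object@alpha < 0)
    return("alpha must be finite and >= 0")
  if (object@gapSimilarity < 0 || object@gapSimilarity > 1)
    return("gapSimilarity must lie in [0, 1]")
  TRUE
})

#' @rdname PredictionConfig-class
#' @param alpha sharpening exponent, >= 0.
#' @param excludeSameFamily logical.
#' @param gapSimilarity gap-column similarity in \[0, 1\].
#' @return a [PredictionConfig-class].
#' @export
predictionConfig <- function(alpha = 3, excludeSameFamily = TRUE,
                             gapSimilarity = 0) {
  new("PredictionConfig", alpha = as.numeric(alpha),
      excludeSameFamily = isTRUE(excludeSameFamily),
      gapSimilarity = as.numeric(gapSimilarity))
}

#' Evolution (genetic algorithm) configuration
#'
#' Controls the learning classifier system that evolves specificity masks:
#' a population of masks is scored by leave-family-out prediction error, the
#' best masks are kept ("elite"), and new masks are generated by mutation and
#' single-point cross-over of elite members until the best fitness stops
#' improving.
#'
#' @slot populationSize masks per generation (default 100).
#' @slot eliteFraction fraction of the population copied unchanged (default 0.2).
#' @slot mutationRate per-position probability that a mask entry is resampled
#'   uniformly on \[0, 1\] (default 0.02).
#' @slot crossoverRate fraction of non-elite offspring produced by single-point
#'   cross-over of two distinct elite parents (default 0.5).
#' @slot maxGenerations generation budget (default 2500, roughly the
#'   generations-to-convergence observed on the human kinome).
#' @slot convergenceWindow stop after this many generations without
#'   best-fitness improvement (default 250).
#' @slot alpha prediction sharpening exponent used during fitness evaluation.
#' @slot seed RNG seed; the whole run is a pure function of inputs and seed.
#' @slot nRuns number of independent deployments for aggregation (default 10).
#' @export
setClass("EvolutionConfig",
  representation(populationSize = "integer", eliteFraction = "numeric",
                 mutationRate = "numeric", crossoverRate = "numeric",
                 maxGenerations = "integer", convergenceWindow = "integer",
                 alpha = "numeric", seed = "integer", nRuns = "integer"),
  prototype(populationSize = 100L, eliteFraction = 0.2, mutationRate = 0.02,
            crossoverRate = 0.5, maxGenerations = 2500L,
            convergenceWindow = 250L, alpha = 3, seed = 1L, nRuns = 10L))

setValidity("EvolutionConfig", function(object) {
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@eliteFraction <= 0 || object@eliteFraction > 1)
    return("eliteFraction must lie in (0, 1]")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    return("mutationRate must lie in [0, 1]")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    return("crossoverRate must lie in [0, 1]")
  if (object@maxGenerations < 1L) return("maxGenerations must be >= 1")
  if (object@convergenceWindow < 1L) return("convergenceWindow must be >= 1")
  if (!is.finite(object@alpha) || object@alpha < 0)
    return("alpha must be finite and >= 0")
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  TRUE
})

#' @rdname EvolutionConfig-class
#' @param populationSize,eliteFraction,mutationRate,crossoverRate GA operators.
#' @param maxGenerations,convergenceWindow stopping rules.
#' @param alpha,seed,nRuns see slots.
#' @return an [EvolutionConfig-class].
#' @export
evolutionConfig <- function(populationSize = 100L, eliteFraction = 0.2,
                            mutationRate = 0.02, crossoverRate = 0.5,
                            maxGenerations = 2500L, convergenceWindow = 250L,
                            alpha = 3, seed = 1L, nRuns = 10L) {
  new("EvolutionConfig", populationSize = as.integer(populationSize),
      eliteFraction = as.numeric(eliteFraction),
      mutationRate = as.numeric(mutationRate),
      crossoverRate = as.numeric(crossoverRate),
      maxGenerations = as.integer(maxGenerations),
      convergenceWindow = as.integer(convergenceWindow),
      alpha = as.numeric(alpha), seed = as.integer(seed),
      nRuns = as.integer(nRuns))
}

#' Result of one evolutionary run
#'
#' @slot bestFitnessTrajectory best (lowest) fitness at each generation;
#'   non-increasing by elitism.
#' @slot bestMaskTrajectory generations x L matrix: the best mask at each
#'   generation (used for inter-run dissimilarity diagnostics).
#' @slot finalPopulation list of [SpecificityMask-class] at the last generation.
#' @slot finalFitness fitness of each final-population mask.
#' @slot bestMask the best mask of the final generation.
#' @slot generationsRun number of generations actually executed.
#' @slot seed the seed the run used.
#' @export
setClass("EvolutionResult",
  representation(bestFitnessTrajectory = "numeric",
                 bestMaskTrajectory = "matrix",
                 finalPopulation = "list", finalFitness = "numeric",
                 bestMask = "SpecificityMask",
                 generationsRun = "integer", seed = "integer"))

setValidity("EvolutionResult", function(object) {
  tr <- object@bestFitnessTrajectory
  if (length(tr) != object@generationsRun)
    return("trajectory length must equal generationsRun")
  if (any(diff(tr) > 1e-12))
    return("best-fitness trajectory must be non-increasing (elitism)")
  if (nrow(object@bestMaskTrajectory) != length(tr))
    return("bestMaskTrajectory must have one row per generation")
  TRUE
})

#' Aggregated per-column DoS scores across independent runs
#'
#' @slot scores per-column mean of the runs' best masks, in \[0, 1\].
#' @slot nRuns number of runs aggregated.
#' @slot perRunBest runs x L matrix of the per-run best masks.
#' @export
setClass("DoSScoreVector",
  representation(scores = "numeric", nRuns = "integer", perRunBest = "matrix"))

setValidity("DoSScoreVector", function(object) {
  if (nrow(object@perRunBest) != object@nRuns)
    return("perRunBest must have nRuns rows")
  if (ncol(object@perRunBest) != length(object@scores))
    return("perRunBest must have one column per score")
  lo <- apply(object@perRunBest, 2L, min)
  hi <- apply(object@perRunBest, 2L, max)
  if (any(object@scores < lo - 1e-12 | object@scores > hi + 1e-12))
    return("aggregated scores must lie within per-run extremes")
  TRUE
})

#' Subset sequence-to-specificity correlation report
#'
#' Spearman correlation, over all unordered pairs of profiled domains, between
#' pairwise sequence similarity restricted to a column subset and pairwise
#' specificity similarity (negative Frobenius distance between PSSMs).
#'
#' @slot subset the alignment columns used (1-based).
#' @slot nColumns number of columns in the subset.
#' @slot fractionOfAlignment `nColumns / L`.
#' @slot rho Spearman correlation (NA if either variable is constant).
#' @slot nPairs number of domain pairs compared.
#' @export
setClass("SubsetCorrelationReport",
  representation(subset = "integer", nColumns = "integer",
                 fractionOfAlignment = "numeric", rho = "numeric",
                 nPairs = "integer"))

#' Synthetic-kinome specification
#'
#' Defines a family-structured synthetic domain set whose specificity profiles
#' are controlled functions of designated ("planted") alignment columns plus
#' Gaussian noise, with optional highly conserved decoy columns that do not
#' influence specificity.
#'
#' @slot nFamilies number of families.
#' @slot kinasesPerFamily records per family.
#' @slot L alignment length.
#' @slot plantedColumns 1-based columns that drive the profiles; the k-th
#'   planted column drives the k-th peptide position.
#' @slot nPeptidePositions rows of each generated PSSM.
#' @slot noiseSd standard deviation of the Gaussian noise added to profiles.
#' @slot conservedColumns 1-based near-invariant decoy columns with no effect
#'   on profiles (a conservation control).
#' @slot seed RNG seed; generation is fully reproducible.
#' @export
setClass("SyntheticSpec",
  representation(nFamilies = "integer", kinasesPerFamily = "integer",
                 L = "integer", plantedColumns = "integer",
                 nPeptidePositions = "integer", noiseSd = "numeric",
                 conservedColumns = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nFamilies * object@kinasesPerFamily < 4L)
    return("need at least 4 records (nFamilies * kinasesPerFamily >= 4)")
  if (object@L < 1L) return("L must be >= 1")
  cols <- c(object@plantedColumns, object@conservedColumns)
  if (length(cols) && (any(cols < 1L) || any(cols > object@L)))
    return("planted/conserved columns must lie in 1..L")
  if (anyDuplicated(object@plantedColumns))
    return("duplicated planted columns")
  if (length(object@plantedColumns) > object@nPeptidePositions)
    return(paste0("more planted columns (", length(object@plantedColumns),
                  ") than peptide positions (", object@nPeptidePositions,
                  "): one column drives one peptide position"))
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @rdname SyntheticSpec-class
#' @param nFamilies,kinasesPerFamily,L,plantedColumns,nPeptidePositions,noiseSd,conservedColumns,seed see slots.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nFamilies, kinasesPerFamily, L, plantedColumns,
                          nPeptidePositions, noiseSd = 0.05,
                          conservedColumns = integer(0), seed = 1L) {
  new("SyntheticSpec", nFamilies = as.integer(nFamilies),
      kinasesPerFamily = as.integer(kinasesPerFamily), L = as.integer(L),
      plantedColumns = as.integer(plantedColumns),
      nPeptidePositions = as.integer(nPeptidePositions),
      noiseSd = as.numeric(noiseSd),
      conservedColumns = as.integer(conservedColumns), seed = as.integer(seed))
}
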