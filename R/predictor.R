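#' @include AllClasses.R substitution.R
NULL

## integer encoding: 1..20 index into .AA20, 21 = gap
.encodeAlignment <- function(aln) {
  m <- sequenceMatrix(aln)
  enc <- match(m, c(.AA20, .GAP))
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

## 21 x 21 lookup of per-column similarities on [0,1]:
## min-max rescaled substitution scores; any pair involving a gap gets
## gapSimilarity.
.simLookup <- function(sm, gapSimilarity = 0) {
  sm <- .checkSubstitutionMatrix(sm)
  lo <- min(sm); hi <- max(sm)
  if (hi <= lo) stop("degenerate substitution matrix (max <= min)")
  lk <- matrix(gapSimilarity, 21L, 21L)
  lk[1:20, 1:20] <- (sm - lo) / (hi - lo)
  lk
}

#' Per-column similarity of two alignment symbols
#'
#' Substitution scores are min-max rescaled to \[0, 1\] over the 20 x 20
#' matrix, so the best-scoring pair (W/W for BLOSUM62) maps to 1 and the worst
#' to 0. If either symbol is the gap '-', `gapSimilarity` is returned.
#'
#' @param a,b single characters from the 20 standard amino acids or '-'.
#' @param sm substitution matrix (default [blosum62()]).
#' @param gapSimilarity similarity assigned to gap-containing pairs.
#' @return similarity in \[0, 1\]; symmetric in `a`, `b`.
#' @export
positionalSimilarity <- function(a, b, sm = blosum62(), gapSimilarity = 0) {
  lk <- .simLookup(sm, gapSimilarity)
  ia <- match(a, c(.AA20, .GAP))
  ib <- match(b, c(.AA20, .GAP))
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("unknown symbol: ", paste(unique(c(a[is.na(ia)], b[is.na(ib)])),
                                   collapse = ", "))
  lk[cbind(ia, ib)]
}

#' Mask-weighted similarity of two aligned records
#'
#' The per-column similarity vector of records `i` and `j` is combined with a
#' specificity mask: similarity in high-scoring mask positions is reinforced
#' and similarity in low-scoring positions is silenced. The result is the
#' mask-weighted mean \eqn{\sum_p m_p s_p / \sum_p m_p}, which is invariant to
#' rescaling the mask by any positive constant; an all-zero mask silences
#' everything and yields 0.
#'
#' @param i,j record ids or indices (must differ).
#' @param aln a [DomainAlignment-class].
#' @param mask a [SpecificityMask-class] of length `alignmentLength(aln)`.
#' @param sm substitution matrix.
#' @param gapSimilarity per-column similarity for gap pairs.
#' @return similarity in \[0, 1\], symmetric in `i`, `j`.
#' @export
maskWeightedSimilarity <- function(i, j, aln, mask, sm = blosum62(),
                                   gapSimilarity = 0) {
  if (is.character(i)) i <- match(i, aln@ids)
  if (is.character(j)) j <- match(j, aln@ids)
  if (is.na(i) || is.na(j)) stop("record not found in alignment")
  if (i == j) stop("i and j must be distinct records")
  m <- maskScores(mask)
  if (length(m) != alignmentLength(aln))
    stop("mask length (", length(m), ") does not match alignment length (",
         alignmentLength(aln), ")")
  enc <- .encodeAlignment(aln)
  lk <- .simLookup(sm, gapSimilarity)
  s <- lk[cbind(enc[i, ], enc[j, ])]
  tot <- sum(m)
  if (tot == 0) return(0)
  sum(m * s) / tot
}

## Precomputed machinery for repeated fitness/prediction over the profiled
## records. Returns closures so the GA's hot loop never re-encodes sequences.
## simPairs: npairs x L, pairs ordered as which(upper.tri()) (column-major).
.makePredictor <- function(aln, profiles, cfg, sm = blosum62()) {
  stopifnot(is(cfg, "PredictionConfig"))
  L <- alignmentLength(aln)
  profIds <- names(profiles)
  if (is.null(profIds) || !all(profIds %in% aln@ids))
    stop("profiles must be a named list keyed by alignment record ids")
  profIds <- aln@ids[aln@ids %in% profIds]  # alignment order
  K <- length(profIds)
  if (K < 1L) stop("no profiled records")
  enc <- .encodeAlignment(aln)[profIds, , drop = FALSE]
  lk <- .simLookup(sm, cfg@gapSimilarity)
  fam <- families(aln)[profIds]

  ut <- which(upper.tri(matrix(0, K, K)))
  pairIdx <- arrayInd(ut, c(K, K))  # (i, j) with i < j, column-major order
  simPairs <- matrix(0, length(ut), L)
  for (r in seq_len(nrow(pairIdx)))
    simPairs[r, ] <- lk[cbind(enc[pairIdx[r, 1], ], enc[pairIdx[r, 2], ])]

  # eligibility: donor j for query i (exclude self, optionally same family)
  elig <- matrix(1, K, K)
  diag(elig) <- 0
  if (cfg@excludeSameFamily)
    elig[outer(fam, fam, "==")] <- 0
  noDonor <- rowSums(elig) == 0

  first <- profiles[[profIds[1]]]
  D <- length(first@values)
  Pobs <- t(vapply(profIds, function(id) as.vector(profiles[[id]]@values),
                   numeric(D)))

  # similarity matrix for one mask (K x K, zero diagonal)
  simMatrix <- function(mask) {
    tot <- sum(mask)
    s <- if (tot == 0) numeric(length(ut)) else
      as.vector(simPairs %*% mask) / tot
    W <- matrix(0, K, K)
    W[ut] <- s
    W + t(W)
  }

  # donor weight matrix: w^alpha, eligibility applied, rows normalised;
  # all-zero eligible rows fall back to the unweighted donor mean.
  weightMatrix <- function(mask) {
    W <- simMatrix(mask)^cfg@alpha * elig
    rs <- rowSums(W)
    fallback <- rs == 0 & !noDonor
    if (any(fallback)) {
      W[fallback, ] <- elig[fallback, , drop = FALSE]
      rs[fallback] <- rowSums(elig[fallback, , drop = FALSE])
    }
    rs[rs == 0] <- 1  # no-donor rows stay all-zero; excluded downstream
    W / rs
  }

  # per-profiled-kinase leave-family-out prediction errors for one mask
  kinaseErrors <- function(mask) {
    Pred <- weightMatrix(mask) %*% Pobs
    err <- sqrt(rowSums((Pred - Pobs)^2))
    err[noDonor] <- NA_real_
    stats::setNames(err, profIds)
  }

  # vectorised over a population: masks as columns of an L x m matrix
  fitnessOfMasks <- function(maskMat) {
    apply(maskMat, 2L, function(m) stats::median(kinaseErrors(m), na.rm = TRUE))
  }

  list(profIds = profIds, fam = fam, noDonor = noDonor, Pobs = Pobs,
       first = first, K = K, L = L,
       simMatrix = simMatrix, weightMatrix = weightMatrix,
       kinaseErrors = kinaseErrors, fitnessOfMasks = fitnessOfMasks)
}

#' Predict a domain's specificity profile from its sequence
#'
#' Leave-family-out prediction: every profiled record outside the query's
#' family is a donor; donors are weighted by the alpha-sharpened mask-weighted
#' sequence similarity to the query, and the prediction is the weighted mean
#' of donor PSSMs, \eqn{\hat P_q = \sum_j w_j^\alpha P_j / \sum_j w_j^\alpha}.
#' If every donor weight is exactly zero the unweighted donor mean is returned,
#' so predictions stay defined for pathological masks.
#'
#' @param q record id of the query.
#' @param aln a [DomainAlignment-class].
#' @param profiles named list of [SpecificityProfile-class] (the donors; a
#'   profile for `q` itself is ignored as a donor).
#' @param mask a [SpecificityMask-class].
#' @param cfg a [PredictionConfig-class].
#' @param sm substitution matrix.
#' @return the predicted [SpecificityProfile-class] for `q`.
#' @export
predictProfile <- function(q, aln, profiles, mask, cfg = predictionConfig(),
                           sm = blosum62()) {
  if (!q %in% aln@ids) stop("query '", q, "' not in alignment")
  m <- maskScores(mask)
  if (length(m) != alignmentLength(aln))
    stop("mask length does not match alignment length")
  donorIds <- setdiff(names(profiles), q)
  if (cfg@excludeSameFamily) {
    fam <- families(aln)
    donorIds <- donorIds[fam[donorIds] != fam[q]]
  }
  if (length(donorIds) == 0L) stop("no donors for ", q)
  w <- vapply(donorIds, function(j)
    maskWeightedSimilarity(q, j, aln, mask, sm, cfg@gapSimilarity), 0)
  wa <- w^cfg@alpha
  if (sum(wa) == 0) wa <- rep(1, length(wa))  # unweighted-mean fallback
  wa <- wa / sum(wa)
  first <- profiles[[donorIds[1]]]
  acc <- matrix(0, nrow(first@values), 20L)
  for (k in seq_along(donorIds))
    acc <- acc + wa[k] * profiles[[donorIds[k]]]@values
  SpecificityProfile(q, acc, positions = first@positions, aas = first@aas)
}

#' Frobenius distance between two matrices or vectors
#'
#' The square root of the sum of squared elementwise differences — the measure
#' of dissimilarity used both for prediction fitness (predicted vs observed
#' PSSM) and for comparing specificity masks across runs.
#'
#' @param A,B numeric matrices or vectors of identical shape.
#' @return non-negative scalar; 0 iff `A == B`.
#' @examples
#' frobeniusDistance(c(0, 0), c(3, 4))  # 5
#' @export
frobeniusDistance <- function(A, B) {
  if (is.matrix(A) != is.matrix(B) ||
      (is.matrix(A) && !identical(dim(A), dim(B))) ||
      (!is.matrix(A) && length(A) != length(B)))
    stop("shape mismatch between A and B")
  sqrt(sum((A - B)^2))
}
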