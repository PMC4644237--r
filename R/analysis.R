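#' @include predictor.R
NULL

#' Call determinant-of-specificity columns by threshold
#'
#' @param scores a [DoSScoreVector-class] or numeric vector of per-column scores.
#' @param threshold in \[0, 1\]; columns with score strictly greater are called.
#' @return ascending 1-based column indices.
#' @examples
#' callDoS(c(0.95, 0.2, 0.91), 0.9)  # columns 1 and 3
#' @export
callDoS <- function(scores, threshold) {
  s <- if (is(scores, "DoSScoreVector")) dosScores(scores) else as.numeric(scores)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  which(s > threshold)
}

#' Sequence-to-specificity correlation on a column subset
#'
#' For every unordered pair of profiled domains, the pairwise sequence
#' similarity restricted to `subset` (sum of BLOSUM62 scores; gap-containing
#' pairs contribute the matrix minimum) is compared with the pairwise
#' specificity similarity (negative Frobenius distance between PSSMs) by
#' Spearman correlation with average-rank ties. A subset of true determinants
#' should maintain or increase the correlation relative to the whole domain.
#'
#' @param aln a [DomainAlignment-class].
#' @param profiles named list of >= 3 [SpecificityProfile-class].
#' @param subset non-empty 1-based column indices.
#' @param sm substitution matrix.
#' @return a [SubsetCorrelationReport-class]; `rho` is `NA` (with a warning)
#'   when either pairwise variable is constant.
#' @export
seqSpecCorrelation <- function(aln, profiles, subset, sm = blosum62()) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  L <- alignmentLength(aln)
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > L)) stop("subset columns must lie in 1..L")
  ids <- aln@ids[aln@ids %in% names(profiles)]
  K <- length(ids)
  if (K < 3L) stop("need >= 3 profiled kinases")
  sm <- .checkSubstitutionMatrix(sm)
  lkRaw <- matrix(min(sm), 21L, 21L)  # gap pairs at the matrix minimum
  lkRaw[1:20, 1:20] <- sm
  enc <- .encodeAlignment(aln)[ids, subset, drop = FALSE]
  x <- numeric(0); y <- numeric(0)
  for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K)) {
    x <- c(x, sum(lkRaw[cbind(enc[i, ], enc[j, ])]))
    y <- c(y, -frobeniusDistance(profiles[[ids[i]]]@values,
                                 profiles[[ids[j]]]@values))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant pairwise similarity vector; rho undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(x, y, method = "spearman")
  }
  new("SubsetCorrelationReport", subset = subset,
      nColumns = length(subset),
      fractionOfAlignment = length(subset) / L,
      rho = rho, nPairs = as.integer(K * (K - 1L) / 2L))
}

#' Enrichment of called columns in a golden list
#'
#' Builds the 2x2 table (called and golden, called only, golden only, neither)
#' over the `L` alignment columns and returns the one-sided (greater) Fisher
#' exact p — the hypergeometric tail — together with the sample odds ratio
#' `(a*d)/(b*c)`.
#'
#' @param called 1-based called columns.
#' @param golden 1-based literature-reported columns.
#' @param L alignment length.
#' @return list with `oddsRatio`, `p`, and the 2x2 `table`.
#' @export
enrichmentTest <- function(called, golden, L) {
  called <- unique(as.integer(called)); golden <- unique(as.integer(golden))
  if (length(union(called, golden)) > L)
    stop("L smaller than |called U golden|")
  if (length(c(called, golden)) &&
      (any(c(called, golden) < 1L) || any(c(called, golden) > L)))
    stop("column indices must lie in 1..L")
  a <- length(intersect(called, golden))
  b <- length(setdiff(called, golden))
  cc <- length(setdiff(golden, called))
  d <- L - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2L, 2L, byrow = TRUE,
                dimnames = list(c("called", "notCalled"),
                                c("golden", "notGolden")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- (a * d) / (b * cc)  # sample odds ratio; may be Inf or NaN at zeros
  list(oddsRatio = or, p = p, table = tab)
}

#' Per-column conservation and gap fraction
#'
#' Conservation is the negative Shannon entropy (base 2) of the amino-acid
#' frequency vector among non-gap symbols, so perfectly conserved columns
#' score 0 and maximally diverse columns approach -log2(20). All-gap columns
#' get `NA` conservation and gap fraction 1.
#'
#' @param aln a [DomainAlignment-class].
#' @return data.frame with `column` (1-based), `conservation`, `gapFraction`.
#' @export
columnConservation <- function(aln) {
  enc <- .encodeAlignment(aln)
  n <- nrow(enc)
  L <- ncol(enc)
  cons <- numeric(L); gapf <- numeric(L)
  for (p in seq_len(L)) {
    col <- enc[, p]
    gaps <- sum(col == 21L)
    gapf[p] <- gaps / n
    if (gaps == n) { cons[p] <- NA_real_; next }
    f <- tabulate(col[col != 21L], nbins = 20L)
    f <- f / sum(f)
    f <- f[f > 0]
    cons[p] <- sum(f * log2(f))  # negative entropy
  }
  data.frame(column = seq_len(L), conservation = cons, gapFraction = gapf)
}

## exact two-sided rank-sum p by enumeration of all group-A assignments of
## the pooled (average-rank) values; feasible for combined n <= 20
.exactRankSumP <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))  # average ranks for ties
  tObs <- sum(r[seq_len(m)])
  combs <- utils::combn(m + n, m)
  tAll <- colSums(matrix(r[combs], nrow = m))
  eps <- 1e-9
  pLe <- mean(tAll <= tObs + eps)
  pGe <- mean(tAll >= tObs - eps)
  min(1, 2 * min(pLe, pGe))
}

## normal approximation with tie correction and continuity correction
.approxRankSumP <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  tObs <- sum(r[seq_len(m)])
  N <- m + n
  mu <- m * (N + 1) / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tieAdj)
  if (sigma2 <= 0) return(1)
  z <- (abs(tObs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  2 * stats::pnorm(z, lower.tail = FALSE)
}

#' Compare conservation between two column sets
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of per-column
#' conservation values between two sets, e.g. called determinants versus the
#' whole domain or the kinase spines. Uses the exact null (full enumeration of
#' rank assignments, average-rank ties) for combined n <= 20 and a normal
#' approximation with tie and continuity correction above.
#'
#' @param setA,setB 1-based column index vectors.
#' @param cons per-column conservation values (e.g.
#'   `columnConservation(aln)$conservation`); `NA` columns are dropped.
#' @return list with `medianDifference` (median A minus median B), `p`, and
#'   `method` ("exact" or "normal approximation").
#' @export
compareConservation <- function(setA, setB, cons) {
  a <- cons[setA]; a <- a[!is.na(a)]
  b <- cons[setB]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("empty column set after dropping missing values")
  if (length(a) + length(b) <= 20L) {
    p <- .exactRankSumP(a, b)
    method <- "exact"
  } else {
    p <- .approxRankSumP(a, b)
    method <- "normal approximation"
  }
  list(medianDifference = stats::median(a) - stats::median(b),
       p = p, method = method)
}

#' Pairwise BLOSUM distance matrix over a column subset
#'
#' `d(i, j) = sum over subset columns of (maxScore - s(a_i, a_j))` where
#' `maxScore` is the substitution-matrix maximum (11 for BLOSUM62) and
#' gap-containing pairs are scored at the matrix minimum. Distances over all
#' columns give the whole-domain tree; distances over called DoS columns give
#' the specificity tree. This is a pseudo-distance: it is symmetric and
#' non-negative but may violate the triangle inequality, and identical
#' sequences have zero distance only when every subset residue attains the
#' matrix maximum (e.g. all-W).
#'
#' @param aln a [DomainAlignment-class].
#' @param subset non-empty 1-based columns.
#' @param sm substitution matrix.
#' @return symmetric K x K matrix with record-id dimnames.
#' @export
blosumDistanceMatrix <- function(aln, subset, sm = blosum62()) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  sm <- .checkSubstitutionMatrix(sm)
  subset <- as.integer(subset)
  L <- alignmentLength(aln)
  if (any(subset < 1L | subset > L)) stop("subset columns must lie in 1..L")
  lk <- matrix(min(sm), 21L, 21L)
  lk[1:20, 1:20] <- sm
  lk <- max(sm) - lk  # per-column distance contribution
  enc <- .encodeAlignment(aln)[, subset, drop = FALSE]
  K <- nrow(enc)
  d <- matrix(0, K, K, dimnames = list(aln@ids, aln@ids))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j < i) { d[i, j] <- d[j, i]; next }
    d[i, j] <- sum(lk[cbind(enc[i, ], enc[j, ])])
  }
  d
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape), used for both the whole-domain tree
#' and the DoS-only specificity tree. Negative branch lengths (possible on
#' non-additive pseudo-distances) are clamped to zero with a message. NJ
#' recovers the generating tree exactly on additive matrices.
#'
#' @param dist symmetric non-negative K x K matrix, K >= 3. Off-diagonal
#'   values are used; the diagonal is ignored.
#' @param labels optional tip labels (default: `rownames(dist)`).
#' @return an `ape::phylo` tree; write with `ape::write.tree()` for Newick.
#' @export
buildDendrogram <- function(dist, labels = rownames(dist)) {
  dist <- as.matrix(dist)
  K <- nrow(dist)
  if (K < 3L) stop("need >= 3 taxa for neighbor joining")
  if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
  if (any(dist < 0)) stop("distance matrix must be non-negative")
  if (is.null(labels)) labels <- paste0("t", seq_len(K))
  dimnames(dist) <- list(labels, labels)
  diag(dist) <- 0
  tree <- ape::nj(dist)
  if (any(tree$edge.length < 0)) {
    message("clamped ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
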