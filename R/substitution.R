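#' @include AllClasses.R
NULL

## cache for the Biostrings BLOSUM62 subset
.smEnv <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix over the 20 standard amino acids
#'
#' Subset of the BLOSUM62 matrix bundled with Biostrings, restricted to the 20
#' standard amino acids (extremes: min -4, max 11 at W/W). This is the default
#' matrix for positional similarity, pairwise distances and dendrograms.
#'
#' @return symmetric 20 x 20 numeric matrix with amino-acid dimnames.
#' @examples
#' sm <- blosum62()
#' sm["W", "W"]  # 11, the matrix maximum
#' @export
blosum62 <- function() {
  if (is.null(.smEnv$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .smEnv$blosum62 <- e$BLOSUM62[.AA20, .AA20]
  }
  .smEnv$blosum62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated format with a header row of
#' residue symbols and one labelled row per residue ('#' comments allowed),
#' returning the symmetric 20 x 20 block over the standard amino acids.
#'
#' @param path matrix file.
#' @return symmetric numeric matrix restricted to the 20 standard amino acids.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  keep <- intersect(.AA20, intersect(rownames(vals), colnames(vals)))
  if (length(keep) != 20L)
    stop("substitution matrix must cover all 20 standard amino acids")
  m <- vals[.AA20, .AA20]
  if (!isSymmetric(unname(m)))
    stop("substitution matrix is not symmetric")
  m
}

.checkSubstitutionMatrix <- function(sm) {
  if (!is.matrix(sm) || !all(.AA20 %in% rownames(sm)) ||
      !all(.AA20 %in% colnames(sm)))
    stop("substitution matrix must have the 20 standard amino acids as dimnames")
  sm <- sm[.AA20, .AA20]
  if (!isSymmetric(unname(sm))) stop("substitution matrix is not symmetric")
  sm
}
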