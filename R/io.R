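#' @include AllClasses.R
NULL

#' Read an aligned FASTA plus its annotation table
#'
#' @param path aligned FASTA (all records the same gapped length).
#' @param annotations TSV with header columns `id`, `family`, `group`
#'   (`group` optional); ids must match the FASTA exactly.
#' @return a [DomainAlignment-class]; record order follows the FASTA.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">k1", "ARND-", ">k2", "ARNDC"), fa)
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tfamily\tgroup", "k1\tfamA\tg1", "k2\tfamB\tg1"), tsv)
#' readAlignment(fa, tsv)
#' @export
readAlignment <- function(path, annotations) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)  # FASTA description after first whitespace
  sequences <- as.character(seqs)
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("id", "family") %in% names(ann)))
    stop("annotation table must have columns 'id' and 'family'")
  if (!"group" %in% names(ann)) ann$group <- ""
  orphanAnn <- setdiff(ann$id, ids)
  orphanFa <- setdiff(ids, ann$id)
  if (length(orphanAnn) || length(orphanFa))
    stop("id mismatch between FASTA and annotations; orphans: ",
         paste(c(orphanAnn, orphanFa), collapse = ", "))
  m <- match(ids, ann$id)
  DomainAlignment(ids = ids, sequences = sequences,
                  family = ann$family[m], group = ann$group[m])
}

#' Write/read an alignment (round-trip helpers)
#'
#' @param aln a [DomainAlignment-class].
#' @param fastaPath,annotationsPath output paths.
#' @return `invisible(NULL)`.
#' @export
writeAlignment <- function(aln, fastaPath, annotationsPath) {
  writeLines(paste0(">", aln@ids, "\n", aln@sequences), fastaPath)
  utils::write.table(
    data.frame(id = aln@ids, family = aln@family, group = aln@group,
               stringsAsFactors = FALSE),
    annotationsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a directory of PSSM tables
#'
#' Each file `<id>.tsv` is a numeric table: first column = peptide-position
#' label, header = 20 amino acids. All profiles must share the same position
#' labels in the same order. Coverage may be partial: profiles need exist only
#' for a subset of alignment records.
#'
#' @param dir directory of `.tsv` PSSM files.
#' @param alignment the [DomainAlignment-class] the profiles are keyed to.
#' @return named list of [SpecificityProfile-class], in alignment order.
#' @export
readProfiles <- function(dir, alignment) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) {
    warning("no profile tables found in ", dir,
            "; prediction will be impossible downstream")
    return(stats::setNames(list(), character(0)))
  }
  ids <- sub("\\.tsv$", "", basename(files))
  unknown <- setdiff(ids, sequenceIds(alignment))
  if (length(unknown))
    stop("profile id(s) not present in alignment: ",
         paste(unknown, collapse = ", "))
  profs <- lapply(seq_along(files), function(k) {
    tab <- utils::read.delim(files[k], check.names = FALSE,
                             stringsAsFactors = FALSE)
    pos <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals) || any(!is.finite(vals)))
      stop("non-numeric or non-finite cell in profile table ", files[k])
    SpecificityProfile(ids[k], vals, positions = pos, aas = colnames(vals))
  })
  names(profs) <- ids
  ref <- profs[[1]]@positions
  for (p in profs)
    if (!identical(p@positions, ref))
      stop("inconsistent positions across profiles: '", p@domainId,
           "' differs from '", profs[[1]]@domainId, "'")
  refAas <- profs[[1]]@aas
  for (p in profs)
    if (!identical(p@aas, refAas))
      stop("inconsistent amino-acid ordering across profiles: '",
           p@domainId, "'")
  # alignment order
  profs[order(match(names(profs), sequenceIds(alignment)))]
}

#' Write one PSSM table
#' @param profile a [SpecificityProfile-class].
#' @param path output TSV path.
#' @return `invisible(path)`.
#' @export
writeProfile <- function(profile, path) {
  tab <- data.frame(position = profile@positions,
                    profile@values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mask round-trip: TSV of (column, score) at full float precision
#'
#' Columns are written 1-based. `readMask(writeMask(m))` reproduces the mask
#' bit-exactly.
#'
#' @param mask a [SpecificityMask-class].
#' @param path file path.
#' @return `writeMask`: `invisible(path)`; `readMask`: a [SpecificityMask-class].
#' @export
writeMask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# specificity mask; columns are 1-based", con)
  writeLines("column\tscore", con)
  writeLines(sprintf("%d\t%.17g", seq_along(mask@scores), mask@scores), con)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  if (nrow(tab) == 0L) stop("empty mask")
  sc <- as.numeric(tab$score)
  if (any(!is.finite(sc)) || any(sc < 0 | sc > 1))
    stop("mask scores outside [0, 1] in ", path)
  SpecificityMask(sc[order(as.integer(tab$column))])
}

#' Write aggregated DoS scores as TSV
#' @param scores a [DoSScoreVector-class] or numeric vector.
#' @param path output TSV path.
#' @return `invisible(path)`.
#' @export
writeDoSScores <- function(scores, path) {
  s <- if (is(scores, "DoSScoreVector")) scores@scores else as.numeric(scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aggregated DoS scores; columns are 1-based", con)
  writeLines("column\tscore", con)
  writeLines(sprintf("%d\t%.17g", seq_along(s), s), con)
  invisible(path)
}

#' @rdname writeDoSScores
#' @export
readDoSScores <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  as.numeric(tab$score)[order(as.integer(tab$column))]
}
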