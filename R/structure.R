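#' @include AllClasses.R
NULL

## 3-letter -> 1-letter for the 20 standard residues
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

## ATOM records of one chain: standard residues only, hydrogens excluded,
## for duplicated altloc atoms keep the highest occupancy
.chainAtoms <- function(pdb, chain) {
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain &
             at$resid %in% names(.AA3), , drop = FALSE]
  if (nrow(at) == 0L) return(at)
  isH <- (!is.na(at$elesy) & toupper(at$elesy) == "H") |
    grepl("^[0-9]*H", at$elety)
  at <- at[!isH, , drop = FALSE]
  if (nrow(at) == 0L) return(at)
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key),
                          function(ix) ix[which.max(occ[ix])]))
    at <- at[sort(keep), , drop = FALSE]
  }
  at
}

#' Per-residue minimum distance from a kinase chain to a bound peptide
#'
#' For each amino-acid residue of the kinase chain (ATOM records, in file
#' order), the minimum Euclidean distance between any of its atoms and any
#' atom of the peptide chain. All-atom by default; `caOnly = TRUE` restricts
#' the kinase side to C-alpha atoms. First model only; for alternate locations
#' the highest-occupancy atom is used; hydrogens, waters, ligands and
#' non-standard residues are excluded.
#'
#' @param pdbPath PDB file.
#' @param kinaseChain,peptideChain chain identifiers.
#' @param caOnly use only C-alpha atoms on the kinase side.
#' @return data.frame with `residueIndex` (1-based order along the chain),
#'   `resno` (author residue number), `aa` (1-letter code) and `minDistance`
#'   (Angstrom).
#' @export
residueMinDistances <- function(pdbPath, kinaseChain, peptideChain,
                                caOnly = FALSE) {
  pdb <- suppressWarnings(bio3d::read.pdb(pdbPath, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  kin <- .chainAtoms(pdb, kinaseChain)
  pep <- .chainAtoms(pdb, peptideChain)
  if (nrow(kin) == 0L)
    stop("kinase chain '", kinaseChain, "' missing or has no amino-acid residues")
  if (nrow(pep) == 0L)
    stop("peptide chain '", peptideChain, "' missing or has no amino-acid residues")
  if (caOnly) {
    kin <- kin[kin$elety == "CA", , drop = FALSE]
    if (nrow(kin) == 0L) stop("no C-alpha atoms on kinase chain")
  }
  pepXyz <- as.matrix(pep[, c("x", "y", "z")])
  resKey <- paste(kin$resno, kin$insert, sep = "|")
  resOrder <- unique(resKey)
  out <- data.frame(residueIndex = seq_along(resOrder),
                    resno = kin$resno[match(resOrder, resKey)],
                    aa = unname(.AA3[kin$resid[match(resOrder, resKey)]]),
                    minDistance = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(resOrder)) {
    xyz <- as.matrix(kin[resKey == resOrder[k], c("x", "y", "z")])
    d2 <- outer(rowSums(xyz^2), rowSums(pepXyz^2), "+") -
      2 * xyz %*% t(pepXyz)
    out$minDistance[k] <- sqrt(max(0, min(d2)))
  }
  out
}

#' Map per-residue substrate distances onto alignment columns
#'
#' Each structure's kinase-chain residues are matched to its alignment record
#' by ungapped index correspondence (the i-th chain residue maps to the column
#' holding the record's i-th non-gap character). Sequence disagreement above
#' 5% makes a structure unmappable: it is skipped with a warning (hard error
#' if all structures are skipped). The per-column value is the minimum over
#' structures; columns with no mapped residue are `NA`.
#'
#' @param perStructure list of entries, each a list with `kinaseId` (alignment
#'   record id) and `distances` (a data.frame from [residueMinDistances()]).
#' @param aln a [DomainAlignment-class].
#' @return data.frame with `column` (1-based), `minDistance` and
#'   `nStructures` (number of structures contributing to that column).
#' @export
mapToColumns <- function(perStructure, aln) {
  L <- alignmentLength(aln)
  seqMat <- sequenceMatrix(aln)
  perCol <- matrix(NA_real_, length(perStructure), L)
  used <- 0L
  for (s in seq_along(perStructure)) {
    entry <- perStructure[[s]]
    id <- entry$kinaseId
    if (!id %in% aln@ids) {
      warning("structure ", s, ": kinase id '", id,
              "' not in alignment; skipped")
      next
    }
    rec <- seqMat[id, ]
    nonGap <- which(rec != .GAP)
    chainAa <- entry$distances$aa
    n <- min(length(chainAa), length(nonGap))
    mism <- sum(chainAa[seq_len(n)] != rec[nonGap[seq_len(n)]]) +
      abs(length(chainAa) - length(nonGap))
    denom <- max(length(chainAa), length(nonGap))
    if (mism / denom > 0.05) {
      warning("structure ", s, " ('", id, "'): ", mism, "/", denom,
              " sequence mismatches (> 5%); skipped")
      next
    }
    used <- used + 1L
    perCol[s, nonGap[seq_len(n)]] <- entry$distances$minDistance[seq_len(n)]
  }
  if (used == 0L) stop("no structure could be mapped onto the alignment")
  minD <- apply(perCol, 2L, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  nS <- colSums(!is.na(perCol))
  data.frame(column = seq_len(L), minDistance = minD, nStructures = nS)
}
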