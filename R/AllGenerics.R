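#' @include AllClasses.R
NULL

#' Accessors for SpecMask objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the relevant class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))
#' @rdname accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname accessors
#' @export
setGeneric("sequenceMatrix", function(x) standardGeneric("sequenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskScores", function(x) standardGeneric("maskScores"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @rdname accessors
#' @export
setGeneric("bestMask", function(x) standardGeneric("bestMask"))
#' @rdname accessors
#' @export
setGeneric("fitnessTrajectory", function(x) standardGeneric("fitnessTrajectory"))
#' @rdname accessors
#' @export
setGeneric("dosScores", function(x) standardGeneric("dosScores"))
#' @rdname accessors
#' @export
setGeneric("perRunBest", function(x) standardGeneric("perRunBest"))

#' @rdname accessors
#' @export
setMethod("sequenceIds", "DomainAlignment", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("families", "DomainAlignment", function(x) {
  stats::setNames(x@family, x@ids)
})
#' @rdname accessors
#' @export
setMethod("groups", "DomainAlignment", function(x) {
  stats::setNames(x@group, x@ids)
})
#' @rdname accessors
#' @export
setMethod("alignmentLength", "DomainAlignment", function(x) {
  nchar(x@sequences[1])
})
#' @rdname accessors
#' @export
setMethod("sequenceMatrix", "DomainAlignment", function(x) {
  m <- do.call(rbind, strsplit(x@sequences, ""))
  rownames(m) <- x@ids
  m
})
#' @rdname accessors
#' @export
setMethod("maskScores", "SpecificityMask", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("alignmentLength", "SpecificityMask", function(x) length(x@scores))
#' @rdname accessors
#' @export
setMethod("profileValues", "SpecificityProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("domainId", "SpecificityProfile", function(x) x@domainId)
#' @rdname accessors
#' @export
setMethod("bestMask", "EvolutionResult", function(x) x@bestMask)
#' @rdname accessors
#' @export
setMethod("fitnessTrajectory", "EvolutionResult", function(x) {
  x@bestFitnessTrajectory
})
#' @rdname accessors
#' @export
setMethod("dosScores", "DoSScoreVector", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("perRunBest", "DoSScoreVector", function(x) x@perRunBest)

setMethod("show", "DomainAlignment", function(object) {
  cat("DomainAlignment:", length(object@ids), "records x",
      alignmentLength(object), "columns;",
      length(unique(object@family)), "families\n")
  cat("  ids:", paste(utils::head(object@ids, 5), collapse = ", "),
      if (length(object@ids) > 5) "..." else "", "\n")
})

setMethod("show", "SpecificityProfile", function(object) {
  cat("SpecificityProfile for", object@domainId, ":",
      length(object@positions), "peptide positions x 20 amino acids\n")
})

setMethod("show", "SpecificityMask", function(object) {
  cat("SpecificityMask over", length(object@scores), "columns; ",
      sum(object@scores > 0.9), "columns > 0.9\n")
})

setMethod("show", "EvolutionResult", function(object) {
  tr <- object@bestFitnessTrajectory
  cat("EvolutionResult:", object@generationsRun, "generations (seed",
      object@seed, ")\n  best fitness:", format(tr[1], digits = 5), "->",
      format(tr[length(tr)], digits = 5), "\n")
})

setMethod("show", "DoSScoreVector", function(object) {
  cat("DoSScoreVector over", length(object@scores), "columns, aggregated from",
      object@nRuns, "runs;", sum(object@scores > 0.9), "columns > 0.9\n")
})

setMethod("show", "SubsetCorrelationReport", function(object) {
  cat("Sequence-to-specificity correlation on", object@nColumns,
      "columns (", sprintf("%.2f%%", 100 * object@fractionOfAlignment),
      "of alignment): Spearman rho =",
      format(object@rho, digits = 4), "over", object@nPairs, "pairs\n")
})
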