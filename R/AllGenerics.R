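#' @include AllClasses.R
NULL

#' Accessors for LysisTyper classes
#'
#' \code{accession}, \code{genomeName}, \code{genomeSequence},
#' \code{geneFeatures}, \code{taxonomy}, \code{hostSpecies} read the slots of
#' a \link{PhageGenome}; \code{moduleMembers}, \code{roleSignature},
#' \code{organizationLabel}, \code{intercalatedCount}, \code{moduleDirection}
#' those of a \link{LysisModule}; \code{canonicalArchitecture},
#' \code{architectureLabel}, \code{hasEAD}, \code{hasCBD} those of an
#' \link{EndolysinArchitecture}; \code{tmdSegments}, \code{tmdCount},
#' \code{tcdbFamily} those of a \link{HolinProfile}.
#'
#' @param x An object of the respective class.
#' @return The slot value.
#' @name accessors
#' @aliases accession genomeName genomeSequence geneFeatures taxonomy
#'   hostSpecies moduleMembers roleSignature organizationLabel
#'   intercalatedCount moduleDirection canonicalArchitecture architectureLabel
#'   hasEAD hasCBD tmdSegments tmdCount tcdbFamily truthGenomes
#'   truthEndolysins truthHolins truthOverlaps
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))
#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("hostSpecies", function(x) standardGeneric("hostSpecies"))
#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setGeneric("roleSignature", function(x) standardGeneric("roleSignature"))
#' @rdname accessors
#' @export
setGeneric("organizationLabel", function(x) standardGeneric("organizationLabel"))
#' @rdname accessors
#' @export
setGeneric("intercalatedCount", function(x) standardGeneric("intercalatedCount"))
#' @rdname accessors
#' @export
setGeneric("moduleDirection", function(x) standardGeneric("moduleDirection"))
#' @rdname accessors
#' @export
setGeneric("canonicalArchitecture", function(x) standardGeneric("canonicalArchitecture"))
#' @rdname accessors
#' @export
setGeneric("architectureLabel", function(x) standardGeneric("architectureLabel"))
#' @rdname accessors
#' @export
setGeneric("hasEAD", function(x) standardGeneric("hasEAD"))
#' @rdname accessors
#' @export
setGeneric("hasCBD", function(x) standardGeneric("hasCBD"))
#' @rdname accessors
#' @export
setGeneric("tmdSegments", function(x) standardGeneric("tmdSegments"))
#' @rdname accessors
#' @export
setGeneric("tmdCount", function(x) standardGeneric("tmdCount"))
#' @rdname accessors
#' @export
setGeneric("tcdbFamily", function(x) standardGeneric("tcdbFamily"))
#' @rdname accessors
#' @export
setGeneric("truthGenomes", function(x) standardGeneric("truthGenomes"))
#' @rdname accessors
#' @export
setGeneric("truthEndolysins", function(x) standardGeneric("truthEndolysins"))
#' @rdname accessors
#' @export
setGeneric("truthHolins", function(x) standardGeneric("truthHolins"))
#' @rdname accessors
#' @export
setGeneric("truthOverlaps", function(x) standardGeneric("truthOverlaps"))

#' @rdname accessors
#' @export
setMethod("accession", "PhageGenome", function(x) x@accession)
#' @rdname accessors
#' @export
setMethod("genomeName", "PhageGenome", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("genomeSequence", "PhageGenome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("geneFeatures", "PhageGenome", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("taxonomy", "PhageGenome", function(x) x@taxonomy)
#' @rdname accessors
#' @export
setMethod("hostSpecies", "PhageGenome", function(x) x@hostSpecies)
#' @export
setMethod("length", "PhageGenome", function(x) length(x@sequence))

#' @rdname accessors
#' @export
setMethod("moduleMembers", "LysisModule", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("roleSignature", "LysisModule", function(x) x@roleSignature)
#' @rdname accessors
#' @export
setMethod("organizationLabel", "LysisModule", function(x) x@organizationLabel)
#' @rdname accessors
#' @export
setMethod("intercalatedCount", "LysisModule", function(x) x@intercalatedCount)
#' @rdname accessors
#' @export
setMethod("moduleDirection", "LysisModule", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("canonicalArchitecture", "EndolysinArchitecture", function(x) x@canonical)
#' @rdname accessors
#' @export
setMethod("architectureLabel", "EndolysinArchitecture", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("hasEAD", "EndolysinArchitecture", function(x) x@hasEAD)
#' @rdname accessors
#' @export
setMethod("hasCBD", "EndolysinArchitecture", function(x) x@hasCBD)

#' @rdname accessors
#' @export
setMethod("tmdSegments", "HolinProfile", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("tmdCount", "HolinProfile", function(x) x@tmdCount)
#' @rdname accessors
#' @export
setMethod("tcdbFamily", "HolinProfile", function(x) x@tcdbFamily)

#' @rdname accessors
#' @export
setMethod("truthGenomes", "SyntheticTruth", function(x) x@genomes)
#' @rdname accessors
#' @export
setMethod("truthEndolysins", "SyntheticTruth", function(x) x@endolysins)
#' @rdname accessors
#' @export
setMethod("truthHolins", "SyntheticTruth", function(x) x@holins)
#' @rdname accessors
#' @export
setMethod("truthOverlaps", "SyntheticTruth", function(x) x@overlaps)

setMethod("show", "PhageGenome", function(object) {
  cat("PhageGenome", object@accession,
      sprintf("(%s)", object@name),
      sprintf("| %d nt | %d CDS features\n",
              length(object@sequence), length(object@features)))
  roles <- table(mcols(object@features)$role)
  roles <- roles[roles > 0L]
  if (length(roles))
    cat("  roles:", paste(names(roles), roles, sep = "=", collapse = " "), "\n")
})

setMethod("show", "LysisModule", function(object) {
  cat(sprintf("LysisModule [%s] signature=%s organization=%s direction=%s (%d members, %d intercalated)\n",
              object@genomeId, object@roleSignature, object@organizationLabel,
              object@direction, length(object@members),
              object@intercalatedCount))
})

setMethod("show", "EndolysinArchitecture", function(object) {
  cat(sprintf("EndolysinArchitecture %s: %s [label=%s, EAD=%s, CBD=%s]\n",
              object@proteinId, object@canonical,
              ifelse(is.na(object@label), "-", object@label),
              object@hasEAD, object@hasCBD))
})

setMethod("show", "HolinProfile", function(object) {
  segs <- if (length(object@segments))
    paste(sprintf("%d-%d", start(object@segments), end(object@segments)),
          collapse = ",") else "none"
  cat(sprintf("HolinProfile %s: %d TMD(s) [%s], family %s\n",
              object@proteinId, object@tmdCount, segs, object@tcdbFamily))
})

setMethod("show", "PanelSpec", function(object) {
  cat("PanelSpec:",
      sum(object@organizationMix) + object@nSpQs1, "genomes | mix:",
      paste(names(object@organizationMix), object@organizationMix,
            sep = "=", collapse = " "),
      sprintf("| SP-QS1-like=%d | seed=%d\n", object@nSpQs1, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (seed %d): %d genomes, %d endolysins, %d holins, %d overlap pairs\n",
              object@seed, nrow(object@genomes), nrow(object@endolysins),
              nrow(object@holins), nrow(object@overlaps)))
})
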