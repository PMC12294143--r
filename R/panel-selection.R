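#' @include AllClasses.R utils.R
NULL

#' Select a taxonomically representative genome panel
#'
#' One accession is kept per named genus (the highest-priority one; ties break
#' to the lexicographically smallest accession) and every accession whose
#' genus is \code{"unassigned"} is systematically included. The selection rule
#' is rank-based; the judgment of which genome best represents a genus
#' (citation frequency, lysis-module complexity, ...) is injected through the
#' optional priority score and defaults to uniform.
#'
#' @param records data.frame with columns \code{accession} and \code{genus}
#'   (use \code{"unassigned"} for genus-unassigned phages); other taxonomy
#'   columns are carried along untouched.
#' @param priority Optional named numeric vector, accession -> score (higher
#'   wins within a genus).
#' @return Sorted character vector of selected accessions.
#' @export
selectRepresentatives <- function(records, priority = NULL) {
  if (!nrow(records)) stop("records must be nonempty")
  if (anyDuplicated(records$accession))
    stop("duplicate accessions in taxonomy records")
  score <- rep(0, nrow(records))
  if (!is.null(priority)) {
    s <- priority[records$accession]
    score <- ifelse(is.na(s), 0, s)
  }
  genus <- records$genus
  genus[is.na(genus) | !nzchar(genus)] <- "unassigned"
  keep <- genus == "unassigned"
  for (g in unique(genus[genus != "unassigned"])) {
    idx <- which(genus == g)
    best <- idx[order(-score[idx], records$accession[idx])][1L]
    keep[best] <- TRUE
  }
  sort(records$accession[keep])
}

#' Read a taxonomy table
#'
#' TSV with columns \code{accession}, \code{v_class}, \code{family},
#' \code{subfamily}, \code{genus}, \code{species} (missing ranks may be
#' \code{"unassigned"}).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readTaxonomyTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
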