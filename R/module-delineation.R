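#' @include AllClasses.R utils.R lexicons.R
NULL

.SIG_SYMBOL <- c(holin = "H", endolysin = "E", endonuclease = "N",
                 hypothetical = "X", other = "X", unassigned = "X")

#' Delineate lysis modules in a genome
#'
#' Scans features in genomic order and merges successive lysis-role genes
#' (holin/endolysin anchors) into one module when each junction spans at most
#' \code{maxIntercalated} non-lysis ORFs and at most \code{maxGapNt} of
#' intergenic distance. A candidate run must contain at least one holin and
#' one endolysin to count as a module. When a genome carries both roles but no
#' run satisfies the tolerance (the widely separated layout), the result is
#' empty and carries a \code{diagnostics} attribute reporting the minimum
#' number of ORFs intervening between any holin/endolysin pair.
#'
#' Module members are stored in transcription-direction order; the signature
#' uses H (holin), E (endolysin), N (endonuclease), X (other intercalated).
#'
#' @param genome A \link{PhageGenome} with roles assigned
#'   (\code{\link{classifyRoles}}).
#' @param maxIntercalated Maximum non-lysis ORFs tolerated per junction
#'   (default 2).
#' @param maxGapNt Maximum intergenic distance (nt) per junction (default 1000).
#' @return list of \link{LysisModule}, possibly with attribute
#'   \code{diagnostics} (data.frame genome_id / intervening_count).
#' @export
delineateModules <- function(genome, maxIntercalated = 2L, maxGapNt = 1000L) {
  ft <- geneFeatures(genome)
  roles <- mcols(ft)$role
  anchors <- which(roles %in% c("holin", "endolysin"))
  out <- list()
  if (length(anchors) == 0L) return(out)

  # chain anchors under the junction tolerance
  chains <- list(anchors[1L])
  if (length(anchors) > 1L) {
    for (k in 2L:length(anchors)) {
      a <- anchors[k - 1L]; b <- anchors[k]
      nInter <- b - a - 1L
      gapOK <- all(start(ft)[(a + 1L):b] - end(ft)[a:(b - 1L)] - 1L <= maxGapNt)
      if (nInter <= maxIntercalated && gapOK)
        chains[[length(chains)]] <- c(chains[[length(chains)]], b)
      else
        chains[[length(chains) + 1L]] <- b
    }
  }

  for (ch in chains) {
    idx <- seq(min(ch), max(ch))
    r <- roles[idx]
    if (!any(r == "holin") || !any(r == "endolysin")) next
    mem <- ft[idx]
    str <- unique(as.character(strand(mem)))
    direction <- if (identical(str, "+")) "forward"
      else if (identical(str, "-")) "reverse" else "mixed"
    if (direction == "reverse") mem <- rev(mem)
    sig <- paste(.SIG_SYMBOL[mcols(mem)$role], collapse = "")
    out[[length(out) + 1L]] <- new("LysisModule",
      genomeId = accession(genome), members = mem, roleSignature = sig,
      organizationLabel = "unclassified",
      intercalatedCount = sum(strsplit(sig, "")[[1L]] %in% c("N", "X")),
      direction = direction)
  }

  if (!length(out) && any(roles == "holin") && any(roles == "endolysin")) {
    hs <- which(roles == "holin"); es <- which(roles == "endolysin")
    interv <- min(outer(hs, es, function(a, b) abs(b - a) - 1L))
    attr(out, "diagnostics") <- data.frame(
      genome_id = accession(genome), intervening_count = interv,
      stringsAsFactors = FALSE)
  }
  out
}

.patternRegex <- function(pattern) {
  paste0("^", gsub("\\(([A-Z])\\)", "(?:\\1)?", pattern), "$")
}

#' Classify a lysis module against the organization catalogue
#'
#' The module signature, with X symbols dropped, is matched against the
#' catalogue patterns in catalogue order; the first match wins. Intercalated
#' endonucleases (N) only match where a pattern licenses them, e.g.
#' \code{"H(N)E"}. No match leaves the label \code{"unclassified"}.
#'
#' @param module A \link{LysisModule}.
#' @param catalogue Catalogue data.frame
#'   (\code{\link{defaultOrganizationCatalogue}}).
#' @return The module with \code{organizationLabel} filled.
#' @export
classifyOrganization <- function(module,
                                 catalogue = defaultOrganizationCatalogue()) {
  sig <- gsub("X", "", module@roleSignature)
  lab <- "unclassified"
  for (i in seq_len(nrow(catalogue))) {
    if (grepl(.patternRegex(catalogue$pattern[i]), sig)) {
      lab <- catalogue$label[i]
      break
    }
  }
  module@organizationLabel <- lab
  module
}

#' Gene-order and organization statistics over a module panel
#'
#' A module is holin-first when its first lysis-role member (H/E projection)
#' is a holin.
#'
#' @param modules list of \link{LysisModule} (classified or not).
#' @return list with \code{fractions} (named numeric: holin_first,
#'   endolysin_first), \code{n_modules}, and \code{histogram} (named integer
#'   counts per organization label). An empty panel yields zeros.
#' @export
orderStatistics <- function(modules) {
  if (!length(modules)) {
    return(list(fractions = c(holin_first = 0, endolysin_first = 0),
                n_modules = 0L, histogram = integer(0)))
  }
  firstAnchor <- vapply(modules, function(m) {
    sy <- strsplit(m@roleSignature, "")[[1L]]
    sy[sy %in% c("H", "E")][1L]
  }, character(1L))
  labs <- vapply(modules, organizationLabel, character(1L))
  hf <- mean(firstAnchor == "H")
  list(fractions = c(holin_first = hf, endolysin_first = 1 - hf),
       n_modules = length(modules),
       histogram = table(labs))
}
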