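#' @include AllClasses.R
NULL

#' Default role lexicon
#'
#' Maps product-string keywords and domain names to lysis roles. Keywords are
#' matched case-insensitively as whole word tokens, so \code{"lysin"} never
#' fires inside \code{"holin"}. The lexicon is an ordinary list and may be
#' edited, or serialized with \code{\link{writeRoleLexicon}} /
#' \code{\link{readRoleLexicon}}.
#'
#' @return list with elements \code{keywords} (named character: keyword ->
#'   role) and \code{domains} (named character: domain name -> role).
#' @export
defaultRoleLexicon <- function() {
  domains <- defaultDomainLexicon()
  dom <- stats::setNames(rep("endolysin", nrow(domains)), domains$domain_name)
  dom <- c(dom,
           Phage_holin_1 = "holin",
           Phage_holin_2 = "holin",
           Phage_holin_3 = "holin")
  list(
    keywords = c(
      holin = "holin",
      endolysin = "endolysin",
      lysin = "endolysin",
      lysozyme = "endolysin",
      amidase = "endolysin",
      muramidase = "endolysin",
      endonuclease = "endonuclease",
      hypothetical = "hypothetical"
    ),
    domains = dom
  )
}

#' Default endolysin domain lexicon
#'
#' Maps domain names to their role (enzymatically active domain, EAD, or
#' cell-wall-binding domain, CBD) and enzymatic activity. Covers the domains
#' commonly reported for streptococcal phage endolysins; extensible via
#' \code{rbind} or the YAML helpers.
#'
#' @return data.frame with columns \code{domain_name}, \code{role}
#'   (\code{"EAD"}/\code{"CBD"}) and \code{activity}.
#' @export
defaultDomainLexicon <- function() {
  data.frame(
    domain_name = c("Amidase_5", "NLPC_P60", "CHAP", "Glucosaminidase",
                    "Glyco_hydro_25", "PGRP", "PlyCA",
                    "ZoocinA_TRD", "pneumo_PspA", "CW_7", "SH3_5", "LysM",
                    "PlyCB"),
    role = c(rep("EAD", 7L), rep("CBD", 6L)),
    activity = c("amidase", "endopeptidase", "CHAP", "glucosaminidase",
                 "lysozyme", "amidase", "unknown",
                 rep("unknown", 6L)),
    stringsAsFactors = FALSE
  )
}

#' Default lysis-module organization catalogue
#'
#' Five organizations over holin (H) and endolysin (E) genes in transcription
#' order: A = H,E; B = H,H,E; C = H,E with an optionally intercalated
#' endonuclease (N); D = E,H; E = E,E,H. A to C are holin-first, D and E
#' endolysin-first. Matching walks the catalogue in order, so a C module
#' without its endonuclease is signature-identical to A and classifies as A.
#'
#' @return data.frame with columns \code{label}, \code{pattern} (signature
#'   over H/E with optional symbols in parentheses) and \code{holin_first}.
#' @export
defaultOrganizationCatalogue <- function() {
  data.frame(
    label = c("A", "B", "C", "D", "E"),
    pattern = c("HE", "HHE", "H(N)E", "EH", "EEH"),
    holin_first = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reference endolysin architecture table (synthetic reconstruction)
#'
#' Twenty-five distinct N-to-C domain layouts with panel counts summing to
#' 256, used as the default planting list of the synthetic generator. The
#' text-documented constraints hold: the most common layout is
#' \code{Amidase_5 & NLPC_P60 & ZoocinA_TRD}, the runner-up is
#' \code{ZoocinA_TRD} alone, one layout places a CW_7 motif between its
#' catalytic domains, exactly seven layouts lack a CBD, exactly three lack an
#' EAD, counts are non-increasing, and the twelve rarest layouts are
#' singletons. The table itself is a synthetic stand-in for an upset-plot
#' census that is not distributed in machine-readable form.
#'
#' @return data.frame with columns \code{canonical} and \code{count}.
#' @export
referenceArchitectures <- function() {
  path <- system.file("extdata", "architecture_reference_synthetic.tsv",
                      package = "LysisTyper", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read or write a role lexicon as YAML
#'
#' @param path File path.
#' @param lexicon A lexicon list as returned by \code{\link{defaultRoleLexicon}}.
#' @return \code{readRoleLexicon} returns the lexicon list;
#'   \code{writeRoleLexicon} returns \code{path} invisibly.
#' @export
readRoleLexicon <- function(path) {
  x <- yaml::read_yaml(path)
  list(keywords = unlist(x$keywords), domains = unlist(x$domains))
}

#' @rdname readRoleLexicon
#' @export
writeRoleLexicon <- function(lexicon, path) {
  yaml::write_yaml(list(keywords = as.list(lexicon$keywords),
                        domains = as.list(lexicon$domains)), path)
  invisible(path)
}
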