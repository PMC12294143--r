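#' @include AllClasses.R utils.R lexicons.R
NULL

.ROLE_PRECEDENCE <- c("holin", "endolysin", "endonuclease")

## Pick one role from a set of candidate roles, by fixed precedence.
.pickRole <- function(roles) {
  hit <- .ROLE_PRECEDENCE[.ROLE_PRECEDENCE %in% roles]
  if (length(hit)) hit[1L] else NA_character_
}

.keywordRole <- function(product, lexicon) {
  tok <- productTokens(product)
  kw <- lexicon$keywords[names(lexicon$keywords) %in% tok]
  main <- .pickRole(unname(kw))
  list(role = if (!is.na(main)) main
         else if (any(kw == "hypothetical")) "hypothetical" else NA_character_,
       tags = if (length(kw)) paste0("keyword:", names(kw)) else character(0))
}

.domainRole <- function(domainNames, lexicon) {
  dm <- lexicon$domains[names(lexicon$domains) %in% domainNames]
  list(role = .pickRole(unname(dm)),
       tags = if (length(dm)) paste0("domain:", unique(names(dm))) else character(0))
}

#' Assign a lysis role to one gene feature
#'
#' Role assignment follows a precedence: (1) product-string keyword, (2) domain
#' evidence from filtered hits, (3) supplemental-evidence rows. When keyword
#' and domain evidence name different lysis roles the keyword wins with a
#' warning (the annotation is treated as the curated signal); set
#' \code{evidenceFirst = TRUE} to flip that precedence. Features matching
#' nothing but a \code{hypothetical} keyword become \code{hypothetical};
#' everything else becomes \code{other}.
#'
#' @param product Product string of the feature.
#' @param domainNames Character vector of domain names hit by the feature's
#'   protein (already E-value filtered; see \code{\link{parseDomtblout}}).
#' @param lexicon Role lexicon (\code{\link{defaultRoleLexicon}}).
#' @param supplementalSubjects Subjects from a supplemental evidence table
#'   already filtered to qualifying rows for this protein.
#' @param evidenceFirst Give domain evidence precedence over keywords.
#' @return list(role =, evidence = character vector of tags).
#' @export
classifyGeneRole <- function(product, domainNames = character(0),
                             lexicon = defaultRoleLexicon(),
                             supplementalSubjects = character(0),
                             evidenceFirst = FALSE) {
  kw <- .keywordRole(product, lexicon)
  dom <- .domainRole(domainNames, lexicon)
  sup <- .domainRole(supplementalSubjects, lexicon)
  sup$tags <- sub("^domain:", "supplemental:", sup$tags)

  kwMain <- if (!is.na(kw$role) && kw$role != "hypothetical") kw$role else NA
  order <- if (evidenceFirst) list(dom$role, kwMain, sup$role)
           else list(kwMain, dom$role, sup$role)
  role <- NA_character_
  tags <- character(0)
  for (i in seq_along(order)) {
    if (!is.na(order[[i]])) { role <- order[[i]]; break }
  }
  if (!is.na(kwMain) && !is.na(dom$role) && kwMain != dom$role)
    warning("keyword role '", kwMain, "' conflicts with domain role '",
            dom$role, "' for product '", product, "'; precedence rule applied")
  if (is.na(role))
    role <- if (identical(kw$role, "hypothetical")) "hypothetical" else "other"
  used <- c(if (!is.na(kwMain) || identical(kw$role, "hypothetical")) kw$tags,
            if (!is.na(dom$role)) dom$tags,
            if (!is.na(sup$role)) sup$tags)
  list(role = role, evidence = unique(c(tags, used)))
}

#' Assign lysis roles to all features of a genome
#'
#' Vectorized wrapper around \code{\link{classifyGeneRole}}.
#'
#' @param genome A \link{PhageGenome}.
#' @param hits Domain-hit data.frame from \code{\link{parseDomtblout}} (may be
#'   NULL); matched to features by \code{protein_id == feature_id}.
#' @param lexicon Role lexicon.
#' @param supplemental Supplemental evidence data.frame with columns
#'   \code{protein_id}, \code{subject}, \code{evalue} (and optionally
#'   \code{identity_pct}); rows with \code{evalue >= eCutoff} are ignored.
#' @param evidenceFirst See \code{\link{classifyGeneRole}}.
#' @param eCutoff E-value cutoff applied to supplemental rows (default 0.01).
#' @return The genome with \code{role} and \code{role_evidence} filled.
#' @export
classifyRoles <- function(genome, hits = NULL,
                          lexicon = defaultRoleLexicon(),
                          supplemental = NULL, evidenceFirst = FALSE,
                          eCutoff = 0.01) {
  ft <- geneFeatures(genome)
  if (!length(ft)) return(genome)
  sup <- .filterSupplemental(supplemental, eCutoff,
                             known = mcols(ft)$feature_id)
  roles <- character(length(ft))
  ev <- vector("list", length(ft))
  for (i in seq_along(ft)) {
    id <- mcols(ft)$feature_id[i]
    dn <- if (!is.null(hits) && nrow(hits))
      hits$domain_name[hits$protein_id == id] else character(0)
    ss <- if (nrow(sup)) sup$subject[sup$protein_id == id] else character(0)
    r <- classifyGeneRole(mcols(ft)$product[i], dn, lexicon, ss, evidenceFirst)
    roles[i] <- r$role
    ev[[i]] <- r$evidence
  }
  mcols(ft)$role <- roles
  mcols(ft)$role_evidence <- CharacterList(ev)
  genome@features <- ft
  validObject(genome)
  genome
}

.filterSupplemental <- function(supplemental, eCutoff, known = NULL) {
  empty <- data.frame(protein_id = character(0), subject = character(0),
                      evalue = numeric(0))
  if (is.null(supplemental) || !nrow(supplemental)) return(empty)
  sup <- supplemental[supplemental$evalue < eCutoff, , drop = FALSE]
  if (!is.null(known)) {
    unknown <- !(sup$protein_id %in% known)
    if (any(unknown)) {
      warning(sum(unknown), " supplemental row(s) reference unknown proteins; skipped")
      sup <- sup[!unknown, , drop = FALSE]
    }
  }
  sup
}

#' Augment an endolysin architecture with supplemental domain evidence
#'
#' Adds domains reported by a supplemental hit table (CDD/BLASTp-style rows:
#' \code{protein_id}, \code{subject}, \code{evalue}, optional
#' \code{identity_pct}) that the primary hit table missed. Rows failing the
#' E-value cutoff or naming other proteins are skipped. Added domains carry no
#' alignment coordinates and are appended after coordinate-bearing ones, in
#' table order. The architecture's activity set is re-derived from the
#' lexicon, so a PGRP gain records amidase activity.
#'
#' @param arch An \link{EndolysinArchitecture}.
#' @param supplemental Supplemental evidence data.frame.
#' @param lexicon Domain lexicon (\code{\link{defaultDomainLexicon}}).
#' @param eCutoff E-value cutoff (default 0.01).
#' @return The augmented \link{EndolysinArchitecture}.
#' @export
applySupplementalEvidence <- function(arch, supplemental,
                                      lexicon = defaultDomainLexicon(),
                                      eCutoff = 0.01) {
  sup <- .filterSupplemental(supplemental, eCutoff)
  sup <- sup[sup$protein_id == arch@proteinId, , drop = FALSE]
  sup <- sup[!(sup$subject %in% arch@domains$domain_name), , drop = FALSE]
  if (!nrow(sup)) return(arch)
  idx <- match(sup$subject, lexicon$domain_name)
  add <- data.frame(
    domain_name = sup$subject,
    role = ifelse(is.na(idx), "unknown", lexicon$role[idx]),
    activity = ifelse(is.na(idx), "unknown", lexicon$activity[idx]),
    ali_from = NA_integer_, ali_to = NA_integer_,
    stringsAsFactors = FALSE)
  d <- rbind(arch@domains[, names(add)], add)
  new("EndolysinArchitecture",
      proteinId = arch@proteinId, domains = d,
      canonical = paste(d$domain_name, collapse = " & "),
      hasEAD = any(d$role == "EAD"), hasCBD = any(d$role == "CBD"),
      label = arch@label)
}
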