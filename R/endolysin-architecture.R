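#' @include AllClasses.R utils.R lexicons.R
NULL

## ---- HMMER3 per-domain table I/O --------------------------------------------

#' Parse a HMMER3 domtblout table into filtered domain hits
#'
#' Reads the whitespace-separated per-domain dialect ('#' comment lines
#' ignored; target = domain model, query = protein). Rows whose independent
#' (per-domain) E-value is >= \code{eCutoff} are dropped; surviving rows are
#' annotated with role (EAD/CBD) and activity from the domain lexicon, unknown
#' domain names keeping role \code{"unknown"}. Malformed rows are skipped with
#' a counted warning; a file whose every row is malformed is an error.
#'
#' @param path Path to the domtblout file.
#' @param eCutoff Independent E-value cutoff; hits qualify when strictly below
#'   it (default 0.01).
#' @param lexicon Domain lexicon (\code{\link{defaultDomainLexicon}}).
#' @return data.frame of hits: \code{protein_id}, \code{domain_name},
#'   \code{source_db}, \code{ali_from}, \code{ali_to}, \code{e_value},
#'   \code{bit_score}, \code{role}, \code{activity}.
#' @export
parseDomtblout <- function(path, eCutoff = 0.01,
                           lexicon = defaultDomainLexicon()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rows <- list()
  bad <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(tok) < 19L) { bad <- bad + 1L; next }
    ev <- suppressWarnings(as.numeric(tok[13L]))
    sc <- suppressWarnings(as.numeric(tok[14L]))
    af <- suppressWarnings(as.integer(tok[18L]))
    at <- suppressWarnings(as.integer(tok[19L]))
    if (anyNA(c(ev, sc, af, at)) || af < 1L || at < af) { bad <- bad + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = tok[4L], domain_name = tok[1L], source_db = tok[2L],
      ali_from = af, ali_to = at, e_value = ev, bit_score = sc,
      stringsAsFactors = FALSE)
  }
  if (bad > 0L) {
    if (!length(rows)) stop("all ", bad, " data rows are malformed: ", path)
    warning(bad, " malformed row(s) skipped in ", path)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), domain_name = character(0),
               source_db = character(0), ali_from = integer(0),
               ali_to = integer(0), e_value = numeric(0),
               bit_score = numeric(0), stringsAsFactors = FALSE)
  hits <- hits[hits$e_value < eCutoff, , drop = FALSE]
  annotateHits(hits, lexicon)
}

#' Annotate domain hits with lexicon role and activity
#'
#' @param hits Hit data.frame (at least \code{domain_name}).
#' @param lexicon Domain lexicon.
#' @return hits with \code{role} and \code{activity} columns.
#' @export
annotateHits <- function(hits, lexicon = defaultDomainLexicon()) {
  idx <- match(hits$domain_name, lexicon$domain_name)
  hits$role <- ifelse(is.na(idx), "unknown", lexicon$role[idx])
  hits$activity <- ifelse(is.na(idx), "unknown", lexicon$activity[idx])
  rownames(hits) <- NULL
  hits
}

#' Write domain hits in the domtblout dialect
#'
#' Emits the 23-column HMMER3 per-domain layout this package parses (used by
#' the synthetic generator).
#'
#' @param hits Hit data.frame (\code{protein_id}, \code{domain_name},
#'   \code{ali_from}, \code{ali_to}, \code{e_value}, \code{bit_score}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDomtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target", con)
  for (i in seq_len(nrow(hits))) {
    len <- hits$ali_to[i] - hits$ali_from[i] + 1L
    writeLines(paste(
      hits$domain_name[i], "-", len, hits$protein_id[i], "-", 400L,
      format(hits$e_value[i], scientific = TRUE), hits$bit_score[i], "0.1",
      1L, 1L,
      format(hits$e_value[i], scientific = TRUE),
      format(hits$e_value[i], scientific = TRUE),
      hits$bit_score[i], "0.1",
      1L, len, hits$ali_from[i], hits$ali_to[i],
      hits$ali_from[i], hits$ali_to[i], "0.98", "-",
      sep = " "), con)
  }
  invisible(path)
}

## ---- architecture building --------------------------------------------------

#' Resolve overlapping domain hits on one protein
#'
#' When two hits overlap by more than \code{maxOverlapFrac} of the shorter
#' hit, the lower-E-value hit survives; ties break by higher bit score, then
#' lexicographic domain name (so exact duplicates collapse to one).
#'
#' @param hits Hit data.frame, all rows on one protein.
#' @param maxOverlapFrac Tolerated overlap fraction of the shorter hit
#'   (default 0.5).
#' @return The surviving hits, in ali_from order.
#' @export
resolveOverlaps <- function(hits, maxOverlapFrac = 0.5) {
  if (!nrow(hits)) return(hits)
  if (length(unique(hits$protein_id)) > 1L)
    stop("resolveOverlaps expects hits on a single protein")
  o <- order(hits$e_value, -hits$bit_score, hits$domain_name)
  hits <- hits[o, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in keep) {
      ov <- min(hits$ali_to[i], hits$ali_to[j]) -
            max(hits$ali_from[i], hits$ali_from[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(hits$ali_to[i] - hits$ali_from[i],
                     hits$ali_to[j] - hits$ali_from[j]) + 1L
      if (ov / shorter > maxOverlapFrac) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  res <- hits[keep, , drop = FALSE]
  res <- res[order(res$ali_from, res$domain_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the canonical N-to-C architecture of one endolysin
#'
#' Domains are ordered strictly by alignment start (overlap resolution first;
#' see \code{\link{resolveOverlaps}}); the canonical string joins domain names
#' with \code{" & "}. An empty hit list yields canonical \code{"(none)"} with
#' both presence flags FALSE.
#'
#' @param proteinId Protein identifier.
#' @param hits Overlap-resolved hit data.frame; rows naming other proteins are
#'   an error.
#' @return An \link{EndolysinArchitecture}.
#' @export
buildArchitecture <- function(proteinId, hits) {
  if (nrow(hits)) {
    if (!all(hits$protein_id == proteinId))
      stop("hits from multiple proteins passed to buildArchitecture")
    d <- hits[order(hits$ali_from, hits$domain_name, na.last = TRUE),
              c("domain_name", "role", "activity", "ali_from", "ali_to"),
              drop = FALSE]
    rownames(d) <- NULL
    new("EndolysinArchitecture", proteinId = proteinId, domains = d,
        canonical = paste(d$domain_name, collapse = " & "),
        hasEAD = any(d$role == "EAD"), hasCBD = any(d$role == "CBD"))
  } else {
    new("EndolysinArchitecture", proteinId = proteinId,
        domains = data.frame(domain_name = character(0), role = character(0),
                             activity = character(0), ali_from = integer(0),
                             ali_to = integer(0), stringsAsFactors = FALSE),
        canonical = "(none)", hasEAD = FALSE, hasCBD = FALSE)
  }
}

#' Build architectures for a whole hit table
#'
#' Convenience wrapper: splits hits by protein, resolves overlaps and builds
#' one \link{EndolysinArchitecture} per protein.
#'
#' @param hits Annotated hit data.frame (\code{\link{parseDomtblout}}).
#' @param proteinIds Proteins to build for; defaults to those present in
#'   \code{hits}. Proteins without hits yield \code{"(none)"} architectures.
#' @param maxOverlapFrac Passed to \code{\link{resolveOverlaps}}.
#' @return Named list of \link{EndolysinArchitecture}.
#' @export
buildArchitectures <- function(hits, proteinIds = NULL, maxOverlapFrac = 0.5) {
  if (is.null(proteinIds)) proteinIds <- unique(hits$protein_id)
  out <- lapply(proteinIds, function(p) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    buildArchitecture(p, resolveOverlaps(h, maxOverlapFrac))
  })
  stats::setNames(out, proteinIds)
}

#' Frequency-rank architectures into panel-relative labels
#'
#' Distinct canonical strings are counted and labeled A1, A2, ... by
#' decreasing count; count ties break lexicographically on the canonical
#' string. Labels are relative to the supplied panel.
#'
#' @param panel list of \link{EndolysinArchitecture}.
#' @return list with \code{panel} (labels filled) and \code{table}
#'   (data.frame: label, canonical, count, non-increasing count order).
#' @export
rankArchitectures <- function(panel) {
  if (!length(panel))
    return(list(panel = panel,
                table = data.frame(label = character(0),
                                   canonical = character(0),
                                   count = integer(0))))
  can <- vapply(panel, canonicalArchitecture, character(1L))
  tab <- as.data.frame(table(can), stringsAsFactors = FALSE)
  names(tab) <- c("canonical", "count")
  tab <- tab[order(-tab$count, tab$canonical), , drop = FALSE]
  tab$label <- sprintf("A%d", seq_len(nrow(tab)))
  tab <- tab[, c("label", "canonical", "count")]
  rownames(tab) <- NULL
  lab <- stats::setNames(tab$label, tab$canonical)
  panel <- lapply(panel, function(a) { a@label <- unname(lab[a@canonical]); a })
  list(panel = panel, table = tab)
}

#' Upset-style combination table of an architecture panel
#'
#' @param panel Labeled list of \link{EndolysinArchitecture} (run
#'   \code{\link{rankArchitectures}} first; unlabeled panels are labeled on
#'   the fly).
#' @return list with \code{matrix} (one row per distinct architecture: label,
#'   canonical, count, plus a 0/1 presence column per domain) and
#'   \code{marginals} (named integer: per-domain frequency over all
#'   endolysins, i.e. presence weighted by row counts).
#' @export
upsetTable <- function(panel) {
  if (!length(panel))
    return(list(matrix = data.frame(), marginals = integer(0)))
  if (anyNA(vapply(panel, architectureLabel, character(1L))))
    panel <- rankArchitectures(panel)$panel
  tab <- rankArchitectures(panel)$table
  doms <- sort(unique(unlist(lapply(panel, function(a) a@domains$domain_name))))
  pres <- t(vapply(tab$canonical, function(cn) {
    parts <- strsplit(cn, " & ", fixed = TRUE)[[1L]]
    as.integer(doms %in% parts)
  }, integer(length(doms))))
  colnames(pres) <- doms
  mat <- cbind(tab, as.data.frame(pres, check.names = FALSE))
  rownames(mat) <- NULL
  marg <- stats::setNames(as.integer(colSums(pres * tab$count)), doms)
  list(matrix = mat, marginals = marg)
}

#' Flag incomplete architectures and report genome co-occurrence partners
#'
#' Flags architectures lacking an EAD or a CBD. For every EAD-less
#' architecture, reports the partner architectures co-encoded in the same
#' genome; an EAD-less endolysin without a catalytically active partner is an
#' exception needing supplemental evidence.
#'
#' @param archByGenome Named list: genome id -> list of
#'   \link{EndolysinArchitecture} encoded by that genome.
#' @return list with \code{flags} (per endolysin: genome_id, protein_id,
#'   label, canonical, no_EAD, no_CBD) and \code{cooccurrence} (per EAD-less
#'   endolysin: partners, comma-separated partner canonicals; exception flag).
#' @export
flagAndCooccur <- function(archByGenome) {
  flags <- list(); co <- list()
  for (g in names(archByGenome)) {
    archs <- archByGenome[[g]]
    for (a in archs) {
      flags[[length(flags) + 1L]] <- data.frame(
        genome_id = g, protein_id = a@proteinId,
        label = a@label, canonical = a@canonical,
        no_EAD = !a@hasEAD, no_CBD = !a@hasCBD, stringsAsFactors = FALSE)
      if (!a@hasEAD) {
        partners <- Filter(function(b) b@proteinId != a@proteinId && b@hasEAD,
                           archs)
        pc <- vapply(partners, canonicalArchitecture, character(1L))
        co[[length(co) + 1L]] <- data.frame(
          genome_id = g, protein_id = a@proteinId, label = a@label,
          canonical = a@canonical,
          partners = paste(pc, collapse = ","),
          exception = length(pc) == 0L, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(genome_id = character(0)),
    cooccurrence = if (length(co)) do.call(rbind, co) else
      data.frame(genome_id = character(0), protein_id = character(0),
                 label = character(0), canonical = character(0),
                 partners = character(0), exception = logical(0))
  )
}
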