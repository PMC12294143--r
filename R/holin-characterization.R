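#' @include AllClasses.R utils.R
NULL

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyteDoolittleScale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Default hydropathy/TMD-calling parameters
#'
#' Window 19 and threshold 1.6 are the classical Kyte-Doolittle settings for
#' membrane-spanning segments; \code{minTmdLen} (15 aa) is the minimum length
#' of a reported segment and \code{minGap} (5) the minimum separation between
#' above-threshold runs before they are merged.
#'
#' @return list(scale, window, threshold, minTmdLen, minGap).
#' @export
defaultHydropathyParams <- function() {
  list(scale = kyteDoolittleScale(), window = 19L, threshold = 1.6,
       minTmdLen = 15L, minGap = 5L)
}

#' Smoothed per-residue hydropathy series
#'
#' Centered moving average of the scale values; windows are truncated at the
#' protein ends so the series has one value per residue. Unknown residue
#' symbols contribute hydropathy 0 with a warning. A protein shorter than the
#' window gets its global mean at every position.
#'
#' @param protein Amino-acid string.
#' @param params See \code{\link{defaultHydropathyParams}}.
#' @return Numeric vector, one value per residue.
#' @export
hydropathyProfile <- function(protein, params = defaultHydropathyParams()) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  v <- unname(params$scale[aa])
  if (anyNA(v)) {
    warning(sum(is.na(v)), " unknown residue symbol(s) treated as hydropathy 0")
    v[is.na(v)] <- 0
  }
  L <- length(v)
  if (L < params$window) return(rep(mean(v), L))
  h <- (params$window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Predict transmembrane segments of a holin from hydropathy
#'
#' Maximal runs of residues whose smoothed hydropathy meets the threshold are
#' the candidate cores; runs separated by fewer than \code{minGap} residues
#' are merged; each core is then expanded by the window half-width on both
#' sides (the window mean reflects the whole window, not only its center),
#' clipped to the protein and truncated at the midpoint where two expansions
#' would collide; segments shorter than \code{minTmdLen} are discarded. A
#' protein with no surviving segment is reported with a "no-TMD holin
#' candidate" warning.
#'
#' @param protein Amino-acid string.
#' @param params See \code{\link{defaultHydropathyParams}}.
#' @param proteinId Identifier stored in the profile.
#' @param genomeId Optional genome of origin.
#' @return A \link{HolinProfile} (family left \code{"unclassified"}; see
#'   \code{\link{assignFamily}}).
#' @export
predictTmds <- function(protein, params = defaultHydropathyParams(),
                        proteinId = "protein", genomeId = NA_character_) {
  prof <- hydropathyProfile(protein, params)
  L <- length(prof)
  above <- prof >= params$threshold
  segs <- matrix(integer(0), ncol = 2L)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # merge runs separated by fewer than minGap residues
    merged <- runs[1L, , drop = FALSE]
    for (k in seq_len(nrow(runs))[-1L]) {
      if (runs[k, 1L] - merged[nrow(merged), 2L] - 1L < params$minGap)
        merged[nrow(merged), 2L] <- runs[k, 2L]
      else merged <- rbind(merged, runs[k, , drop = FALSE])
    }
    h <- (params$window - 1L) %/% 2L
    ex <- cbind(pmax(merged[, 1L] - h, 1L), pmin(merged[, 2L] + h, L))
    if (nrow(ex) > 1L) {
      for (k in seq_len(nrow(ex) - 1L)) {
        if (ex[k, 2L] >= ex[k + 1L, 1L]) {
          mid <- (merged[k, 2L] + merged[k + 1L, 1L]) %/% 2L
          ex[k, 2L] <- mid
          ex[k + 1L, 1L] <- mid + 1L
        }
      }
    }
    keep <- (ex[, 2L] - ex[, 1L] + 1L) >= params$minTmdLen
    segs <- ex[keep, , drop = FALSE]
  }
  if (!nrow(segs))
    warning("no-TMD holin candidate: ", proteinId)
  new("HolinProfile", proteinId = proteinId,
      segments = IRanges(start = segs[, 1L], end = segs[, 2L]),
      tmdCount = nrow(segs), tcdbFamily = "unclassified",
      genomeId = genomeId)
}

#' Assign a TCDB family from a transporter hit table
#'
#' Rows carry a subject TCDB accession (\code{class.subclass.family.<...>});
#' the family is the first three dot-separated fields. The best qualifying hit
#' (lowest E-value, ties by higher bit score, then lexicographic subject)
#' determines the family; no qualifying hit leaves the holin
#' \code{"unclassified"}. Rows whose subject does not yield a valid family
#' string are skipped with a warning.
#'
#' @param proteinId Protein identifier.
#' @param tcdbHits data.frame with columns \code{protein_id}, \code{subject},
#'   \code{evalue}, \code{bitscore} (tabular BLASTp dialect).
#' @param eCutoff E-value cutoff (default 0.01, strict).
#' @return Family string such as \code{"1.E.10"}, or \code{"unclassified"}.
#' @export
assignFamily <- function(proteinId, tcdbHits, eCutoff = 0.01) {
  if (is.null(tcdbHits) || !nrow(tcdbHits)) return("unclassified")
  h <- tcdbHits[tcdbHits$protein_id == proteinId & tcdbHits$evalue < eCutoff,
                , drop = FALSE]
  if (!nrow(h)) return("unclassified")
  fam <- vapply(strsplit(h$subject, ".", fixed = TRUE), function(p) {
    if (length(p) >= 3L) paste(p[1:3], collapse = ".") else NA_character_
  }, character(1L))
  bad <- is.na(fam) | !grepl("^[0-9]+\\.[A-Z]+\\.[0-9]+$", fam)
  if (any(bad)) {
    warning(sum(bad), " TCDB row(s) with malformed family skipped")
    h <- h[!bad, , drop = FALSE]; fam <- fam[!bad]
  }
  if (!nrow(h)) return("unclassified")
  o <- order(h$evalue, -h$bitscore, h$subject)
  fam[o][1L]
}

#' Tandem-holin and family-consistency report
#'
#' Three checks over a panel of holin profiles: (1) every genome encoding two
#' holins should carry proteins from two different families (pairs involving
#' an unclassified holin are indeterminate); (2) within each family all
#' members should share one TMD count; (3) genomes whose two holins both have
#' a single TMD are listed. Violations are reported, never dropped.
#'
#' @param profiles list of \link{HolinProfile} with families assigned.
#' @return list with data.frames \code{tandem} (genome_id, families, status),
#'   \code{family_consistency} (family, tmd_counts, n, status) and
#'   \code{single_tmd_pairs} (genome_id).
#' @export
tandemConsistencyReport <- function(profiles) {
  gid <- vapply(profiles, function(p) p@genomeId, character(1L))
  fam <- vapply(profiles, tcdbFamily, character(1L))
  cnt <- vapply(profiles, tmdCount, integer(1L))

  tandem <- list(); singles <- list()
  for (g in unique(gid[!is.na(gid)])) {
    idx <- which(gid == g)
    if (length(idx) != 2L) next
    f <- fam[idx]
    status <- if (any(f == "unclassified")) "indeterminate"
      else if (f[1L] != f[2L]) "pass" else "violation"
    tandem[[length(tandem) + 1L]] <- data.frame(
      genome_id = g, families = paste(sort(f), collapse = "/"),
      status = status, stringsAsFactors = FALSE)
    if (all(cnt[idx] == 1L))
      singles[[length(singles) + 1L]] <- data.frame(genome_id = g,
                                                    stringsAsFactors = FALSE)
  }

  famTab <- lapply(sort(unique(fam)), function(f) {
    counts <- sort(unique(cnt[fam == f]))
    data.frame(family = f,
               tmd_counts = paste(counts, collapse = ","),
               n = sum(fam == f),
               status = if (length(counts) == 1L) "consistent" else "violation",
               stringsAsFactors = FALSE)
  })

  list(
    tandem = if (length(tandem)) do.call(rbind, tandem) else
      data.frame(genome_id = character(0), families = character(0),
                 status = character(0)),
    family_consistency = do.call(rbind, famTab),
    single_tmd_pairs = if (length(singles)) do.call(rbind, singles) else
      data.frame(genome_id = character(0))
  )
}
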