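#' @include AllClasses.R utils.R
NULL

#' Detect overlapping (overprinted) gene pairs in a genome
#'
#' Every pair of features whose nucleotide spans intersect by at least 1 nt
#' yields one record. Offsets are measured in the transcription direction of
#' the upstream gene (5' to 3'): on the plus strand the upstream gene is the
#' one with the smaller start and \code{start_offset_nt} is the start-to-start
#' distance; on the minus strand the upstream gene is the one with the larger
#' end and the offset is the distance between the two 5' ends. Because the
#' phrase "starting N nt downstream" admits a second reading, the record also
#' carries \code{junction_offset_nt}, the distance from the downstream gene's
#' 5' start to the upstream gene's 3' end (the overlap junction). For
#' opposite-strand pairs \code{frame_offset} is reported as \code{NA}.
#'
#' @param genome A \link{PhageGenome} with roles assigned.
#' @param rolesFilter Restrict to pairs where both members carry one of these
#'   roles; default \code{"endolysin"} (endolysin-endolysin pairs). Use
#'   \code{NULL} for all pairs.
#' @return data.frame: genome_id, upstream_id, downstream_id, start_offset_nt,
#'   overlap_len_nt, junction_offset_nt, frame_offset, same_strand.
#' @export
detectOverlaps <- function(genome, rolesFilter = "endolysin") {
  ft <- geneFeatures(genome)
  empty <- data.frame(genome_id = character(0), upstream_id = character(0),
                      downstream_id = character(0),
                      start_offset_nt = integer(0), overlap_len_nt = integer(0),
                      junction_offset_nt = integer(0), frame_offset = integer(0),
                      same_strand = logical(0))
  if (!is.null(rolesFilter))
    ft <- ft[mcols(ft)$role %in% rolesFilter]
  if (length(ft) < 2L) return(empty)
  hp <- GenomicRanges::findOverlaps(ft, minoverlap = 1L,
                                    drop.self = TRUE, drop.redundant = TRUE,
                                    ignore.strand = TRUE)
  if (!length(hp)) return(empty)
  rows <- lapply(seq_along(hp), function(k) {
    i <- S4Vectors::queryHits(hp)[k]; j <- S4Vectors::subjectHits(hp)[k]
    si <- as.character(strand(ft))[i]; sj <- as.character(strand(ft))[j]
    same <- si == sj
    # upstream in transcription direction of the pair
    if (same && si == "-") {
      up <- if (end(ft)[i] >= end(ft)[j]) i else j
    } else {
      up <- if (start(ft)[i] <= start(ft)[j]) i else j
    }
    dn <- if (up == i) j else i
    # 5'-to-5' distance along the upstream gene's transcription direction
    off <- if (same && si == "-") end(ft)[up] - end(ft)[dn]
           else start(ft)[dn] - start(ft)[up]
    ovl <- min(end(ft)[i], end(ft)[j]) - max(start(ft)[i], start(ft)[j]) + 1L
    # downstream 5' start relative to the upstream 3' end (overlap junction)
    junc <- if (same && si == "-") end(ft)[dn] - start(ft)[up]
            else end(ft)[up] - start(ft)[dn]
    data.frame(genome_id = accession(genome),
               upstream_id = mcols(ft)$feature_id[up],
               downstream_id = mcols(ft)$feature_id[dn],
               start_offset_nt = as.integer(off),
               overlap_len_nt = as.integer(ovl),
               junction_offset_nt = as.integer(junc),
               frame_offset = if (same) as.integer(off %% 3L) else NA_integer_,
               same_strand = same, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
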