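#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges start end strand seqnames width
#' @importFrom Biostrings DNAString DNAStringSet AAString
NULL

## Central container: one annotated phage genome. CDS features are kept in a
## GRanges (1-based inclusive, GenBank convention) whose mcols carry
## feature_id, product, protein_seq, role and role_evidence.

#' PhageGenome: an annotated phage genome
#'
#' Holds the genome sequence plus its CDS features. Features are stored in a
#' \link[GenomicRanges]{GRanges} sorted by start coordinate, with metadata
#' columns \code{feature_id}, \code{product}, \code{protein_seq} (NA when no
#' translation is available), \code{role} (one of \code{holin},
#' \code{endolysin}, \code{endonuclease}, \code{hypothetical}, \code{other},
#' \code{unassigned}) and \code{role_evidence} (a \code{CharacterList} of
#' evidence tags).
#'
#' @slot accession Genome accession/identifier.
#' @slot name Free-text genome name.
#' @slot sequence A \link[Biostrings]{DNAString} with the genome sequence.
#' @slot features A \code{GRanges} of CDS features (see Details).
#' @slot taxonomy Named character vector over ranks
#'   \code{c("v_class","family","subfamily","genus","species")}; any rank may
#'   be \code{"unassigned"}.
#' @slot hostSpecies Host species, or \code{NA_character_}.
#'
#' @export
setClass("PhageGenome",
  representation(
    accession = "character",
    name = "character",
    sequence = "DNAString",
    features = "GRanges",
    taxonomy = "character",
    hostSpecies = "character"
  )
)

.ROLE_LEVELS <- c("holin", "endolysin", "endonuclease", "hypothetical",
                  "other", "unassigned")

.validPhageGenome <- function(object) {
  msg <- character(0)
  ft <- object@features
  L <- length(object@sequence)
  if (length(object@accession) != 1L || is.na(object@accession))
    msg <- c(msg, "accession must be a single non-NA string")
  need <- c("feature_id", "product", "protein_seq", "role", "role_evidence")
  miss <- setdiff(need, colnames(mcols(ft)))
  if (length(miss))
    msg <- c(msg, paste0("features lack mcols: ", paste(miss, collapse = ", ")))
  if (length(ft)) {
    if (any(start(ft) < 1L) || any(end(ft) > L))
      msg <- c(msg, "feature coordinates fall outside [1, genome length]")
    if (!length(miss)) {
      ids <- mcols(ft)$feature_id
      if (anyDuplicated(ids))
        msg <- c(msg, "feature identifiers are not unique")
      if (is.unsorted(start(ft)))
        msg <- c(msg, "features must be sorted by start coordinate")
      bad <- setdiff(unique(mcols(ft)$role), .ROLE_LEVELS)
      if (length(bad))
        msg <- c(msg, paste0("invalid role value(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhageGenome", .validPhageGenome)

#' LysisModule: an ordered run of genes forming a lysis cassette
#'
#' Members are stored in transcription-direction order (for reverse-strand
#' modules the genomic order is reversed). The role signature is a string over
#' \code{H} (holin), \code{E} (endolysin), \code{N} (endonuclease) and
#' \code{X} (any other intercalated ORF).
#'
#' @slot genomeId Accession of the genome the module belongs to.
#' @slot members \code{GRanges} of member features in transcription order.
#' @slot roleSignature Signature string, one symbol per member.
#' @slot organizationLabel Catalogue label (e.g. \code{"A"}) or
#'   \code{"unclassified"}.
#' @slot intercalatedCount Number of N/X symbols in the signature.
#' @slot direction \code{"forward"}, \code{"reverse"} or \code{"mixed"}.
#'
#' @export
setClass("LysisModule",
  representation(
    genomeId = "character",
    members = "GRanges",
    roleSignature = "character",
    organizationLabel = "character",
    intercalatedCount = "integer",
    direction = "character"
  ),
  prototype(organizationLabel = "unclassified")
)

.validLysisModule <- function(object) {
  msg <- character(0)
  sig <- object@roleSignature
  if (nchar(sig) != length(object@members))
    msg <- c(msg, "signature length must equal member count")
  sy <- strsplit(sig, "")[[1]]
  if (!all(sy %in% c("H", "E", "N", "X")))
    msg <- c(msg, "signature may only contain H, E, N, X")
  if (sum(sy == "H") < 1L || sum(sy == "E") < 1L)
    msg <- c(msg, "a module needs at least one holin and one endolysin")
  if (object@intercalatedCount != sum(sy %in% c("N", "X")))
    msg <- c(msg, "intercalatedCount inconsistent with signature")
  if (!object@direction %in% c("forward", "reverse", "mixed"))
    msg <- c(msg, "direction must be forward/reverse/mixed")
  if (length(msg)) msg else TRUE
}
setValidity("LysisModule", .validLysisModule)

#' EndolysinArchitecture: the canonical N-to-C domain layout of one endolysin
#'
#' @slot proteinId Protein (feature) identifier.
#' @slot domains data.frame with columns \code{domain_name}, \code{role}
#'   (EAD/CBD/unknown), \code{activity}, \code{ali_from}, \code{ali_to},
#'   ordered N to C.
#' @slot canonical Domain names joined by \code{" & "}; \code{"(none)"} when
#'   no domain survived filtering.
#' @slot hasEAD,hasCBD Presence flags derived from the lexicon roles.
#' @slot label Panel-relative frequency label (\code{"A1"} ...), empty until
#'   \code{\link{rankArchitectures}} runs.
#'
#' @export
setClass("EndolysinArchitecture",
  representation(
    proteinId = "character",
    domains = "data.frame",
    canonical = "character",
    hasEAD = "logical",
    hasCBD = "logical",
    label = "character"
  ),
  prototype(label = NA_character_)
)

.validEndolysinArchitecture <- function(object) {
  msg <- character(0)
  d <- object@domains
  need <- c("domain_name", "role", "activity", "ali_from", "ali_to")
  if (!all(need %in% colnames(d)))
    msg <- c(msg, "domains data.frame lacks required columns")
  else if (nrow(d)) {
    if (is.unsorted(stats::na.omit(d$ali_from)))
      msg <- c(msg, "domains must be ordered by ali_from (N to C)")
    if (object@canonical != paste(d$domain_name, collapse = " & "))
      msg <- c(msg, "canonical string inconsistent with ordered domains")
    if (object@hasEAD != any(d$role == "EAD") ||
        object@hasCBD != any(d$role == "CBD"))
      msg <- c(msg, "hasEAD/hasCBD inconsistent with domain roles")
  } else {
    if (object@canonical != "(none)" || object@hasEAD || object@hasCBD)
      msg <- c(msg, "empty architecture must be '(none)' with flags FALSE")
  }
  if (length(msg)) msg else TRUE
}
setValidity("EndolysinArchitecture", .validEndolysinArchitecture)

#' HolinProfile: predicted transmembrane segments and family of one holin
#'
#' @slot proteinId Protein identifier.
#' @slot segments \link[IRanges]{IRanges} of predicted TMD segments (aa
#'   coordinates), non-overlapping.
#' @slot tmdCount Number of segments.
#' @slot tcdbFamily Transporter Classification Database family such as
#'   \code{"1.E.10"}, or \code{"unclassified"}.
#' @slot genomeId Genome of origin (may be \code{NA}).
#'
#' @export
setClass("HolinProfile",
  representation(
    proteinId = "character",
    segments = "IRanges",
    tmdCount = "integer",
    tcdbFamily = "character",
    genomeId = "character"
  ),
  prototype(tcdbFamily = "unclassified", genomeId = NA_character_)
)

.validHolinProfile <- function(object) {
  msg <- character(0)
  seg <- object@segments
  if (object@tmdCount != length(seg))
    msg <- c(msg, "tmdCount must equal the number of segments")
  if (length(seg) > 1L) {
    o <- order(start(seg))
    if (any(start(seg)[o][-1L] <= end(seg)[o][-length(seg)]))
      msg <- c(msg, "TMD segments must not overlap")
  }
  fam <- object@tcdbFamily
  if (!(fam == "unclassified" || grepl("^1\\.E\\.[0-9]+$", fam)))
    msg <- c(msg, "tcdbFamily must match 1.E.<integer> or be 'unclassified'")
  if (length(msg)) msg else TRUE
}
setValidity("HolinProfile", .validHolinProfile)

#' PanelSpec: parameters of the synthetic phage-genome generator
#'
#' The defaults returned by \code{\link{defaultPanelSpec}} encode the study
#' conditions the package emulates: 34 genomes, 33 of them carrying one lysis
#' cassette drawn from the five-organization catalogue (mix A=20, B=5, C=3,
#' D=3, E=2, giving a 28/33 = 85\% holin-first split) plus one genome whose
#' holin and endolysin are separated by 18 unrelated genes.
#'
#' @slot seed Integer seed; regeneration with the same spec is byte-identical.
#' @slot organizationMix Named integer vector, catalogue label -> genome count.
#' @slot nSpQs1 Number of genomes with the widely separated (no-module) layout.
#' @slot spQs1Intervening Number of decoy ORFs between holin and endolysin in
#'   those genomes (default 18).
#' @slot decoyRange Integer length-2: min/max decoy ORFs flanking each cassette.
#' @slot architectures Character vector of canonical endolysin domain layouts
#'   (\code{"Amidase_5 & NLPC_P60 & ZoocinA_TRD"} style) cycled across
#'   endolysin ORFs.
#' @slot holinFamilies TCDB families (or \code{"unclassified"}) cycled across
#'   holin ORFs; the family fixes the planted TMD count.
#' @slot overlapOffsetNt Start-to-start offset (nt) of the planted overlapping
#'   endolysin pair in the first two-endolysin genome; \code{NA} disables it.
#' @slot noise Probability that a decoy ORF receives a decoy domain hit; all
#'   such hits carry E-values >= 0.01 so the default filter removes them.
#' @slot obfuscate Probability that a planted lysis gene's product string is
#'   replaced by \code{"hypothetical protein"} (exercises evidence rescue).
#' @slot minusFraction Probability that a cassette is laid on the minus strand.
#'
#' @export
setClass("PanelSpec",
  representation(
    seed = "integer",
    organizationMix = "integer",
    nSpQs1 = "integer",
    spQs1Intervening = "integer",
    decoyRange = "integer",
    architectures = "character",
    holinFamilies = "character",
    overlapOffsetNt = "integer",
    noise = "numeric",
    obfuscate = "numeric",
    minusFraction = "numeric"
  )
)

.validPanelSpec <- function(object) {
  msg <- character(0)
  if (any(object@organizationMix < 0L))
    msg <- c(msg, "organization counts must be nonnegative")
  if (is.null(names(object@organizationMix)) && length(object@organizationMix))
    msg <- c(msg, "organizationMix must be named by catalogue label")
  if (object@nSpQs1 < 0L) msg <- c(msg, "nSpQs1 must be nonnegative")
  for (p in c("noise", "obfuscate", "minusFraction")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste0(p, " must lie in [0,1]"))
  }
  if (length(object@decoyRange) != 2L || any(object@decoyRange < 0L) ||
      object@decoyRange[1L] > object@decoyRange[2L])
    msg <- c(msg, "decoyRange must be a nondecreasing nonnegative pair")
  if (length(msg)) msg else TRUE
}
setValidity("PanelSpec", .validPanelSpec)

#' SyntheticTruth: the planted ground truth of a generated panel
#'
#' @slot seed Seed the panel was generated from.
#' @slot genomes data.frame: \code{genome_id}, \code{organization} (planted
#'   label or \code{"none"}), \code{signature}, \code{intercalated_count},
#'   \code{cassette_strand}, \code{host_species}.
#' @slot endolysins data.frame: \code{protein_id}, \code{genome_id},
#'   \code{architecture} (canonical planted layout).
#' @slot holins data.frame: \code{protein_id}, \code{genome_id},
#'   \code{tmd_count}, \code{tcdb_family}, \code{segments} (dash/comma coded).
#' @slot overlaps data.frame: \code{genome_id}, \code{upstream_id},
#'   \code{downstream_id}, \code{start_offset_nt}.
#'
#' @export
setClass("SyntheticTruth",
  representation(
    seed = "integer",
    genomes = "data.frame",
    endolysins = "data.frame",
    holins = "data.frame",
    overlaps = "data.frame"
  )
)
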