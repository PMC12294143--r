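#' @include AllClasses.R
NULL

## Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Lowercased word tokens of a product string ("whole word" keyword matching).
productTokens <- function(product) {
  if (is.na(product) || !nzchar(product)) return(character(0))
  tok <- strsplit(tolower(product), "[^a-z0-9_]+")[[1]]
  tok[nzchar(tok)]
}

#' Construct a feature GRanges for a PhageGenome
#'
#' Convenience builder turning a data.frame of CDS coordinates into the
#' GRanges layout \link{PhageGenome} expects. Features are sorted by start.
#'
#' @param df data.frame with columns \code{feature_id}, \code{start},
#'   \code{end}, \code{strand}, \code{product} and optionally
#'   \code{protein_seq}, \code{role}.
#' @param seqname Sequence name used for the GRanges (genome accession).
#' @return A \code{GRanges} with the required metadata columns.
#' @export
featureRanges <- function(df, seqname = "genome") {
  if (!nrow(df)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(feature_id = character(0), product = character(0),
                           protein_seq = character(0), role = character(0),
                           role_evidence = CharacterList())
    return(gr)
  }
  o <- order(df$start, df$end)
  df <- df[o, , drop = FALSE]
  gr <- GRanges(seqnames = seqname,
                ranges = IRanges(start = df$start, end = df$end),
                strand = df$strand)
  mcols(gr) <- DataFrame(
    feature_id = as.character(df$feature_id),
    product = as.character(df$product),
    protein_seq = if ("protein_seq" %in% names(df))
      as.character(df$protein_seq) else rep(NA_character_, nrow(df)),
    role = if ("role" %in% names(df)) as.character(df$role)
      else rep("unassigned", nrow(df)),
    role_evidence = CharacterList(rep(list(character(0)), nrow(df)))
  )
  gr
}

#' Construct a PhageGenome
#'
#' @param accession Genome accession.
#' @param sequence Genome sequence (character or \code{DNAString}).
#' @param features Feature \code{GRanges} (see \code{\link{featureRanges}}) or
#'   a data.frame accepted by it.
#' @param name Genome name (defaults to the accession).
#' @param taxonomy Named character vector of taxonomy ranks (optional).
#' @param hostSpecies Host species (optional).
#' @return A \link{PhageGenome}.
#' @export
PhageGenome <- function(accession, sequence, features,
                        name = accession, taxonomy = character(0),
                        hostSpecies = NA_character_) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (is.data.frame(features)) features <- featureRanges(features, accession)
  new("PhageGenome", accession = accession, name = name, sequence = sequence,
      features = features, taxonomy = taxonomy, hostSpecies = hostSpecies)
}

## Features of a genome as a plain data.frame (internal convenience).
featureTable <- function(genome) {
  ft <- geneFeatures(genome)
  data.frame(
    feature_id = mcols(ft)$feature_id,
    start = start(ft), end = end(ft),
    strand = as.character(strand(ft)),
    product = mcols(ft)$product,
    protein_seq = mcols(ft)$protein_seq,
    role = mcols(ft)$role,
    stringsAsFactors = FALSE
  )
}

## Translate a nucleotide span with the bacterial/phage code (table 11).
translateSpan <- function(genomeSeq, start, end, strand) {
  sub <- Biostrings::subseq(genomeSeq, start, end)
  if (strand == "-") sub <- Biostrings::reverseComplement(sub)
  aa <- Biostrings::translate(DNAStringSet(sub),
                              genetic.code = Biostrings::getGeneticCode("11"),
                              if.fuzzy.codon = "X")
  sub("\\*$", "", as.character(aa[[1L]]))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
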