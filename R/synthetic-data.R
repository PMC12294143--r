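#' @include AllClasses.R utils.R lexicons.R endolysin-architecture.R
NULL

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
.HYDROPHOBIC <- c("L", "I", "V", "F", "A")
.HYDROPHILIC <- c("D", "E", "K", "R", "S", "N")
.DECOY_PRODUCTS <- c("hypothetical protein", "major capsid protein",
                     "terminase", "portal protein")

#' Planted TMD counts per TCDB holin family
#'
#' One TMD for families 1.E.26, 1.E.65 and unclassified holins; two for
#' 1.E.11, 1.E.18 and 1.E.24; three for 1.E.10, 1.E.16, 1.E.19 and 1.E.21.
#'
#' @return Named integer vector, family -> TMD count.
#' @export
holinFamilyTmdCounts <- function() {
  c("1.E.10" = 3L, "1.E.11" = 2L, "1.E.16" = 3L, "1.E.18" = 2L,
    "1.E.19" = 3L, "1.E.21" = 3L, "1.E.24" = 2L, "1.E.26" = 1L,
    "1.E.65" = 1L, "unclassified" = 1L)
}

.randProtein <- function(n, alphabet = .AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Back-translate an amino-acid string with uniform codon choice (code 11),
## appending a stop codon.
.backTranslate <- function(protein) {
  code <- Biostrings::getGeneticCode("11")
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(a) {
    cand <- names(code)[code == a]
    cand[sample.int(length(cand), 1L)]
  }, character(1L))
  stopc <- names(code)[code == "*"]
  paste0(paste(codons, collapse = ""), stopc[sample.int(length(stopc), 1L)])
}

## Core holin builder operating on the current RNG stream.
.holinProtein <- function(nTmds) {
  stopifnot(nTmds >= 1L, nTmds <= 3L)
  outer <- sample(20:30, 2L)                       # N/C-terminal linkers
  inner <- if (nTmds > 1L) sample(10:16, nTmds - 1L, replace = TRUE) else integer(0)
  parts <- character(0)
  segs <- matrix(0L, nrow = nTmds, ncol = 2L)
  pos <- 0L
  parts <- c(parts, .randProtein(outer[1L], .HYDROPHILIC)); pos <- outer[1L]
  for (k in seq_len(nTmds)) {
    segs[k, ] <- c(pos + 1L, pos + 21L)
    parts <- c(parts, .randProtein(21L, .HYDROPHOBIC)); pos <- pos + 21L
    if (k < nTmds) {
      parts <- c(parts, .randProtein(inner[k], .HYDROPHILIC))
      pos <- pos + inner[k]
    }
  }
  parts <- c(parts, .randProtein(outer[2L], .HYDROPHILIC))
  list(protein = paste(parts, collapse = ""),
       segments = IRanges(start = segs[, 1L], end = segs[, 2L]))
}

#' Generate a synthetic holin protein with planted transmembrane helices
#'
#' Builds a 60-160 aa protein containing \code{nTmds} hydrophobic 21-aa
#' stretches (residues drawn from L/I/V/F/A) separated by hydrophilic linkers
#' of at least 10 aa (D/E/K/R/S/N), and records the planted segment
#' coordinates.
#'
#' @param nTmds Number of helices, 1 to 3.
#' @param seed Integer seed; same seed, same protein.
#' @return list with \code{protein} (string) and \code{segments}
#'   (\link[IRanges]{IRanges} of planted helices).
#' @export
generateHolinProtein <- function(nTmds, seed = 1L) {
  if (nTmds < 1L || nTmds > 3L)
    stop("nTmds must be between 1 and 3")
  withSeed(seed, .holinProtein(as.integer(nTmds)))
}

## Endolysin protein + planted domain hit rows for a canonical layout.
.endolysinFromLayout <- function(proteinId, canonical) {
  doms <- strsplit(canonical, " & ", fixed = TRUE)[[1L]]
  k <- length(doms)
  protein <- .randProtein(70L * k + 10L)
  hits <- data.frame(
    protein_id = proteinId, domain_name = doms, source_db = "PF_SYN",
    ali_from = (seq_len(k) - 1L) * 70L + 11L,
    ali_to = (seq_len(k) - 1L) * 70L + 70L,
    e_value = 10^stats::runif(k, -30, -6),
    bit_score = round(stats::runif(k, 60, 300), 1L),
    stringsAsFactors = FALSE)
  list(protein = protein, hits = hits)
}

## Expand a catalogue pattern ("H(N)E") into the planted role sequence,
## including optional symbols.
.patternRoles <- function(pattern) {
  sym <- strsplit(gsub("[()]", "", pattern), "")[[1L]]
  c(H = "holin", E = "endolysin", N = "endonuclease")[sym]
}

#' Generate a synthetic overlapping gene pair
#'
#' Two same-strand CDS whose starts differ by \code{startOffsetNt}, both with
#' lengths divisible by 3, intersecting by construction. The downstream
#' protein is the in-frame translation of its span over the shared DNA.
#'
#' @param startOffsetNt Start-to-start offset in nt; must be positive and
#'   smaller than the first gene's length.
#' @param seed Integer seed.
#' @param len1,len2 Gene lengths in nt (multiples of 3; defaults 300/312).
#' @return list with \code{features} (2-row data.frame), \code{dna} (string
#'   covering the union span) and \code{truth} (offset bookkeeping).
#' @export
generateOverlapPair <- function(startOffsetNt, seed = 1L,
                                len1 = 300L, len2 = 312L) {
  if (len1 %% 3L != 0L || len2 %% 3L != 0L)
    stop("gene lengths must be multiples of 3")
  if (startOffsetNt <= 0L || startOffsetNt >= len1)
    stop("offset must be positive and smaller than the first gene's length ",
         "(no overlap otherwise)")
  withSeed(seed, {
    p1 <- .randProtein(len1 %/% 3L - 1L)
    dna1 <- .backTranslate(p1)
    unionLen <- startOffsetNt + len2
    extra <- unionLen - len1
    dna <- paste0(dna1,
                  paste(sample(c("A","C","G","T"), max(extra, 0L),
                               replace = TRUE), collapse = ""))
    dna <- substr(dna, 1L, unionLen)
    p2 <- translateSpan(DNAString(dna), startOffsetNt + 1L,
                        startOffsetNt + len2, "+")
    feats <- data.frame(
      feature_id = c("overlap_up", "overlap_dn"),
      start = c(1L, startOffsetNt + 1L),
      end = c(len1, startOffsetNt + len2),
      strand = "+",
      product = "endolysin",
      protein_seq = c(p1, p2),
      stringsAsFactors = FALSE)
    list(features = feats, dna = dna,
         truth = data.frame(start_offset_nt = startOffsetNt,
                            overlap_len_nt = len1 - startOffsetNt,
                            frame_offset = startOffsetNt %% 3L))
  })
}

#' Generate a genome with widely separated lysis genes
#'
#' One holin, then \code{nIntervening} decoy ORFs (structural/hypothetical
#' products), then one endolysin, all co-directional — the layout in which no
#' contiguous lysis module exists.
#'
#' @param nIntervening Number of decoy ORFs between holin and endolysin.
#' @param seed Integer seed.
#' @param decoyProducts Optional character vector of products for the
#'   intervening ORFs (recycled); defaults to the structural/hypothetical
#'   lexicon.
#' @return list with \code{genome} (\link{PhageGenome}, roles unassigned) and
#'   \code{truth} (expected module call under default tolerances).
#' @export
generateSpQs1Layout <- function(nIntervening, seed = 1L, decoyProducts = NULL) {
  stopifnot(nIntervening >= 0L)
  withSeed(seed, {
    products <- c("holin",
                  if (nIntervening > 0L) {
                    if (is.null(decoyProducts))
                      sample(.DECOY_PRODUCTS, nIntervening, replace = TRUE)
                    else rep_len(decoyProducts, nIntervening)
                  },
                  "endolysin")
    prot <- c(list(.holinProtein(1L)$protein),
              replicate(nIntervening, .randProtein(sample(80:200, 1L)),
                        simplify = FALSE),
              list(.randProtein(150L)))
    g <- .assembleGenome("SPQ001", products, prot, strand = "+")
    expected <- if (nIntervening == 0L) "A"
      else if (nIntervening <= 2L) "intercalated"
      else "none"
    list(genome = g,
         truth = data.frame(genome_id = "SPQ001", organization = expected,
                            intervening = nIntervening,
                            stringsAsFactors = FALSE))
  })
}

## Assemble a PhageGenome from parallel product/protein lists laid out 5'->3'
## in transcription order on the given strand, with random intergenic spacers.
## `overlapAfter` (index) makes ORF i+1 start `overlapOffset` nt after ORF i.
.assembleGenome <- function(accession, products, proteins, strand = "+",
                            overlapAfter = NA_integer_,
                            overlapOffset = NA_integer_,
                            hostSpecies = NA_character_) {
  n <- length(products)
  stopifnot(length(proteins) == n)
  stopifnot(is.na(overlapAfter) || strand == "+")
  if (strand == "-") {    # genomic order is the reverse of transcription order
    products <- rev(products); proteins <- rev(proteins)
    if (!is.na(overlapAfter)) overlapAfter <- n - overlapAfter
  }
  dna <- character(0)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  i <- 1L
  while (i <= n) {
    spacer <- .randProtein(sample(20:60, 1L), c("A", "C", "G", "T"))
    dna <- c(dna, spacer); pos <- pos + nchar(spacer)
    if (!is.na(overlapAfter) && i == overlapAfter) {
      len1 <- 3L * (nchar(proteins[[i]]) + 1L)
      len2 <- 3L * (nchar(proteins[[i + 1L]]) + 1L)
      block <- .overlapBlockDna(proteins[[i]], len1, len2, overlapOffset)
      starts[i] <- pos + 1L; ends[i] <- pos + len1
      starts[i + 1L] <- pos + overlapOffset + 1L
      ends[i + 1L] <- pos + overlapOffset + len2
      # downstream protein is the in-frame translation of its span
      proteins[[i + 1L]] <- translateSpan(DNAString(block),
                                          overlapOffset + 1L,
                                          overlapOffset + len2, "+")
      dna <- c(dna, block); pos <- pos + nchar(block)
      i <- i + 2L
    } else {
      orf <- .backTranslate(proteins[[i]])
      if (strand == "-")   # genomic plus strand carries the reverse complement
        orf <- as.character(Biostrings::reverseComplement(DNAString(orf)))
      starts[i] <- pos + 1L; ends[i] <- pos + nchar(orf)
      dna <- c(dna, orf); pos <- pos + nchar(orf)
      i <- i + 1L
    }
  }
  dna <- c(dna, .randProtein(sample(20:60, 1L), c("A", "C", "G", "T")))
  seq <- paste(dna, collapse = "")
  df <- data.frame(
    feature_id = sprintf("%s_%04d", accession, seq_len(n)),
    start = starts, end = ends, strand = strand,
    product = unlist(products),
    protein_seq = vapply(proteins, identity, character(1L)),
    stringsAsFactors = FALSE)
  PhageGenome(accession = accession, sequence = seq, features = df,
              hostSpecies = hostSpecies)
}

.overlapBlockDna <- function(protein1, len1, len2, offset) {
  dna1 <- .backTranslate(protein1)
  unionLen <- offset + len2
  extra <- unionLen - len1
  paste0(dna1, if (extra > 0L)
    paste(sample(c("A", "C", "G", "T"), extra, replace = TRUE), collapse = ""))
}

#' Construct a PanelSpec
#'
#' @param seed Integer seed.
#' @param organizationMix Named integer vector, catalogue label -> number of
#'   genomes planted with that organization.
#' @param nSpQs1,spQs1Intervening Widely-separated-layout genomes and their
#'   intervening decoy count.
#' @param decoyRange Min/max decoy ORFs on each side of the cassette.
#' @param architectures Canonical endolysin layouts cycled across endolysin
#'   ORFs.
#' @param holinFamilies TCDB families (may include \code{"unclassified"})
#'   cycled across holin ORFs.
#' @param overlapOffsetNt Planted start offset of the overlapping endolysin
#'   pair in the first two-endolysin genome (NA disables).
#' @param noise Decoy-hit probability (all noise E-values >= 0.01).
#' @param obfuscate Probability a planted lysis gene is labeled
#'   "hypothetical protein" (rescued through domain evidence).
#' @param minusFraction Probability a cassette genome is laid on the minus
#'   strand.
#' @return A \link{PanelSpec}.
#' @export
PanelSpec <- function(seed = 1L,
                      organizationMix = c(A = 1L, B = 1L, C = 1L, D = 1L, E = 1L),
                      nSpQs1 = 0L, spQs1Intervening = 18L,
                      decoyRange = c(2L, 4L),
                      architectures = referenceArchitectures()$canonical,
                      holinFamilies = names(holinFamilyTmdCounts()),
                      overlapOffsetNt = NA_integer_,
                      noise = 0, obfuscate = 0, minusFraction = 0) {
  mix <- as.integer(organizationMix)
  names(mix) <- names(organizationMix)
  new("PanelSpec", seed = as.integer(seed), organizationMix = mix,
      nSpQs1 = as.integer(nSpQs1), spQs1Intervening = as.integer(spQs1Intervening),
      decoyRange = as.integer(decoyRange), architectures = architectures,
      holinFamilies = holinFamilies,
      overlapOffsetNt = as.integer(overlapOffsetNt),
      noise = noise, obfuscate = obfuscate, minusFraction = minusFraction)
}

#' The default study panel specification
#'
#' 34 genomes: organization mix A=20, B=5, C=3, D=3, E=2 (33 modules, 28
#' holin-first = 85\%) plus one genome whose holin and endolysin are separated
#' by 18 unrelated genes. The first two-endolysin genome carries its two
#' endolysin ORFs as an overlapping pair offset by 39 nt. Endolysin layouts
#' cycle through the 25-architecture reference list; holin families cycle
#' through the nine TCDB holin families plus unclassified.
#'
#' @param seed Integer seed (default 42).
#' @return A \link{PanelSpec}.
#' @export
defaultPanelSpec <- function(seed = 42L) {
  PanelSpec(seed = seed,
            organizationMix = c(A = 20L, B = 5L, C = 3L, D = 3L, E = 2L),
            nSpQs1 = 1L, spQs1Intervening = 18L,
            decoyRange = c(2L, 4L),
            overlapOffsetNt = 39L,
            noise = 0.05, obfuscate = 0.1, minusFraction = 0.25)
}

#' Generate a synthetic phage-genome panel with planted ground truth
#'
#' Each genome carries exactly one planted lysis cassette realizing its
#' assigned catalogue organization, flanked by decoy ORFs with structural or
#' hypothetical products. The generator also emits a domtblout-dialect domain
#' hit table consistent with the planted endolysin architectures (plus noise
#' hits at the requested rate, all with E-values >= 0.01 so the default filter
#' removes them) and a TCDB-style hit table for the planted holin families.
#'
#' @param spec A \link{PanelSpec}.
#' @param catalogue Organization catalogue whose patterns define the planted
#'   cassette layouts (\code{\link{defaultOrganizationCatalogue}}).
#' @return list with \code{genomes} (list of \link{PhageGenome}),
#'   \code{hits} (domain hit data.frame, noise included), \code{tcdb}
#'   (transporter hit data.frame) and \code{truth} (\link{SyntheticTruth}).
#' @export
generatePanel <- function(spec, catalogue = defaultOrganizationCatalogue()) {
  validObject(spec)
  labels <- rep(names(spec@organizationMix), spec@organizationMix)
  unknown <- setdiff(unique(labels), catalogue$label)
  if (length(unknown))
    stop("organization label(s) absent from the active catalogue: ",
         paste(unknown, collapse = ", "))
  withSeed(spec@seed, {
    genomes <- list()
    hits <- list(); tcdb <- list()
    tGen <- list(); tEnd <- list(); tHol <- list(); tOvl <- list()
    archCycle <- 0L; famCycle <- 0L
    famTmd <- holinFamilyTmdCounts()
    hosts <- c("Streptococcus thermophilus", "Streptococcus pneumoniae",
               "Streptococcus pyogenes", "Streptococcus mutans",
               "Streptococcus suis")
    overlapPending <- !is.na(spec@overlapOffsetNt)
    gi <- 0L

    for (lab in labels) {
      gi <- gi + 1L
      acc <- sprintf("SYN%03d", gi)
      pattern <- catalogue$pattern[catalogue$label == lab]
      roles <- .patternRoles(pattern)
      nE <- sum(roles == "endolysin")
      planted <- list()

      # overlapping endolysin pair goes into the first two-endolysin genome
      doOverlap <- overlapPending && nE >= 2L
      strand <- if (doOverlap) "+" else
        if (stats::runif(1L) < spec@minusFraction) "-" else "+"

      nPre <- sample(spec@decoyRange[1L]:spec@decoyRange[2L], 1L)
      nPost <- sample(spec@decoyRange[1L]:spec@decoyRange[2L], 1L)
      products <- character(0); proteins <- list(); roleTrack <- character(0)
      addDecoys <- function(k) {
        for (d in seq_len(k)) {
          products <<- c(products, sample(.DECOY_PRODUCTS, 1L))
          proteins[[length(proteins) + 1L]] <<-
            .randProtein(sample(80:250, 1L))
          roleTrack <<- c(roleTrack, "decoy")
        }
      }
      addDecoys(nPre)
      cassetteIdx <- integer(0)
      eSeen <- 0L
      for (r in roles) {
        if (r == "holin") {
          famCycle <- famCycle + 1L
          fam <- spec@holinFamilies[(famCycle - 1L) %% length(spec@holinFamilies) + 1L]
          hp <- .holinProtein(famTmd[[fam]])
          products <- c(products, "holin")
          proteins[[length(proteins) + 1L]] <- hp$protein
          roleTrack <- c(roleTrack, "holin")
          planted[[length(planted) + 1L]] <- list(kind = "holin", fam = fam,
                                                  segs = hp$segments,
                                                  idx = length(products))
        } else if (r == "endolysin") {
          eSeen <- eSeen + 1L
          can <- if (doOverlap && eSeen == 1L) "Amidase_5"
            else if (doOverlap && eSeen == 2L) "NLPC_P60"
            else {
              archCycle <- archCycle + 1L
              spec@architectures[(archCycle - 1L) %% length(spec@architectures) + 1L]
            }
          el <- .endolysinFromLayout("tmp", can)
          products <- c(products, "endolysin")
          proteins[[length(proteins) + 1L]] <- el$protein
          roleTrack <- c(roleTrack, "endolysin")
          planted[[length(planted) + 1L]] <- list(kind = "endolysin",
                                                  can = can, hits = el$hits,
                                                  idx = length(products))
        } else { # endonuclease
          products <- c(products, "endonuclease")
          proteins[[length(proteins) + 1L]] <- .randProtein(sample(90:180, 1L))
          roleTrack <- c(roleTrack, "endonuclease")
        }
        cassetteIdx <- c(cassetteIdx, length(products))
      }
      addDecoys(nPost)

      # obfuscate some planted lysis products (rescued via domain evidence)
      obf <- roleTrack %in% c("holin", "endolysin") &
        stats::runif(length(products)) < spec@obfuscate
      products[obf] <- "hypothetical protein"

      ovAfter <- NA_integer_; ovOff <- NA_integer_
      if (doOverlap) {
        eIdx <- which(roleTrack == "endolysin")
        if (length(eIdx) >= 2L && eIdx[2L] == eIdx[1L] + 1L) {
          ovAfter <- eIdx[1L]; ovOff <- spec@overlapOffsetNt
          overlapPending <- FALSE
        }
      }

      host <- hosts[(gi - 1L) %% length(hosts) + 1L]
      g <- .assembleGenome(acc, products, proteins, strand = strand,
                           overlapAfter = ovAfter, overlapOffset = ovOff,
                           hostSpecies = host)

      # map transcription-order indices to genomic feature ids
      n <- length(products)
      featIds <- mcols(geneFeatures(g))$feature_id
      id_of <- function(txIdx) {
        gIdx <- if (strand == "-") n - txIdx + 1L else txIdx
        featIds[gIdx]
      }

      for (p in planted) {
        pid <- id_of(p$idx)
        if (p$kind == "holin") {
          tHol[[length(tHol) + 1L]] <- data.frame(
            protein_id = pid, genome_id = acc,
            tmd_count = length(p$segs), tcdb_family = p$fam,
            segments = paste(sprintf("%d-%d", start(p$segs), end(p$segs)),
                             collapse = ";"), stringsAsFactors = FALSE)
          if (p$fam != "unclassified")
            tcdb[[length(tcdb) + 1L]] <- data.frame(
              protein_id = pid,
              subject = sprintf("%s.%d.%d", p$fam, sample(1:3, 1L), sample(1:9, 1L)),
              evalue = 10^stats::runif(1L, -30, -6),
              bitscore = round(stats::runif(1L, 80, 400), 1L),
              stringsAsFactors = FALSE)
          # obfuscated holins get a holin-family domain hit for rescue
          if (products[p$idx] == "hypothetical protein")
            hits[[length(hits) + 1L]] <- data.frame(
              protein_id = pid, domain_name = "Phage_holin_1",
              source_db = "PF_SYN", ali_from = 5L,
              ali_to = 5L + nchar(proteins[[p$idx]]) %/% 2L,
              e_value = 1e-10, bit_score = 90, stringsAsFactors = FALSE)
        } else {
          h <- p$hits; h$protein_id <- pid
          hits[[length(hits) + 1L]] <- h
          tEnd[[length(tEnd) + 1L]] <- data.frame(
            protein_id = pid, genome_id = acc, architecture = p$can,
            stringsAsFactors = FALSE)
        }
      }

      if (!is.na(ovAfter)) {
        tOvl[[length(tOvl) + 1L]] <- data.frame(
          genome_id = acc, upstream_id = id_of(ovAfter),
          downstream_id = id_of(ovAfter + 1L),
          start_offset_nt = spec@overlapOffsetNt, stringsAsFactors = FALSE)
      }

      # noise hits on decoy ORFs: E-values >= 0.01 by construction
      for (d in which(roleTrack == "decoy")) {
        if (stats::runif(1L) < spec@noise) {
          dom <- sample(defaultDomainLexicon()$domain_name, 1L)
          hits[[length(hits) + 1L]] <- data.frame(
            protein_id = id_of(d), domain_name = dom, source_db = "PF_SYN",
            ali_from = 1L, ali_to = 40L,
            e_value = 10^stats::runif(1L, -2, 1),   # in [0.01, 10)
            bit_score = round(stats::runif(1L, 5, 15), 1L),
            stringsAsFactors = FALSE)
        }
      }

      sig <- paste(c(holin = "H", endolysin = "E",
                     endonuclease = "N")[roles], collapse = "")
      tGen[[length(tGen) + 1L]] <- data.frame(
        genome_id = acc, organization = lab, signature = sig,
        intercalated_count = sum(roles == "endonuclease"),
        cassette_strand = strand, host_species = host,
        stringsAsFactors = FALSE)
      genomes[[length(genomes) + 1L]] <- g
    }

    for (s in seq_len(spec@nSpQs1)) {
      gi <- gi + 1L
      acc <- sprintf("SYN%03d", gi)
      nI <- spec@spQs1Intervening
      products <- c("holin", sample(.DECOY_PRODUCTS, nI, replace = TRUE),
                    "endolysin")
      famCycle <- famCycle + 1L
      fam <- spec@holinFamilies[(famCycle - 1L) %% length(spec@holinFamilies) + 1L]
      hp <- .holinProtein(famTmd[[fam]])
      archCycle <- archCycle + 1L
      can <- spec@architectures[(archCycle - 1L) %% length(spec@architectures) + 1L]
      el <- .endolysinFromLayout("tmp", can)
      proteins <- c(list(hp$protein),
                    replicate(nI, .randProtein(sample(80:250, 1L)),
                              simplify = FALSE),
                    list(el$protein))
      g <- .assembleGenome(acc, products, proteins, strand = "+",
                           hostSpecies = hosts[(gi - 1L) %% length(hosts) + 1L])
      featIds <- mcols(geneFeatures(g))$feature_id
      hid <- featIds[1L]; eid <- featIds[length(featIds)]
      tHol[[length(tHol) + 1L]] <- data.frame(
        protein_id = hid, genome_id = acc, tmd_count = length(hp$segments),
        tcdb_family = fam,
        segments = paste(sprintf("%d-%d", start(hp$segments), end(hp$segments)),
                         collapse = ";"), stringsAsFactors = FALSE)
      if (fam != "unclassified")
        tcdb[[length(tcdb) + 1L]] <- data.frame(
          protein_id = hid, subject = paste0(fam, ".1.1"),
          evalue = 1e-15, bitscore = 200, stringsAsFactors = FALSE)
      h <- el$hits; h$protein_id <- eid
      hits[[length(hits) + 1L]] <- h
      tEnd[[length(tEnd) + 1L]] <- data.frame(
        protein_id = eid, genome_id = acc, architecture = can,
        stringsAsFactors = FALSE)
      tGen[[length(tGen) + 1L]] <- data.frame(
        genome_id = acc, organization = "none",
        signature = paste0("H", strrep("X", nI), "E"),
        intercalated_count = nI, cassette_strand = "+",
        host_species = hosts[(gi - 1L) %% length(hosts) + 1L],
        stringsAsFactors = FALSE)
      genomes[[length(genomes) + 1L]] <- g
    }

    bindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
    truth <- new("SyntheticTruth", seed = spec@seed,
      genomes = bindOr(tGen, data.frame(genome_id = character(0))),
      endolysins = bindOr(tEnd, data.frame(protein_id = character(0),
                                           genome_id = character(0),
                                           architecture = character(0))),
      holins = bindOr(tHol, data.frame(protein_id = character(0))),
      overlaps = bindOr(tOvl, data.frame(genome_id = character(0),
                                         upstream_id = character(0),
                                         downstream_id = character(0),
                                         start_offset_nt = integer(0))))
    list(genomes = genomes,
         hits = bindOr(hits, data.frame(protein_id = character(0),
                                        domain_name = character(0),
                                        source_db = character(0),
                                        ali_from = integer(0),
                                        ali_to = integer(0),
                                        e_value = numeric(0),
                                        bit_score = numeric(0))),
         tcdb = bindOr(tcdb, data.frame(protein_id = character(0),
                                        subject = character(0),
                                        evalue = numeric(0),
                                        bitscore = numeric(0))),
         truth = truth)
  })
}

#' Generate one domain-hit record per reference architecture
#'
#' Expands an architecture table (canonical layout + count) into per-protein
#' planted hit rows: \code{count} proteins per layout, domains at consecutive
#' coordinates, E-values well below the default cutoff.
#'
#' @param reference data.frame with columns \code{canonical} and \code{count}
#'   (\code{\link{referenceArchitectures}}).
#' @param seed Integer seed.
#' @return list with \code{hits} (data.frame) and \code{truth} (protein_id ->
#'   canonical).
#' @export
generateArchitectureHits <- function(reference = referenceArchitectures(),
                                     seed = 1L) {
  withSeed(seed, {
    hits <- list(); truth <- list()
    p <- 0L
    for (i in seq_len(nrow(reference))) {
      for (k in seq_len(reference$count[i])) {
        p <- p + 1L
        pid <- sprintf("LYS%04d", p)
        el <- .endolysinFromLayout(pid, reference$canonical[i])
        hits[[length(hits) + 1L]] <- el$hits
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = pid, architecture = reference$canonical[i],
          stringsAsFactors = FALSE)
      }
    }
    list(hits = do.call(rbind, hits), truth = do.call(rbind, truth))
  })
}

#' Write a generated panel to disk
#'
#' Emits one GenBank file per genome, the domain hit table in the domtblout
#' dialect, the TCDB-style hit TSV and the planted truth tables.
#'
#' @param panel Output of \code{\link{generatePanel}}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in panel$genomes)
    writeGenBank(g, file.path(dir, paste0(accession(g), ".gbk")))
  writeDomtblout(panel$hits, file.path(dir, "hits.domtblout"))
  writeTsv(panel$tcdb, file.path(dir, "tcdb_hits.tsv"))
  tr <- panel$truth
  writeTsv(truthGenomes(tr), file.path(dir, "truth_genomes.tsv"))
  writeTsv(truthEndolysins(tr), file.path(dir, "truth_endolysins.tsv"))
  writeTsv(truthHolins(tr), file.path(dir, "truth_holins.tsv"))
  writeTsv(truthOverlaps(tr), file.path(dir, "truth_overlaps.tsv"))
  invisible(dir)
}
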