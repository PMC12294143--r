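#' @include AllClasses.R genome-io.R role-classification.R module-delineation.R
#' @include endolysin-architecture.R gene-overlap.R holin-characterization.R
#' @include synthetic-data.R
NULL

#' Run the full lysis-module analysis pipeline
#'
#' Orchestrates simulate/read -> role assignment -> module delineation and
#' organization classification -> endolysin architecture typing -> overlap
#' detection -> holin characterization, writing every tabular output to
#' \code{outDir}: \code{modules.tsv}/\code{modules.gff3},
#' \code{architectures.tsv}, \code{upset.tsv}, \code{cooccurrence.tsv},
#' \code{overlaps.tsv}, \code{holins.tsv}, \code{tandem_report.tsv} and a
#' \code{summary.txt} with headline counts. Given the same input (or the same
#' generator spec) the outputs are byte-identical across runs.
#'
#' @param input Either a \link{PanelSpec} (the panel is generated, and its
#'   GenBank/domtblout/TCDB files are written under \code{outDir/simulated} so
#'   the run exercises the on-disk formats) or a directory containing
#'   \code{*.gbk} genomes, optionally \code{hits.domtblout} and
#'   \code{tcdb_hits.tsv}.
#' @param outDir Output directory (created).
#' @param lexicon Role lexicon.
#' @param domainLexicon Domain lexicon.
#' @param catalogue Organization catalogue.
#' @param hydropathy Hydropathy/TMD parameters.
#' @param eCutoff E-value cutoff for domain and transporter hits.
#' @param maxIntercalated,maxGapNt Module delineation tolerances.
#' @param supplemental Optional supplemental evidence data.frame.
#' @return (invisibly) list with the in-memory results: genomes, modules,
#'   diagnostics, architectures (ranked list + table), upset, cooccurrence,
#'   overlaps, holins, tandem report and the headline summary.
#' @export
runPipeline <- function(input, outDir,
                        lexicon = defaultRoleLexicon(),
                        domainLexicon = defaultDomainLexicon(),
                        catalogue = defaultOrganizationCatalogue(),
                        hydropathy = defaultHydropathyParams(),
                        eCutoff = 0.01,
                        maxIntercalated = 2L, maxGapNt = 1000L,
                        supplemental = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## stage: input
  if (is(input, "PanelSpec")) {
    panel <- generatePanel(input, catalogue = catalogue)
    simDir <- file.path(outDir, "simulated")
    writePanel(panel, simDir)
    genomes <- lapply(list.files(simDir, pattern = "\\.gbk$",
                                 full.names = TRUE), readGenBank)
    hits <- parseDomtblout(file.path(simDir, "hits.domtblout"),
                           eCutoff = eCutoff, lexicon = domainLexicon)
    tcdb <- utils::read.delim(file.path(simDir, "tcdb_hits.tsv"),
                              stringsAsFactors = FALSE)
  } else if (is.character(input)) {
    if (!dir.exists(input))
      stop("input stage: directory not found: ", input)
    gbk <- list.files(input, pattern = "\\.(gbk|gb|gbff)$", full.names = TRUE)
    if (!length(gbk))
      stop("input stage: no GenBank files in ", input)
    genomes <- lapply(gbk, readGenBank)
    hf <- file.path(input, "hits.domtblout")
    hits <- if (file.exists(hf))
      parseDomtblout(hf, eCutoff = eCutoff, lexicon = domainLexicon)
    else annotateHits(data.frame(protein_id = character(0),
                                 domain_name = character(0),
                                 source_db = character(0),
                                 ali_from = integer(0), ali_to = integer(0),
                                 e_value = numeric(0), bit_score = numeric(0)),
                      domainLexicon)
    tf <- file.path(input, "tcdb_hits.tsv")
    tcdb <- if (file.exists(tf)) utils::read.delim(tf, stringsAsFactors = FALSE)
      else data.frame(protein_id = character(0), subject = character(0),
                      evalue = numeric(0), bitscore = numeric(0))
  } else stop("input must be a PanelSpec or a directory path")

  ## stage: role assignment
  genomes <- lapply(genomes, classifyRoles, hits = hits, lexicon = lexicon,
                    supplemental = supplemental, eCutoff = eCutoff)
  names(genomes) <- vapply(genomes, accession, character(1L))

  ## stage: module delineation + organization classification
  modules <- list(); diagnostics <- list()
  for (g in genomes) {
    mods <- delineateModules(g, maxIntercalated = maxIntercalated,
                             maxGapNt = maxGapNt)
    d <- attr(mods, "diagnostics")
    if (!is.null(d)) diagnostics[[length(diagnostics) + 1L]] <- d
    modules <- c(modules, lapply(mods, classifyOrganization,
                                 catalogue = catalogue))
  }
  diagnostics <- if (length(diagnostics)) do.call(rbind, diagnostics) else
    data.frame(genome_id = character(0), intervening_count = integer(0))
  writeModulesGff(genomes, modules, file.path(outDir, "modules.gff3"))
  writeTsv(diagnostics, file.path(outDir, "module_diagnostics.tsv"))

  ## stage: endolysin architectures
  endolysinIds <- unlist(lapply(genomes, function(g) {
    ft <- geneFeatures(g)
    mcols(ft)$feature_id[mcols(ft)$role == "endolysin"]
  }), use.names = FALSE)
  archs <- buildArchitectures(hits[hits$protein_id %in% endolysinIds, ,
                                   drop = FALSE],
                              proteinIds = endolysinIds)
  if (!is.null(supplemental))
    archs <- lapply(archs, applySupplementalEvidence,
                    supplemental = supplemental, lexicon = domainLexicon,
                    eCutoff = eCutoff)
  ranked <- rankArchitectures(archs)
  archTab <- data.frame(
    protein_id = vapply(ranked$panel, function(a) a@proteinId, character(1L)),
    label = vapply(ranked$panel, architectureLabel, character(1L)),
    canonical = vapply(ranked$panel, canonicalArchitecture, character(1L)),
    has_EAD = vapply(ranked$panel, hasEAD, logical(1L)),
    has_CBD = vapply(ranked$panel, hasCBD, logical(1L)),
    stringsAsFactors = FALSE)
  writeTsv(archTab, file.path(outDir, "architectures.tsv"))
  up <- upsetTable(ranked$panel)
  writeTsv(up$matrix, file.path(outDir, "upset.tsv"))
  byGenome <- lapply(genomes, function(g) {
    ft <- geneFeatures(g)
    ids <- mcols(ft)$feature_id[mcols(ft)$role == "endolysin"]
    ranked$panel[names(archs) %in% ids]
  })
  cooc <- flagAndCooccur(byGenome)
  writeTsv(cooc$cooccurrence, file.path(outDir, "cooccurrence.tsv"))

  ## stage: gene overlaps
  overlaps <- do.call(rbind, c(lapply(genomes, detectOverlaps,
                                      rolesFilter = "endolysin"),
                               make.row.names = FALSE))
  writeTsv(overlaps, file.path(outDir, "overlaps.tsv"))

  ## stage: holin characterization
  holins <- list()
  for (g in genomes) {
    ft <- geneFeatures(g)
    idx <- which(mcols(ft)$role == "holin")
    for (i in idx) {
      prot <- mcols(ft)$protein_seq[i]
      if (is.na(prot)) next
      prof <- suppressWarnings(
        predictTmds(prot, params = hydropathy,
                    proteinId = mcols(ft)$feature_id[i],
                    genomeId = accession(g)))
      prof@tcdbFamily <- assignFamily(prof@proteinId, tcdb, eCutoff = eCutoff)
      holins[[length(holins) + 1L]] <- prof
    }
  }
  holinTab <- data.frame(
    protein_id = vapply(holins, function(p) p@proteinId, character(1L)),
    genome_id = vapply(holins, function(p) p@genomeId, character(1L)),
    tmd_count = vapply(holins, tmdCount, integer(1L)),
    tcdb_family = vapply(holins, tcdbFamily, character(1L)),
    segments = vapply(holins, function(p) {
      if (!length(p@segments)) return("")
      paste(sprintf("%d-%d", start(p@segments), end(p@segments)),
            collapse = ";")
    }, character(1L)),
    stringsAsFactors = FALSE)
  writeTsv(holinTab, file.path(outDir, "holins.tsv"))
  tandem <- tandemConsistencyReport(holins)
  writeTsv(tandem$tandem, file.path(outDir, "tandem_report.tsv"))

  ## stage: summary
  stats <- orderStatistics(modules)
  labs <- vapply(modules, organizationLabel, character(1L))
  summary <- list(
    n_genomes = length(genomes),
    n_modules = length(modules),
    organization_histogram = table(labs),
    holin_first_fraction = stats$fractions[["holin_first"]],
    n_architecture_types = nrow(ranked$table),
    n_endolysins = length(archs),
    holin_family_histogram = table(holinTab$tcdb_family),
    tmd_histogram = table(holinTab$tmd_count),
    n_overlap_pairs = if (is.null(overlaps)) 0L else nrow(overlaps),
    diagnostics = diagnostics)
  txt <- c(
    sprintf("genomes: %d", summary$n_genomes),
    sprintf("modules: %d", summary$n_modules),
    sprintf("modules per organization: %s",
            paste(names(summary$organization_histogram),
                  summary$organization_histogram, sep = "=", collapse = " ")),
    sprintf("holin-first fraction: %.3f", summary$holin_first_fraction),
    sprintf("architecture types: %d (over %d endolysins)",
            summary$n_architecture_types, summary$n_endolysins),
    sprintf("holin families: %s",
            paste(names(summary$holin_family_histogram),
                  summary$holin_family_histogram, sep = "=", collapse = " ")),
    sprintf("TMD counts: %s",
            paste(names(summary$tmd_histogram), summary$tmd_histogram,
                  sep = "=", collapse = " ")),
    sprintf("overlapping endolysin pairs: %d", summary$n_overlap_pairs),
    sprintf("no-module genomes with diagnostics: %d", nrow(diagnostics)))
  writeLines(txt, file.path(outDir, "summary.txt"))

  invisible(list(genomes = genomes, modules = modules,
                 diagnostics = diagnostics, architectures = ranked,
                 upset = up, cooccurrence = cooc, overlaps = overlaps,
                 holins = holins, tandem = tandem, summary = summary))
}
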