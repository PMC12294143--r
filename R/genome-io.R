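#' @include AllClasses.R utils.R
NULL

## ---- GenBank flat files ----------------------------------------------------

#' Read a single-record GenBank flat file
#'
#' Parses CDS features (coordinates, strand, \code{/product},
#' \code{/translation}) of a one-record GenBank file into a
#' \link{PhageGenome}. Coordinates stay 1-based inclusive in ascending order;
#' complement locations set the strand to \code{"-"} without reordering.
#' A CDS lacking \code{/translation} is translated from its span (genetic
#' code 11) when the span length is a multiple of 3; otherwise the feature is
#' kept with \code{protein_seq = NA} and a warning is raised.
#'
#' @param path Path to the GenBank file.
#' @return A \link{PhageGenome}.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nrec <- sum(grepl("^LOCUS ", lines))
  if (nrec != 1L)
    stop("expected a single-record GenBank file, found ", nrec, " records")
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[grepl("^LOCUS ", lines)][1L])),
                    "[[:space:]]+")[[1L]]
  accession <- locus[1L]
  acc_line <- lines[grepl("^ACCESSION", lines)]
  if (length(acc_line)) {
    a <- trimws(sub("^ACCESSION", "", acc_line[1L]))
    if (nzchar(a)) accession <- strsplit(a, "[[:space:]]+")[[1L]][1L]
  }
  def_line <- lines[grepl("^DEFINITION", lines)]
  name <- if (length(def_line))
    sub("\\.$", "", trimws(sub("^DEFINITION", "", def_line[1L]))) else accession

  i_feat <- grep("^FEATURES", lines)
  i_orig <- grep("^ORIGIN", lines)
  i_end <- grep("^//\\s*$", lines)
  if (!length(i_orig)) stop("GenBank file has no ORIGIN sequence block")
  seq_lines <- lines[(i_orig[1L] + 1L):(if (length(i_end)) i_end[1L] - 1L else length(lines))]
  dna <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  sequence <- DNAString(toupper(dna))

  feats <- list()
  if (length(i_feat)) {
    block <- lines[(i_feat[1L] + 1L):(i_orig[1L] - 1L)]
    # split the feature table into entries: a new entry starts with a key at
    # column 6; qualifier/continuation lines are indented to column 22
    is_key <- grepl("^ {5}\\S", block)
    entry_idx <- cumsum(is_key)
    for (k in seq_len(max(c(entry_idx, 0L)))) {
      ent <- block[entry_idx == k]
      key <- strsplit(trimws(ent[1L]), "[[:space:]]+")[[1L]]
      if (key[1L] != "CDS") next
      loc <- paste(key[-1L], collapse = "")
      qlines <- ent[-1L]
      # location may continue onto lines before the first qualifier
      qstart <- grep("^\\s*/", qlines)
      if (length(qstart) && qstart[1L] > 1L) {
        loc <- paste0(loc, paste(trimws(qlines[seq_len(qstart[1L] - 1L)]),
                                 collapse = ""))
        qlines <- qlines[-seq_len(qstart[1L] - 1L)]
      }
      quals <- .parseQualifiers(qlines)
      pl <- .parseLocation(loc)
      feats[[length(feats) + 1L]] <- c(pl, quals)
    }
  }

  df <- .featsToDf(feats, sequence, accession)
  PhageGenome(accession = accession, sequence = sequence, features = df,
              name = name)
}

.parseLocation <- function(loc) {
  strand <- "+"
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc))
    stop("compound (join/order) CDS locations are not supported: ", loc)
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1L]]
  if (length(m) != 3L) stop("cannot parse CDS location: ", loc)
  list(start = as.integer(m[2L]), end = as.integer(m[3L]), strand = strand)
}

.parseQualifiers <- function(qlines) {
  quals <- list()
  cur <- NULL
  for (ln in qlines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      eq <- regexpr("=", t, fixed = TRUE)
      if (eq > 0L) {
        cur <- substr(t, 2L, eq - 1L)
        quals[[cur]] <- gsub("\"", "", substr(t, eq + 1L, nchar(t)))
      } else {
        cur <- substr(t, 2L, nchar(t))
        quals[[cur]] <- ""
      }
    } else if (!is.null(cur)) {
      sep <- if (cur == "translation") "" else " "
      quals[[cur]] <- paste0(quals[[cur]], sep, gsub("\"", "", t))
    }
  }
  quals
}

.featsToDf <- function(feats, sequence, accession) {
  n <- length(feats)
  df <- data.frame(feature_id = character(n), start = integer(n),
                   end = integer(n), strand = character(n),
                   product = character(n), protein_seq = NA_character_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    df$start[i] <- f$start; df$end[i] <- f$end; df$strand[i] <- f$strand
    df$feature_id[i] <- if (!is.null(f$locus_tag)) f$locus_tag
      else if (!is.null(f$protein_id)) f$protein_id
      else sprintf("%s_CDS_%04d", accession, i)
    df$product[i] <- if (!is.null(f$product)) f$product else ""
    if (!is.null(f$translation)) {
      df$protein_seq[i] <- gsub("[[:space:]]", "", f$translation)
    } else if ((f$end - f$start + 1L) %% 3L == 0L) {
      df$protein_seq[i] <- translateSpan(sequence, f$start, f$end, f$strand)
    } else {
      warning("CDS ", df$feature_id[i],
              " has no translation and a span not divisible by 3; ",
              "protein_seq left absent")
    }
  }
  df
}

#' Write a PhageGenome as a GenBank flat file
#'
#' Inverse of \code{\link{readGenBank}} for the fields this package models.
#'
#' @param genome A \link{PhageGenome}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  seq <- as.character(genomeSequence(genome))
  L <- nchar(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %6d bp    DNA     linear   PHG 01-JAN-2026",
                     accession(genome), L), con)
  writeLines(sprintf("DEFINITION  %s.", genomeName(genome)), con)
  writeLines(sprintf("ACCESSION   %s", accession(genome)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  ft <- featureTable(genome)
  for (i in seq_len(nrow(ft))) {
    loc <- sprintf("%d..%d", ft$start[i], ft$end[i])
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", ft$feature_id[i]), con)
    writeLines(sprintf("                     /product=\"%s\"", ft$product[i]), con)
    if (!is.na(ft$protein_seq[i])) {
      tr <- ft$protein_seq[i]
      starts <- seq(1L, nchar(tr), 44L)
      chunks <- substring(tr, starts, pmin(starts + 43L, nchar(tr)))
      chunks[1L] <- paste0("/translation=\"", chunks[1L])
      chunks[length(chunks)] <- paste0(chunks[length(chunks)], "\"")
      for (ch in chunks)
        writeLines(sprintf("                     %s", ch), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- GFF3 + FASTA ----------------------------------------------------------

#' Read a GFF3 + FASTA pair
#'
#' CDS rows of the GFF3 become features; the FASTA supplies the genome
#' sequence. The \code{product} attribute (fallback \code{Name}) fills the
#' product; a missing attribute yields an empty product. Proteins are
#' translated from the spans (reverse complement on the minus strand).
#'
#' @param gffPath Path to the GFF3 file.
#' @param fastaPath Path to the genome FASTA.
#' @return A \link{PhageGenome}.
#' @export
readGFF3 <- function(gffPath, fastaPath) {
  fa <- Biostrings::readDNAStringSet(fastaPath)
  if (length(fa) != 1L) stop("expected a single-sequence FASTA")
  seqid <- strsplit(names(fa)[1L], "[[:space:]]+")[[1L]][1L]
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[mcols(gr)$type == "CDS"]
  if (length(gr)) {
    used <- unique(as.character(seqnames(gr)))
    if (!all(used == seqid))
      stop("GFF3 sequence id (", paste(used, collapse = ","),
           ") does not match FASTA id (", seqid, ")")
  }
  sequence <- fa[[1L]]
  mc <- mcols(gr)
  product <- if ("product" %in% colnames(mc)) as.character(mc$product)
    else rep(NA_character_, length(gr))
  if ("Name" %in% colnames(mc)) {
    nm <- as.character(mc$Name)
    product <- ifelse(is.na(product), nm, product)
  }
  product[is.na(product)] <- ""
  ids <- if ("ID" %in% colnames(mc)) as.character(mc$ID)
    else sprintf("%s_CDS_%04d", seqid, seq_along(gr))
  df <- data.frame(feature_id = ids, start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)), product = product,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  df$protein_seq <- vapply(seq_len(nrow(df)), function(i) {
    if ((df$end[i] - df$start[i] + 1L) %% 3L == 0L)
      translateSpan(sequence, df$start[i], df$end[i], df$strand[i])
    else NA_character_
  }, character(1L))
  PhageGenome(accession = seqid, sequence = sequence, features = df,
              name = seqid)
}

## ---- module output ---------------------------------------------------------

#' Write delineated lysis modules as GFF3 (plus a TSV twin)
#'
#' One \code{region} row per module (attributes: organization label, role
#' signature, intercalated count) and one child \code{CDS} row per member.
#'
#' @param genomes List of \link{PhageGenome} objects the modules refer to.
#' @param modules List of \link{LysisModule}.
#' @param out Output GFF3 path; the TSV twin is written next to it with
#'   extension \code{.tsv}.
#' @return \code{out}, invisibly.
#' @export
writeModulesGff <- function(genomes, modules, out) {
  known <- unlist(lapply(genomes, function(g) {
    paste(accession(g), mcols(geneFeatures(g))$feature_id)
  }))
  lines <- "##gff-version 3"
  rows <- list()
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    mem <- moduleMembers(m)
    ref <- paste(m@genomeId, mcols(mem)$feature_id)
    if (!all(ref %in% known))
      stop("module ", i, " references features absent from the given genomes")
    mid <- sprintf("module_%03d", i)
    lines <- c(lines, sprintf(
      "%s\tLysisTyper\tregion\t%d\t%d\t.\t%s\t.\tID=%s;organization=%s;signature=%s;intercalated=%d",
      m@genomeId, min(start(mem)), max(end(mem)),
      c(forward = "+", reverse = "-", mixed = ".")[m@direction],
      mid, m@organizationLabel, m@roleSignature, m@intercalatedCount))
    for (j in seq_along(mem)) {
      lines <- c(lines, sprintf(
        "%s\tLysisTyper\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;Parent=%s;role=%s;product=%s",
        m@genomeId, start(mem)[j], end(mem)[j],
        as.character(strand(mem))[j],
        mcols(mem)$feature_id[j], mid, mcols(mem)$role[j],
        gsub("[;=\t]", "_", mcols(mem)$product[j])))
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = m@genomeId, module_id = mid,
        organization = m@organizationLabel, signature = m@roleSignature,
        intercalated = m@intercalatedCount, direction = m@direction,
        feature_id = mcols(mem)$feature_id[j],
        start = start(mem)[j], end = end(mem)[j],
        strand = as.character(strand(mem))[j],
        role = mcols(mem)$role[j], stringsAsFactors = FALSE)
    }
  }
  writeLines(lines, out)
  tsv <- sub("\\.[^.]*$", ".tsv", out)
  if (identical(tsv, out)) tsv <- paste0(out, ".tsv")
  if (length(rows)) writeTsv(do.call(rbind, rows), tsv)
  else writeTsv(data.frame(genome_id = character(0)), tsv)
  invisible(out)
}

#' Read a modules GFF3 written by writeModulesGff
#'
#' Restores module membership, labels and signatures (round-trip support).
#'
#' @param path GFF3 path.
#' @return data.frame with one row per member gene (module_id, organization,
#'   signature, intercalated, feature_id, coordinates).
#' @export
readModulesGff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(genome_id = character(0), module_id = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr1 <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))[[1L]]
    if (length(m)) m[3L] else NA_character_
  }
  regions <- Filter(function(x) x[3L] == "region", f)
  reg <- do.call(rbind, lapply(regions, function(x) data.frame(
    module_id = attr1(x[9L], "ID"), genome_id = x[1L],
    organization = attr1(x[9L], "organization"),
    signature = attr1(x[9L], "signature"),
    intercalated = as.integer(attr1(x[9L], "intercalated")),
    stringsAsFactors = FALSE)))
  cds <- Filter(function(x) x[3L] == "CDS", f)
  mem <- do.call(rbind, lapply(cds, function(x) data.frame(
    module_id = attr1(x[9L], "Parent"), feature_id = attr1(x[9L], "ID"),
    start = as.integer(x[4L]), end = as.integer(x[5L]), strand = x[7L],
    role = attr1(x[9L], "role"), stringsAsFactors = FALSE)))
  merge(reg, mem, by = "module_id", sort = FALSE)
}
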