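test_that("GenBank round trip preserves coordinates, strand, products and proteins", {
  spec <- PanelSpec(seed = 11, organizationMix = c(A = 1L, D = 1L),
                    minusFraction = 1)   # exercise complement locations
  panel <- generatePanel(spec)
  for (g in panel$genomes) {
    f <- tempfile(fileext = ".gbk")
    writeGenBank(g, f)
    g2 <- readGenBank(f)
    expect_equal(accession(g2), accession(g))
    expect_equal(as.character(genomeSequence(g2)),
                 as.character(genomeSequence(g)))
    t1 <- featureTable(g)[, 1:6]; t2 <- featureTable(g2)[, 1:6]
    expect_equal(t2, t1)
  }
})

test_that("a minimal one-CDS GenBank parses to the expected feature", {
  prot <- strrep("M", 99L)
  g <- PhageGenome("MINI01", strrep("ATG", 100L),
                   gene("MINI01_0001", 1L, 300L, "+", "holin", protein = prot))
  f <- tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  g2 <- readGenBank(f)
  ft <- featureTable(g2)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$start, 1L)
  expect_equal(ft$end, 300L)
  expect_equal(ft$strand, "+")
  expect_equal(ft$product, "holin")

  # complement strand: ascending coordinates kept, strand flips
  gm <- PhageGenome("MINI02", strrep("ATG", 100L),
                    gene("MINI02_0001", 1L, 300L, "-", "holin", protein = prot))
  writeGenBank(gm, f)
  ftm <- featureTable(readGenBank(f))
  expect_equal(ftm$strand, "-")
  expect_equal(c(ftm$start, ftm$end), c(1L, 300L))
})

test_that("two CDS offset by 39 nt are both retained in start order", {
  df <- rbind(gene("g1", 1L, 300L, protein = strrep("A", 99L)),
              gene("g2", 40L, 351L, protein = strrep("A", 103L)))
  g <- tinyGenome(df, len = 400L)
  f <- tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  ft <- featureTable(readGenBank(f))
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$start, c(1L, 40L))
  expect_equal(ft$start[2L] - ft$start[1L], 39L)
})

test_that("multi-record files are rejected with the record count", {
  g <- rolesGenome(c("holin", "endolysin"))
  f <- tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  two <- c(readLines(f), readLines(f))
  f2 <- tempfile(fileext = ".gbk")
  writeLines(two, f2)
  expect_error(readGenBank(f2), "2 records")
})

test_that("Biopython independently confirms the GenBank writer/parser", {
  panel <- generatePanel(PanelSpec(seed = 3, organizationMix = c(E = 1L)))
  g <- panel$genomes[[1L]]
  f <- tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  py <- paste(
    "import sys",
    "from Bio import SeqIO",
    "r = list(SeqIO.parse(sys.argv[1], 'genbank'))",
    "assert len(r) == 1",
    "rec = r[0]",
    "for ft in rec.features:",
    "    if ft.type != 'CDS': continue",
    "    s = int(ft.location.start) + 1",
    "    e = int(ft.location.end)",
    "    st = '+' if ft.location.strand == 1 else '-'",
    "    print(ft.qualifiers['locus_tag'][0], s, e, st,",
    "          ft.qualifiers['product'][0].replace(' ', '_'),",
    "          ft.qualifiers['translation'][0], sep='\\t')",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py), shQuote(f)), stdout = TRUE)
  ref <- read.delim(text = out, header = FALSE,
                    col.names = c("feature_id", "start", "end", "strand",
                                  "product", "protein_seq"))
  ft <- featureTable(g)
  expect_equal(ref$feature_id, ft$feature_id)
  expect_equal(ref$start, ft$start)
  expect_equal(ref$end, ft$end)
  expect_equal(ref$strand, ft$strand)
  expect_equal(ref$product, gsub(" ", "_", ft$product))
  expect_equal(ref$protein_seq, ft$protein_seq)
})

test_that("GenBank and GFF3+FASTA encodings of one genome parse identically", {
  panel <- generatePanel(PanelSpec(seed = 5, organizationMix = c(B = 1L),
                                   minusFraction = 1))
  g <- panel$genomes[[1L]]
  gbk <- tempfile(fileext = ".gbk")
  writeGenBank(g, gbk)
  ft <- featureTable(g)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c("##gff-version 3", sprintf(
    "%s\tsyn\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
    accession(g), ft$start, ft$end, ft$strand, ft$feature_id,
    gsub(" ", "%20", ft$product))), gff)
  writeLines(c(paste0(">", accession(g)), as.character(genomeSequence(g))), fa)
  g1 <- readGenBank(gbk)
  g2 <- readGFF3(gff, fa)
  expect_equal(featureTable(g2), featureTable(g1))
  expect_equal(as.character(genomeSequence(g2)),
               as.character(genomeSequence(g1)))
})

test_that("GFF3 reader translates minus-strand CDS from the reverse complement", {
  dna <- paste0("AAAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTGCTTAA"))), "AA")
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fasta")
  writeLines(c("##gff-version 3",
               "chr1\tsyn\tCDS\t5\t16\t.\t-\t0\tID=c1;product=endolysin"), gff)
  writeLines(c(">chr1", dna), fa)
  g <- readGFF3(gff, fa)
  expect_equal(featureTable(g)$protein_seq, "MAA")
})

test_that("GFF3 with mismatching sequence id is rejected; empty GFF3 gives zero features", {
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fasta")
  writeLines(c("##gff-version 3",
               "other\tsyn\tCDS\t1\t12\t.\t+\t0\tID=c1;product=holin"), gff)
  writeLines(c(">chr1", strrep("ACGT", 10L)), fa)
  expect_error(readGFF3(gff, fa), "does not match")
  writeLines("##gff-version 3", gff)
  g <- readGFF3(gff, fa)
  expect_equal(length(geneFeatures(g)), 0L)
})

test_that("module GFF3 output round-trips membership and labels", {
  panel <- generatePanel(PanelSpec(seed = 9))
  genomes <- lapply(panel$genomes, classifyRoles,
                    hits = panel$hits[panel$hits$e_value < 0.01, ])
  modules <- unlist(lapply(genomes, function(g)
    lapply(delineateModules(g), classifyOrganization)), recursive = FALSE)
  out <- tempfile(fileext = ".gff3")
  writeModulesGff(genomes, modules, out)
  back <- readModulesGff(out)
  expect_equal(length(unique(back$module_id)), length(modules))
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    b <- back[back$module_id == sprintf("module_%03d", i), ]
    expect_setequal(b$feature_id,
                    S4Vectors::mcols(moduleMembers(m))$feature_id)
    expect_equal(unique(b$organization), organizationLabel(m))
    expect_equal(unique(b$signature), roleSignature(m))
    expect_equal(unique(b$intercalated), intercalatedCount(m))
  }
  # intercalated attribute is preserved for a planted C module
  cm <- Filter(function(m) organizationLabel(m) == "C", modules)
  expect_true(all(vapply(cm, intercalatedCount, integer(1L)) == 1L))

  # unknown member features are rejected; empty module list is valid
  expect_error(writeModulesGff(genomes[1], modules[2], out), "absent")
  expect_silent(writeModulesGff(genomes, list(), out))
  expect_equal(readLines(out), "##gff-version 3")
})
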