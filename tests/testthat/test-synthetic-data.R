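test_that("panel generation is byte-identical under a fixed seed", {
  s <- defaultPanelSpec(seed = 123)
  p1 <- generatePanel(s)
  p2 <- generatePanel(s)
  expect_identical(lapply(p1$genomes, function(g) as.character(genomeSequence(g))),
                   lapply(p2$genomes, function(g) as.character(genomeSequence(g))))
  expect_identical(p1$hits, p2$hits)
  expect_identical(p1$tcdb, p2$tcdb)
  expect_identical(truthGenomes(p1$truth), truthGenomes(p2$truth))
  expect_false(identical(p1$hits, generatePanel(defaultPanelSpec(124))$hits))
})

test_that("each genome realizes its assigned organization with planted truth", {
  spec <- PanelSpec(seed = 2,
                    organizationMix = c(A = 2L, B = 2L, C = 2L, D = 2L, E = 2L))
  p <- generatePanel(spec)
  tg <- truthGenomes(p$truth)
  expect_equal(nrow(tg), 10L)
  expect_setequal(unique(tg$organization), c("A", "B", "C", "D", "E"))
  expect_equal(tg$signature[tg$organization == "C"], rep("HNE", 2L))
  # every planted endolysin/holin maps to exactly one generated feature
  ids <- unlist(lapply(p$genomes, function(g)
    S4Vectors::mcols(geneFeatures(g))$feature_id))
  expect_true(all(truthEndolysins(p$truth)$protein_id %in% ids))
  expect_true(all(truthHolins(p$truth)$protein_id %in% ids))
  expect_false(anyDuplicated(c(truthEndolysins(p$truth)$protein_id,
                               truthHolins(p$truth)$protein_id)) > 0L)
})

test_that("unknown organization labels are rejected", {
  expect_error(generatePanel(PanelSpec(seed = 1, organizationMix = c(Z = 1L))),
               "absent from the active catalogue")
})

test_that("an empty spec yields an empty panel and empty truth", {
  p <- generatePanel(PanelSpec(seed = 1, organizationMix = integer(0)))
  expect_length(p$genomes, 0L)
  expect_equal(nrow(truthGenomes(p$truth)), 0L)
  expect_equal(nrow(p$hits), 0L)
})

test_that("noise hits all carry E-values >= 0.01 so filtering removes them", {
  s0 <- PanelSpec(seed = 31, noise = 0)
  s5 <- PanelSpec(seed = 31, noise = 0.5)
  p0 <- generatePanel(s0)
  p5 <- generatePanel(s5)
  noise <- p5$hits[!(p5$hits$protein_id %in% truthEndolysins(p5$truth)$protein_id), ]
  expect_gt(nrow(noise), 0L)
  expect_true(all(noise$e_value >= 0.01))
  f <- tempfile(); writeDomtblout(p5$hits, f)
  kept <- parseDomtblout(f, eCutoff = 0.01)
  expect_equal(sort(unique(kept$protein_id)),
               sort(unique(truthEndolysins(p5$truth)$protein_id)))
  expect_equal(nrow(kept), nrow(p0$hits))
})

test_that("synthetic holins carry the requested hydrophobic helices", {
  h1 <- generateHolinProtein(1L, seed = 7)
  expect_equal(length(h1$segments), 1L)
  expect_true(nchar(h1$protein) >= 60L && nchar(h1$protein) <= 160L)
  # the planted 21-aa block averages above the classical 1.6 cutoff
  kd <- kyteDoolittleScale()
  aa <- strsplit(h1$protein, "")[[1L]]
  seg <- h1$segments
  expect_equal(IRanges::width(seg), 21L)
  expect_gt(mean(kd[aa[IRanges::start(seg):IRanges::end(seg)]]), 1.6)

  h3 <- generateHolinProtein(3L, seed = 7)
  expect_equal(length(h3$segments), 3L)
  gaps <- IRanges::start(h3$segments)[-1L] - IRanges::end(h3$segments)[-3L] - 1L
  expect_true(all(gaps >= 10L))

  expect_identical(generateHolinProtein(2L, seed = 99),
                   generateHolinProtein(2L, seed = 99))
  expect_error(generateHolinProtein(4L, seed = 1), "between 1 and 3")
  expect_error(generateHolinProtein(0L, seed = 1), "between 1 and 3")
})

test_that("the widely separated layout is generated as specified", {
  r <- generateSpQs1Layout(18L, seed = 4)
  ft <- featureTable(r$genome)
  expect_equal(nrow(ft), 20L)
  expect_equal(ft$product[1L], "holin")
  expect_equal(ft$product[20L], "endolysin")
  expect_true(all(ft$strand == "+"))
  expect_equal(r$truth$organization, "none")

  r0 <- generateSpQs1Layout(0L, seed = 4)
  expect_equal(r0$truth$organization, "A")
  expect_equal(nrow(featureTable(r0$genome)), 2L)

  r2 <- generateSpQs1Layout(2L, seed = 4,
                            decoyProducts = c("endonuclease",
                                              "hypothetical protein"))
  expect_equal(featureTable(r2$genome)$product[2L], "endonuclease")
  expect_equal(r2$truth$organization, "intercalated")
})

test_that("overlap pairs honor the requested start offset and frame", {
  r <- generateOverlapPair(39L, seed = 1)
  ft <- r$features
  expect_equal(ft$start[2L] - ft$start[1L], 39L)
  expect_equal(r$truth$overlap_len_nt, 300L - 39L)
  expect_equal(r$truth$frame_offset, 0L)
  expect_equal((ft$end - ft$start + 1L) %% 3L, c(0L, 0L))

  expect_equal(generateOverlapPair(40L, seed = 1)$truth$frame_offset, 1L)
  expect_error(generateOverlapPair(300L, seed = 1, len1 = 300L), "smaller")
  expect_error(generateOverlapPair(0L, seed = 1), "positive")
})

test_that("written panels land on disk in the expected formats", {
  dir <- file.path(tempdir(), "paneldump")
  p <- generatePanel(PanelSpec(seed = 6, organizationMix = c(A = 1L, E = 1L),
                               overlapOffsetNt = 39L))
  writePanel(p, dir)
  expect_length(list.files(dir, pattern = "\\.gbk$"), 2L)
  expect_true(file.exists(file.path(dir, "hits.domtblout")))
  tr <- read.delim(file.path(dir, "truth_overlaps.tsv"))
  expect_equal(tr$start_offset_nt, 39L)
})
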