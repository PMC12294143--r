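test_that("domtblout parsing applies the strict E-value cutoff", {
  hits <- rbind(hitRow("p1", "Amidase_5", 5, 120, e = 1e-6),
                hitRow("p1", "NLPC_P60", 130, 240, e = 5e-3),
                hitRow("p1", "ZoocinA_TRD", 250, 300, e = 0.02))
  f <- tempfile()
  writeDomtblout(hits, f)
  kept <- parseDomtblout(f, eCutoff = 0.01)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$domain_name, c("Amidase_5", "NLPC_P60"))
  # lexicon annotation
  am <- kept[kept$domain_name == "Amidase_5", ]
  expect_equal(am$role, "EAD")
  expect_equal(am$activity, "amidase")
})

test_that("malformed domtblout rows are skipped with a warning; all-bad files error", {
  f <- tempfile()
  writeLines(c("# comment",
               "Amidase_5 - 116 p1 - 400 1e-10 99 0.1 1 1 1e-10 1e-10 99 0.1 1 116 5 120 5 120 0.98 -",
               "broken row"), f)
  expect_warning(kept <- parseDomtblout(f), "malformed")
  expect_equal(nrow(kept), 1L)
  writeLines(c("broken", "also broken"), f)
  expect_error(suppressWarnings(parseDomtblout(f)), "malformed")
  writeLines("# only comments", f)
  expect_equal(nrow(parseDomtblout(f)), 0L)
})

test_that("overlap resolution keeps the dominant hit with a deterministic tie chain", {
  a <- hitRow("p1", "Amidase_5", 1, 120, e = 1e-10)
  b <- hitRow("p1", "Spurious", 50, 130, e = 1e-3)
  r <- resolveOverlaps(rbind(a, b))
  expect_equal(r$domain_name, "Amidase_5")
  # non-overlapping hits both survive
  c2 <- hitRow("p1", "ZoocinA_TRD", 250, 300, e = 1e-4)
  expect_equal(nrow(resolveOverlaps(rbind(a, c2))), 2L)
  # exact duplicates collapse to one
  expect_equal(nrow(resolveOverlaps(rbind(a, a))), 1L)
  # E-value tie broken by bit score, then name
  t1 <- hitRow("p1", "CHAP", 1, 100, e = 1e-5, bits = 50)
  t2 <- hitRow("p1", "Amidase_5", 1, 100, e = 1e-5, bits = 80)
  expect_equal(resolveOverlaps(rbind(t1, t2))$domain_name, "Amidase_5")
  t3 <- hitRow("p1", "CHAP", 1, 100, e = 1e-5, bits = 80)
  expect_equal(resolveOverlaps(rbind(t1, t3))$domain_name, "CHAP")
  expect_error(resolveOverlaps(rbind(a, hitRow("p2", "CHAP", 1, 50))),
               "single protein")
})

test_that("canonical architectures preserve N-to-C arrangement", {
  h <- rbind(hitRow("p1", "Amidase_5", 5, 120),
             hitRow("p1", "NLPC_P60", 130, 240),
             hitRow("p1", "ZoocinA_TRD", 250, 300))
  a <- buildArchitecture("p1", h)
  expect_equal(canonicalArchitecture(a), "Amidase_5 & NLPC_P60 & ZoocinA_TRD")
  expect_true(hasEAD(a) && hasCBD(a))

  cbdOnly <- buildArchitecture("p2", hitRow("p2", "ZoocinA_TRD", 10, 80))
  expect_equal(canonicalArchitecture(cbdOnly), "ZoocinA_TRD")
  expect_false(hasEAD(cbdOnly))
  expect_true(hasCBD(cbdOnly))

  # central CBD between catalytic domains is kept in place
  central <- buildArchitecture("p3", rbind(
    hitRow("p3", "Amidase_5", 1, 90),
    hitRow("p3", "NLPC_P60", 100, 190),
    hitRow("p3", "CW_7", 200, 240),
    hitRow("p3", "Glucosaminidase", 250, 340)))
  expect_equal(canonicalArchitecture(central),
               "Amidase_5 & NLPC_P60 & CW_7 & Glucosaminidase")

  expect_error(buildArchitecture("p1", rbind(h, hitRow("p9", "CHAP", 1, 50))),
               "multiple proteins")
})

test_that("canonical strings are invariant to hit order and to filtered noise", {
  h <- rbind(hitRow("p1", "Amidase_5", 5, 120),
             hitRow("p1", "NLPC_P60", 130, 240),
             hitRow("p1", "ZoocinA_TRD", 250, 300))
  base <- canonicalArchitecture(buildArchitecture("p1", resolveOverlaps(h)))
  for (i in 1:5) {
    hp <- h[sample(nrow(h)), ]
    expect_equal(canonicalArchitecture(
      buildArchitecture("p1", resolveOverlaps(hp))), base)
  }
  withNoise <- rbind(h, hitRow("p1", "LysM", 60, 110, e = 0.05))
  f <- tempfile(); writeDomtblout(withNoise, f)
  kept <- parseDomtblout(f)
  expect_equal(canonicalArchitecture(
    buildArchitecture("p1", resolveOverlaps(kept))), base)
})

test_that("frequency ranking is monotone with deterministic tie-breaks", {
  mk <- function(id, doms) {
    h <- do.call(rbind, lapply(seq_along(doms), function(i)
      hitRow(id, doms[i], (i - 1) * 100 + 1, i * 100 - 10)))
    buildArchitecture(id, h)
  }
  panel <- c(lapply(1:10, function(i) mk(paste0("x", i), "CHAP")),
             lapply(1:3, function(i) mk(paste0("y", i), c("Amidase_5", "LysM"))),
             list(mk("z1", "ZoocinA_TRD")))
  r <- rankArchitectures(panel)
  expect_equal(r$table$label, c("A1", "A2", "A3"))
  expect_equal(r$table$count, c(10L, 3L, 1L))
  expect_true(all(diff(r$table$count) <= 0))
  expect_equal(architectureLabel(r$panel[[1L]]), "A1")

  # tied singletons: lexicographically smaller canonical gets the lower index
  tie <- list(mk("t1", "ZoocinA_TRD"), mk("t2", "Amidase_5"))
  rt <- rankArchitectures(tie)
  expect_equal(rt$table$canonical[rt$table$label == "A1"], "Amidase_5")

  single <- rankArchitectures(list(mk("s", "CHAP")))
  expect_equal(single$table$label, "A1")
  empty <- rankArchitectures(list())
  expect_equal(nrow(empty$table), 0L)
})

test_that("upset marginals equal a brute-force recount", {
  p <- generateArchitectureHits(seed = 3)
  archs <- buildArchitectures(annotateHits(p$hits))
  ranked <- rankArchitectures(archs)
  up <- upsetTable(ranked$panel)
  expect_equal(sum(up$matrix$count), nrow(p$truth))
  # brute force: count proteins containing each domain
  doms <- names(up$marginals)
  brute <- vapply(doms, function(d) {
    sum(vapply(ranked$panel, function(a) d %in% a@domains$domain_name,
               logical(1L)))
  }, integer(1L))
  expect_equal(unname(up$marginals), unname(brute))
  # two identical proteins collapse to one row of count 2
  two <- list(buildArchitecture("q1", hitRow("q1", "CHAP", 1, 90)),
              buildArchitecture("q2", hitRow("q2", "CHAP", 1, 90)))
  u2 <- upsetTable(rankArchitectures(two)$panel)
  expect_equal(nrow(u2$matrix), 1L)
  expect_equal(u2$matrix$count, 2L)
})

test_that("EAD-less architectures report their co-encoded partners", {
  a1 <- buildArchitecture("e1", rbind(hitRow("e1", "Amidase_5", 1, 100),
                                      hitRow("e1", "NLPC_P60", 110, 200),
                                      hitRow("e1", "ZoocinA_TRD", 210, 260)))
  a2 <- buildArchitecture("e2", hitRow("e2", "ZoocinA_TRD", 1, 60))
  plyCA <- buildArchitecture("e3", rbind(hitRow("e3", "CHAP", 1, 100),
                                         hitRow("e3", "PlyCA", 110, 200)))
  plyCB <- buildArchitecture("e4", hitRow("e4", "PlyCB", 1, 70))
  lone <- buildArchitecture("e5", hitRow("e5", "LysM", 1, 50))
  mutans1 <- buildArchitecture("e6", hitRow("e6", "CHAP", 1, 100))
  mutans2 <- buildArchitecture("e7", hitRow("e7", "Glucosaminidase", 1, 100))

  res <- flagAndCooccur(list(G1 = list(a1, a2), C1 = list(plyCA, plyCB),
                             IPP = list(lone), MUT = list(mutans1, mutans2)))
  co <- res$cooccurrence
  expect_equal(co$partners[co$protein_id == "e2"],
               "Amidase_5 & NLPC_P60 & ZoocinA_TRD")
  expect_false(co$exception[co$protein_id == "e2"])
  expect_equal(co$partners[co$protein_id == "e4"], "CHAP & PlyCA")
  expect_true(co$exception[co$protein_id == "e5"])
  fl <- res$flags
  expect_true(all(fl$no_CBD[fl$genome_id == "MUT"]))
  expect_false(any(fl$no_EAD[fl$genome_id == "MUT"]))
})

test_that("zero-noise synthetic architectures are recovered exactly", {
  ref <- referenceArchitectures()
  onePer <- ref; onePer$count <- 1L
  p <- generateArchitectureHits(onePer, seed = 17)
  archs <- buildArchitectures(annotateHits(p$hits))
  got <- vapply(archs, canonicalArchitecture, character(1L))
  expect_equal(unname(got[p$truth$protein_id]), p$truth$architecture)
  expect_equal(length(unique(got)), nrow(ref))
})

test_that("endolysin gene-length bounds hold in the generated panel", {
  p <- generatePanel(PanelSpec(seed = 19))
  te <- truthEndolysins(p$truth)
  for (g in p$genomes) {
    ft <- featureTable(g)
    e <- ft[ft$feature_id %in% te$protein_id, ]
    len <- e$end - e$start + 1L
    expect_true(all(len >= 228L & len <= 1386L))
  }
})
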