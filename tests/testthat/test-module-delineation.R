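test_that("contiguous holin/endolysin pairs form one module classified as A", {
  g <- rolesGenome(c("holin", "endolysin"))
  mods <- delineateModules(g)
  expect_length(mods, 1L)
  m <- classifyOrganization(mods[[1L]])
  expect_equal(roleSignature(m), "HE")
  expect_equal(organizationLabel(m), "A")
  expect_equal(moduleDirection(m), "forward")
  expect_equal(intercalatedCount(m), 0L)
})

test_that("catalogue patterns map signatures to the expected labels", {
  cases <- list(
    list(roles = c("holin", "endolysin"), label = "A"),
    list(roles = c("holin", "holin", "endolysin"), label = "B"),
    list(roles = c("holin", "endonuclease", "endolysin"), label = "C"),
    list(roles = c("endolysin", "holin"), label = "D"),
    list(roles = c("endolysin", "endolysin", "holin"), label = "E"),
    # out of catalogue: three endolysins
    list(roles = c("holin", "holin", "endolysin", "endolysin", "endolysin"),
         label = "unclassified"))
  for (cs in cases) {
    for (strand in c("+", "-")) {
      roles <- if (strand == "-") rev(cs$roles) else cs$roles
      g <- rolesGenome(roles, strand = strand)
      mods <- delineateModules(g)
      expect_length(mods, 1L)
      m <- classifyOrganization(mods[[1L]])
      expect_equal(organizationLabel(m), cs$label,
                   info = paste(cs$roles, collapse = ","))
      expect_equal(moduleDirection(m),
                   if (strand == "+") "forward" else "reverse")
    }
  }
})

test_that("endolysin-first projections never classify into the holin-first group", {
  g <- rolesGenome(c("endolysin", "holin"))
  m <- classifyOrganization(delineateModules(g)[[1L]])
  expect_true(m@organizationLabel %in% c("D", "E"))
  cat <- defaultOrganizationCatalogue()
  expect_false(cat$holin_first[cat$label == organizationLabel(m)])
})

test_that("intercalated endonuclease and hypothetical ORFs are tolerated and counted", {
  g <- rolesGenome(c("holin", "endolysin", "endonuclease", "hypothetical",
                     "endolysin"))
  mods <- delineateModules(g, maxIntercalated = 2L)
  expect_length(mods, 1L)
  m <- mods[[1L]]
  expect_equal(roleSignature(m), "HENXE")
  expect_equal(intercalatedCount(m), 2L)
})

test_that("the 18-gene separation yields zero modules with a diagnostic", {
  roles <- c("holin", rep("hypothetical", 18L), "endolysin")
  g <- rolesGenome(roles)
  mods <- delineateModules(g, maxIntercalated = 2L)
  expect_length(mods, 0L)
  d <- attr(mods, "diagnostics")
  expect_equal(d$intervening_count, 18L)
})

test_that("genomes lacking a holin or an endolysin give an empty result without diagnostics", {
  g <- rolesGenome(c("endolysin", "hypothetical"))
  mods <- delineateModules(g)
  expect_length(mods, 0L)
  expect_null(attr(mods, "diagnostics"))
})

test_that("large intergenic gaps break modules even with few intervening ORFs", {
  df <- rbind(gene("h1", 1L, 300L, product = "holin", role = "holin"),
              gene("e1", 5000L, 5300L, product = "endolysin",
                   role = "endolysin"))
  g <- tinyGenome(df, len = 6000L)
  expect_length(delineateModules(g, maxGapNt = 1000L), 0L)
  expect_length(delineateModules(g, maxGapNt = 10000L), 1L)
})

test_that("delineation is idempotent and ignores decoy content outside the window", {
  spec <- PanelSpec(seed = 21, organizationMix = c(A = 3L, D = 2L),
                    decoyRange = c(0L, 6L), minusFraction = 0.5)
  p <- generatePanel(spec)
  hits <- annotateHits(p$hits[p$hits$e_value < 0.01, ])
  for (g in p$genomes) {
    g2 <- classifyRoles(g, hits = hits)
    m1 <- delineateModules(g2)
    m2 <- delineateModules(g2)
    expect_equal(lapply(m1, roleSignature), lapply(m2, roleSignature))
    expect_length(m1, 1L)
  }
})

test_that("holin-first equals membership of the A-C group over synthetic panels", {
  spec <- PanelSpec(seed = 8, organizationMix = c(A = 4L, B = 3L, C = 3L,
                                                  D = 3L, E = 3L),
                    minusFraction = 0.4)
  p <- generatePanel(spec)
  hits <- annotateHits(p$hits[p$hits$e_value < 0.01, ])
  cat <- defaultOrganizationCatalogue()
  for (g in p$genomes) {
    mods <- delineateModules(classifyRoles(g, hits = hits))
    for (m in mods) {
      m <- classifyOrganization(m)
      sy <- strsplit(roleSignature(m), "")[[1L]]
      holinFirst <- sy[sy %in% c("H", "E")][1L] == "H"
      expect_equal(holinFirst,
                   cat$holin_first[cat$label == organizationLabel(m)])
    }
  }
})

test_that("order statistics reproduce the 85/15 split and edge cases", {
  mk <- function(first) {
    g <- rolesGenome(if (first == "H") c("holin", "endolysin")
                     else c("endolysin", "holin"))
    delineateModules(g)[[1L]]
  }
  panel <- c(replicate(17L, mk("H"), simplify = FALSE),
             replicate(3L, mk("E"), simplify = FALSE))
  st <- orderStatistics(panel)
  expect_equal(unname(st$fractions), c(0.85, 0.15))
  expect_equal(unname(orderStatistics(list(mk("H")))$fractions), c(1, 0))
  expect_equal(unname(orderStatistics(list(mk("E")))$fractions), c(0, 1))
  empty <- orderStatistics(list())
  expect_equal(unname(empty$fractions), c(0, 0))
  expect_equal(empty$n_modules, 0L)
})
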