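test_that("panel matching orders by HPO overlap with category fallback", {
  panels <- makePanels()
  ## single overlap
  expect_equal(matchPanels(c("HP:0008997"), "LGMD", panels), "panel_LGMD")
  ## overlap ordering: larger overlap first
  p2 <- panels
  p2$hpo_terms[p2$panel_id == "panel_PN"] <- "HP:0008997;HP:0003701;HP:0009830"
  got <- matchPanels(c("HP:0008997", "HP:0003701", "HP:0009830"), "LGMD", p2)
  expect_equal(got, c("panel_PN", "panel_LGMD"))
  ## tie broken by panel id
  got <- matchPanels(c("HP:0008997"), "LGMD",
                     rbind(panels,
                           data.frame(panel_id = "panel_AAA", name = "x",
                                      gene = "GNE", mode = "AR",
                                      hpo_terms = "HP:0008997")))
  expect_equal(got, c("panel_AAA", "panel_LGMD"))
  ## no overlap: fall back to the category-mapped panel
  expect_equal(matchPanels("HP:9999999", "LGMD", panels), "panel_LGMD")
  ## no overlap and unknown category: unresolvable
  expect_error(matchPanels("HP:9999999", "not_a_category", panels),
               "no panel resolvable")
})

test_that("MAF filter applies strict inheritance-specific thresholds", {
  expect_true(mafPass(0.005, "AR"))
  expect_false(mafPass(0.005, "AD"))
  expect_false(mafPass(0.005, "XL"))
  ## strict inequality at the threshold
  expect_false(mafPass(0.01, "AR"))
  expect_false(mafPass(0.001, "AD"))
  expect_true(mafPass(0.01 - 1e-12, "AR"))
  ## unobserved counts as zero
  expect_true(mafPass(numeric(0), "AD"))
  expect_true(mafPass(c(NA, NA), "AD"))
  ## max across catalogs governs
  expect_false(mafPass(c(1e-6, 0.02), "AR"))
  expect_error(mafPass(1.2, "AR"), "\\[0, 1\\]")
  expect_error(mafPass(0.001, "mitochondrial"), "AR, AD or XL")
})

test_that("zygosity consistency implements the biallelic-recessive rule", {
  expect_false(zygosityConsistent("het", "AR"))
  expect_true(zygosityConsistent("hom", "AR"))
  expect_true(zygosityConsistent(c("het", "het"), "AR"))
  expect_true(zygosityConsistent("het", "AD"))
  expect_true(zygosityConsistent("hemi", "XL", "M"))
  expect_false(zygosityConsistent("het", "XL", "M"))
  expect_true(zygosityConsistent("het", "XL", "F"))
  expect_false(zygosityConsistent(character(), "AD"))
})

test_that("prioritization keeps planted groups and drops decoys", {
  pb <- makeProband()
  panels <- makePanels()
  vars <- rbind(
    makeVariant("P00001_v01", "DYSF", "hom", 1e-5, pos = 10),
    makeVariant("P00001_v02", "GNE", "het", 1e-6, pos = 20),   # not in panel
    makeVariant("P00001_v03", "CAPN3", "het", 0.02, pos = 30)) # fails AR MAF
  cand <- prioritizeVariants(pb, vars, panels)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene, "DYSF")
  expect_equal(cand$variant_ids, "P00001_v01")
  expect_false(flagExtendedAnalysis(cand))
  ## same variant but common: empty candidate set, extended-analysis flag
  vars2 <- makeVariant("P00001_v01", "DYSF", "hom", 0.02)
  cand2 <- prioritizeVariants(pb, vars2, panels)
  expect_equal(nrow(cand2), 0)
  expect_true(flagExtendedAnalysis(cand2))
  ## compound het flagged phase unconfirmed, ids in position order
  vars3 <- rbind(makeVariant("P00001_v05", "DYSF", "het", NA, pos = 500),
                 makeVariant("P00001_v04", "DYSF", "het", NA, pos = 50))
  cand3 <- prioritizeVariants(pb, vars3, panels)
  expect_equal(cand3$variant_ids, "P00001_v04;P00001_v05")
  expect_equal(cand3$phase_note, "phase unconfirmed")
})

test_that("lowering a variant's frequency never removes it from candidates", {
  pb <- makeProband()
  panels <- makePanels()
  set.seed(101)
  for (rep in 1:25) {
    af <- 10^stats::runif(1, -6, -1.4)
    vars <- rbind(
      makeVariant("P00001_v01", "DYSF", "hom", af, pos = 10),
      makeVariant("P00001_v02", "CAV3", "het", 10^stats::runif(1, -6, -2),
                  pos = 20))
    before <- prioritizeVariants(pb, vars, panels)
    vars$af_gnomad <- vars$af_gnomad / 10
    after <- prioritizeVariants(pb, vars, panels)
    genesBefore <- unlist(strsplit(before$variant_ids, ";"))
    genesAfter <- unlist(strsplit(after$variant_ids, ";"))
    expect_true(all(genesBefore %in% genesAfter))
  }
})
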