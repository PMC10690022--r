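makeOutcomes <- function(n, nSolved, nPossibly = 0, modality = "WES",
                         category = "LGMD") {
  data.frame(proband_id = sprintf("P%05d", seq_len(n)),
             category = rep(category, length.out = n),
             modality = rep(modality, length.out = n),
             outcome = c(rep("solved", nSolved),
                         rep("possibly_solved", nPossibly),
                         rep("unsolved", n - nSolved - nPossibly)),
             stringsAsFactors = FALSE)
}

test_that("yield table derives percentages from counts with half-up display", {
  yt <- yieldTable(makeOutcomes(10, 5))
  expect_equal(yt$pct_solved, 50)
  expect_equal(yt$solved + yt$possibly_solved + yt$unsolved, yt$n)
  ## the single-gene-test exemplar: 43/80 = 53.75 displays as 54
  sgt <- yieldTable(makeOutcomes(80, 43, modality = "SGT"), by = "modality")
  expect_equal(sgt$pct_solved, 53.75)
  expect_equal(sgt$pct_solved_display, 54)
  ## combined column recomputed from counts
  both <- yieldTable(makeOutcomes(100, 41, 15))
  expect_equal(both$pct_combined, 56)
  expect_error(yieldTable(makeOutcomes(5, 1), by = "no_such_key"),
               "unknown grouping key")
  expect_error(yieldTable(makeOutcomes(0, 0)), "empty")
})

test_that("gene frequency counts probands per gene with PMP22 mechanisms split", {
  outcomes <- makeOutcomes(10, 3)
  causal <- data.frame(
    proband_id = c("P00001", "P00002", "P00003", "P00004"),
    category = "PN",
    gene = c("GJB1", "GJB1", "PMP22", "PMP22"),
    hgvs_c = c("c.1A>G", "c.2A>G", "c.3A>G", "c.4_400dup"),
    consequence = c("missense", "missense", "missense", "exonic_duplication"),
    acmg_class = "Pathogenic", novel = FALSE, stringsAsFactors = FALSE)
  gf <- geneFrequency(outcomes, causal)
  expect_equal(gf$gene[1], "GJB1")
  expect_equal(gf$n[gf$gene == "GJB1"], 2)
  ## duplication and point mutation tracked as distinct mechanism labels
  expect_true(all(c("PMP22 dup", "PMP22 pm") %in% gf$gene))
  expect_equal(gf$percent[gf$gene == "GJB1"], 20)
  ## a compound het counts its proband once
  causal2 <- rbind(causal, causal[1, ])
  gf2 <- geneFrequency(outcomes, causal2)
  expect_equal(gf2$n[gf2$gene == "GJB1"], 2)
})

test_that("novel fraction is computed over causal variants with category breakdown", {
  causal <- data.frame(proband_id = sprintf("P%d", 1:7),
                       category = c(rep("PN", 4), rep("LGMD", 3)),
                       gene = "G", hgvs_c = "c.1A>G", consequence = "missense",
                       acmg_class = "VUS",
                       novel = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  nf <- novelFraction(causal)
  expect_equal(nf$overall, 2 / 7)
  expect_equal(nf$by_category$fraction[nf$by_category$category == "PN"], 0.5)
  expect_warning(empty <- novelFraction(NULL), "undefined")
  expect_true(is.na(empty$overall))
})
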