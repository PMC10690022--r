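classifyOne <- function(variants, proband = makeProband(),
                        panels = makePanels(), fit = NULL) {
  variants <- classifyVariants(variants)
  cand <- prioritizeVariants(proband, variants, panels)
  if (is.null(fit)) fit <- rep(TRUE, nrow(cand))
  classifyOutcome(proband, cand, variants, phenotypeFit = fit)
}

test_that("outcome rules implement solved / possibly solved / unsolved", {
  ## homozygous LP variant in an AR panel gene, fitting phenotype: solved
  lp <- makeVariant("P00001_v01", "DYSF", "hom", NA, evidence = "PS1;PM1",
                    insilico = TRUE)
  out <- classifyOne(lp)
  expect_equal(out$outcome, "solved")
  expect_equal(out$causal_gene, "DYSF")
  ## single heterozygous VUS in an AR gene fails the biallelic requirement
  vus <- makeVariant("P00001_v01", "DYSF", "het", 5e-5, evidence = "PP3",
                     insilico = TRUE)
  expect_equal(classifyOne(vus)$outcome, "unsolved")
  ## homozygous ultra-rare supported VUS: possibly solved
  vus2 <- makeVariant("P00001_v01", "DYSF", "hom", 5e-5, evidence = "PP3",
                      insilico = TRUE)
  expect_equal(classifyOne(vus2)$outcome, "possibly_solved")
  ## same but too common for the 0.01% rule: unsolved
  vus3 <- makeVariant("P00001_v01", "DYSF", "hom", 5e-3, evidence = "PP3",
                      insilico = TRUE)
  expect_equal(classifyOne(vus3)$outcome, "unsolved")
  ## same but without in-silico support: unsolved
  vus4 <- makeVariant("P00001_v01", "DYSF", "hom", 5e-5, evidence = "PP3",
                      insilico = FALSE)
  expect_equal(classifyOne(vus4)$outcome, "unsolved")
  ## phenotype fit is required even for P/LP
  expect_equal(classifyOne(lp, fit = FALSE)$outcome, "unsolved")
})

test_that("a passing decoy sharing the causal gene does not spoil the call", {
  vars <- rbind(
    makeVariant("P00001_v01", "DYSF", "hom", NA, evidence = "PVS1;PS3",
                insilico = TRUE, pos = 10),
    makeVariant("P00001_v02", "DYSF", "het", 2e-3, evidence = "",
                insilico = FALSE, pos = 20))
  out <- classifyOne(vars)
  expect_equal(out$outcome, "solved")
  expect_equal(out$causal_variants, "P00001_v01")
})

test_that("missing ACMG class on a candidate is a validation error", {
  pb <- makeProband()
  v <- makeVariant("P00001_v01", "DYSF", "hom", NA, evidence = "PS1;PM1")
  cand <- prioritizeVariants(pb, classifyVariants(v), makePanels())
  expect_error(classifyOutcome(pb, cand, v), "acmg_class")
})

test_that("end-to-end recovery of planted truth is exact on a synthetic cohort", {
  cfg <- cohortConfig(seed = 13)
  sim <- simulateCohortVariants(simulateCohort(cfg, 500), cfg)
  catalogs <- simulateCatalogs(sim$variants, sim$truth)
  cls <- classifyCohort(sim$probands, sim$variants, defaultPanels(), catalogs)
  expect_identical(cls$outcomes$proband_id, sim$truth$proband_id)
  ## exact label recovery
  expect_identical(cls$outcomes$outcome, sim$truth$outcome)
  ## causal gene recovery on non-unsolved probands
  idx <- sim$truth$outcome != "unsolved"
  expect_identical(cls$outcomes$causal_gene[idx], sim$truth$causal_gene[idx])
  ## outcome-record invariants
  for (i in which(idx)) {
    cl <- strsplit(cls$outcomes$variant_classes[i], ";")[[1]]
    if (cls$outcomes$outcome[i] == "solved")
      expect_true(all(cl %in% c("Pathogenic", "Likely pathogenic")))
    else
      expect_true(any(cl == "VUS"))
  }
  expect_true(all(cls$outcomes$causal_variants[!idx] == ""))
  ## novelty flags recovered exactly from the synthetic catalogs
  planted <- rep(sim$truth$novel[idx],
                 lengths(strsplit(sim$truth$causal_variant_ids[idx], ";")))
  nf <- novelFraction(cls$causal)
  expect_equal(nrow(cls$causal), length(planted))
  expect_equal(nf$overall, mean(planted), tolerance = 1e-12)
})
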