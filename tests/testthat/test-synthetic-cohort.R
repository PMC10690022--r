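test_that("degenerate category weights give a single-category cohort", {
  cfg <- cohortConfig(seed = 3, categoryWeights = c(LGMD = 1.0))
  sim <- simulateCohort(cfg, 5)
  expect_equal(nrow(sim$probands), 5)
  expect_true(all(sim$probands$category == "LGMD"))
  expect_true(all(nchar(sim$probands$hpo_pos) > 0))
})

test_that("cohort generation is deterministic and substream-stable", {
  cfg <- cohortConfig(seed = 42)
  a <- simulateCohort(cfg, 40)
  b <- simulateCohort(cfg, 40)
  expect_identical(a, b)
  ## enlarging the cohort must not reshuffle earlier probands
  big <- simulateCohort(cfg, 60)
  expect_identical(a$probands, big$probands[1:40, ])
  expect_identical(a$truth, big$truth[1:40, ])
})

test_that("configured composition, sex ratio and age model are recovered", {
  cfg <- cohortConfig(seed = 9)
  n <- 30000
  sim <- simulateCohort(cfg, n)
  w <- categoryWeights(cfg)
  for (cat in names(w)) {
    phat <- mean(sim$probands$category == cat)
    se <- sqrt(w[[cat]] * (1 - w[[cat]]) / n)
    expect_lt(abs(phat - w[[cat]]), 4 * se)
  }
  expect_lt(abs(mean(sim$probands$sex == "M") - 0.65),
            4 * sqrt(0.65 * 0.35 / n))
  expect_lt(abs(stats::median(sim$probands$age) - 26), 1)
  expect_lt(abs(mean(sim$probands$age <= 18) - 0.35),
            4 * sqrt(0.35 * 0.65 / n))
})

test_that("planted variants honour outcome, inheritance and zygosity rules", {
  cfg <- cohortConfig(seed = 17)
  sim <- simulateCohort(cfg, 300)
  sv <- simulateCohortVariants(sim, cfg)
  ## every causal variant id resolves to a generated variant, and only
  ## non-unsolved probands have causal variants
  for (i in seq_len(nrow(sv$truth))) {
    tr <- sv$truth[i, ]
    ids <- strsplit(tr$causal_variant_ids, ";")[[1]]
    if (tr$outcome == "unsolved") {
      expect_length(ids, 0)
    } else {
      expect_true(all(ids %in% sv$variants$id))
      vg <- sv$variants[sv$variants$id %in% ids, ]
      expect_true(all(vg$gene == tr$causal_gene))
      if (tr$mode == "AR")
        expect_true((nrow(vg) == 1 && vg$zygosity == "hom") ||
                      (nrow(vg) == 2 && all(vg$zygosity == "het")))
      if (tr$outcome == "possibly_solved") {
        maxAf <- suppressWarnings(max(c(vg$af_gnomad, vg$af_local), na.rm = TRUE))
        expect_true(!is.finite(maxAf) || maxAf < 1e-4)
      }
    }
  }
  ## decoy frequencies straddle both MAF thresholds
  decoys <- sv$variants[!sv$variants$id %in%
                          unlist(strsplit(sv$truth$causal_variant_ids, ";")), ]
  expect_gt(sum(decoys$af_gnomad > 0.01), 0)
  expect_gt(sum(decoys$af_gnomad < 0.001), 0)
})

test_that("truth/proband mismatch is a consistency error", {
  cfg <- cohortConfig(seed = 2)
  sim <- simulateCohort(cfg, 2)
  expect_error(simulateVariants(sim$probands[1, ], sim$truth[2, ], cfg),
               "does not match")
})

test_that("DMD cohort generator honours country mixes and breakpoints", {
  cfg <- cohortConfig(seed = 21)
  ## a country with duplication weight zero yields no duplications
  sv <- simulateDmdCohort(cfg, 400, countries = "India")
  expect_equal(sum(sv$kind == "duplication"), 0)
  expect_true(all(sv$country == "India"))
  ## unknown country is a configuration error
  expect_error(simulateDmdCohort(cfg, 5, countries = "Atlantis"), "Atlantis")
  ## degenerate breakpoint weights put the single deletion in intron 45
  w <- stats::setNames(rep(0, 79), as.character(0:78)); w["45"] <- 1
  cfgBp <- cohortConfig(seed = 4,
                        dmdCountryTypeMix = rbind(India = c(1, 0, 0, 0)) |>
                          (\(m) {colnames(m) <- c("deletion", "nonsense",
                                                  "duplication", "splice"); m})(),
                        dmdBreakpointWeights = w)
  one <- simulateDmdCohort(cfgBp, 1, countries = "India")
  expect_equal(one$kind, "deletion")
  expect_true("45" %in% breakpointIntrons(one$first_exon, one$last_exon))
})

test_that("empirical hotspot fraction matches the analytic mixture probability", {
  cfg <- cohortConfig(seed = 31)
  sv <- simulateDmdCohort(cfg, 6000)
  h <- hotspotSummary(sv)
  p <- dmdHotspotProbability(cfg)
  se <- sqrt(p * (1 - p) / h$n_deldup)
  expect_lt(abs(h$fraction_hotspot - p), 4 * se)
})
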