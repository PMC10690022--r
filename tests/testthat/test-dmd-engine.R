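model <- dmdExonModel()

test_that("packaged exon model is a complete 79-exon CDS", {
  expect_equal(exonCount(model), 79)
  len <- exonLengths(model)
  expect_true(all(len > 0))
  expect_equal(sum(len) %% 3, 0)
  expect_equal(sum(len), 11058)
  ## clinically established sizes in the skipping region
  expect_equal(unname(len[c("44", "45", "50", "51", "52", "53")]),
               c(148, 176, 109, 233, 118, 212))
})

test_that("frame rule matches clinical exemplars and handles terminal exons", {
  expect_equal(frameStatus(52, 52, model), "out_of_frame")
  expect_equal(frameStatus(45, 47, model), "in_frame")
  expect_equal(frameStatus(45, 48, model), "in_frame")
  expect_equal(frameStatus(45, 50, model), "out_of_frame")
  expect_equal(frameStatus(1, 3, model), "inapplicable")
  expect_equal(frameStatus(70, 79, model), "inapplicable")
  expect_error(frameStatus(0, 5, model), "exon interval")
  expect_error(frameStatus(10, 80, model), "exon interval")
})

test_that("frame rule agrees with the nucleotide-layout oracle on all 3160 intervals", {
  oracle <- makeFrameOracle(model)
  for (a in 1:79) for (b in a:79)
    expect_identical(frameStatus(a, b, model), oracle(a, b),
                     info = sprintf("del %d-%d", a, b))
})

test_that("deletion and duplication of the same interval share frame status", {
  set.seed(5)
  for (rep in 1:50) {
    a <- sample(2:78, 1); b <- if (a == 78) 78L else sample(a:78, 1)
    expect_identical(predictSeverity("deletion", a, b, model) == "BMD_like",
                     predictSeverity("duplication", a, b, model) == "BMD_like")
  }
})

test_that("severity prediction follows the frame rule and truncation logic", {
  expect_equal(predictSeverity("deletion", 45, 47, model), "BMD_like")
  expect_equal(predictSeverity("deletion", 52, 52, model), "DMD_like")
  expect_equal(predictSeverity("nonsense", model = model), "DMD_like")
  expect_equal(predictSeverity("small_frameshift", model = model), "DMD_like")
  expect_equal(predictSeverity("deletion", 75, 79, model), "indeterminate")
})

test_that("single-exon skipping amenability requires adjacency and frame restoration", {
  expect_true(skipAmenable(52, 52, 51, model))
  expect_true(skipAmenable(52, 52, 53, model))
  expect_false(skipAmenable(52, 52, 45, model))   # not adjacent
  ## in-frame deletions are not amenable by definition
  expect_false(skipAmenable(45, 47, 48, model))
  ## skip-closure: every amenable skip restores the frame
  for (a in 2:78) for (b in a:78) {
    if (frameStatus(a, b, model) != "out_of_frame") next
    for (e in c(a - 1, b + 1)) {
      if (e < 1 || e > 79) next
      if (skipAmenable(a, b, e, model))
        expect_equal(frameStatus(min(a, e), max(b, e), model), "in_frame",
                     info = sprintf("del %d-%d skip %d", a, b, e))
    }
  }
})

test_that("therapy-exon reporting returns the amenable licensed/trial subsets", {
  am <- amenableTherapyExons(52, 52, model)
  expect_equal(am$licensed, c(51, 53))
  expect_equal(am$trial, integer(0))
  am2 <- amenableTherapyExons(45, 50, model)
  expect_true(51 %in% am2$licensed)
  expect_false(45 %in% am2$licensed)
  ## deletion of exon 45 alone is the classic exon-44 trial case
  am3 <- amenableTherapyExons(45, 45, model)
  expect_equal(am3$trial, 44)
  ## in-frame deletion: nothing amenable
  am4 <- amenableTherapyExons(45, 47, model)
  expect_equal(lengths(am4), c(licensed = 0L, trial = 0L))
})

test_that("breakpoints map to flanking introns with boundary sentinels", {
  expect_equal(breakpointIntrons(46, 50), c("45", "50"))
  expect_equal(breakpointIntrons(1, 3), c("5prime", "3"))
  expect_equal(breakpointIntrons(2, 2), c("1", "2"))
  expect_equal(breakpointIntrons(77, 79), c("76", "3prime"))
})

test_that("hotspot summary counts variants once per touched intron", {
  one <- data.frame(kind = "deletion", first_exon = 46, last_exon = 50)
  h <- hotspotSummary(one)
  expect_equal(h$n_deldup, 1)
  expect_equal(h$counts$proportion[h$counts$intron == "45"], 1)
  expect_equal(h$fraction_hotspot, 1)
  two <- rbind(one, data.frame(kind = "duplication", first_exon = 11,
                               last_exon = 20))
  h2 <- hotspotSummary(two)
  expect_equal(h2$counts$proportion[h2$counts$intron == "45"], 0.5)
  expect_equal(h2$fraction_hotspot, 0.5)
  expect_warning(h0 <- hotspotSummary(one[0, ]), "empty")
  expect_equal(h0$n_deldup, 0)
})

test_that("variant type table cross-tabulates country by type", {
  fix <- loadFixture("dmd_counts")
  long <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i)
    data.frame(country = fix$country[i],
               kind = rep(c("deletion", "nonsense", "duplication", "splice"),
                          times = unlist(fix[i, -1])))))
  tab <- variantTypeTable(long)
  expect_equal(unname(rowSums(tab)[c("India", "South Africa")]), c(64, 40))
  expect_equal(unname(tab["India", ]), c(60, 3, 0, 1))
  ## a single Brazilian deletion + nonsense
  bz <- variantTypeTable(data.frame(country = "Brazil",
                                    kind = c("deletion", "nonsense")))
  expect_equal(unname(bz["Brazil", ]), c(1, 1, 0, 0))
  expect_equal(nrow(variantTypeTable(long[0, ])), 0)
  expect_error(variantTypeTable(data.frame(country = "x", kind = "inversion")),
               "unknown DMD variant type")
})

test_that("per-patient report combines frame, severity and amenability", {
  sv <- data.frame(sample_id = c("a", "b", "c"), country = "India",
                   kind = c("deletion", "nonsense", "deletion"),
                   first_exon = c(52, NA, 45), last_exon = c(52, NA, 47),
                   locus = c(NA, "exon30", NA))
  rep <- dmdReport(sv, model)
  expect_equal(rep$frame, c("out_of_frame", "inapplicable", "in_frame"))
  expect_equal(rep$severity, c("DMD_like", "DMD_like", "BMD_like"))
  expect_equal(rep$amenable_licensed, c("51;53", "", ""))
})
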