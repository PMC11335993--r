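test_that("generators are deterministic under a fixed seed", {
  a <- simulateQuantExperiment(nProteins = 100, spikeFraction = 0.1,
                               spikeLog2fc = 2, seed = 7)
  b <- simulateQuantExperiment(nProteins = 100, spikeFraction = 0.1,
                               spikeLog2fc = 2, seed = 7)
  expect_identical(assay(a$quant), assay(b$quant))
  expect_identical(a$truth, b$truth)

  ca <- simulateAnnotationCatalog(60, plantedSet = "prot0001", seed = 3)
  cb <- simulateAnnotationCatalog(60, plantedSet = "prot0001", seed = 3)
  expect_identical(ca$annotations, cb$annotations)
  expect_identical(diseaseTerms(ca$catalog), diseaseTerms(cb$catalog))

  sa <- simulateScoreTable(list(x = c("p1", "p2")), seed = 5)
  sb <- simulateScoreTable(list(x = c("p1", "p2")), seed = 5)
  expect_identical(sa, sb)

  ea <- simulateExpressionSeries(nGenes = 20, seed = 9)
  eb <- simulateExpressionSeries(nGenes = 20, seed = 9)
  expect_identical(ea, eb)
})

test_that("no-signal no-noise experiment has exactly equal paired intensities", {
  sim <- simulateQuantExperiment(nProteins = 30, spikeFraction = 0,
                                 noiseSd = 0, missingRate = 0, seed = 2)
  m <- assay(sim$quant)
  cd <- colData(sim$quant)
  for (p in unique(cd$pair)) {
    expect_equal(m[, cd$condition == "case" & cd$pair == p],
                 m[, cd$condition == "control" & cd$pair == p])
  }
  d <- pairedLogFoldChange(sim$quant)
  expect_true(all(d$log2fc == 0))
})

test_that("observed mean log2FC over the spiked set matches the generative effect", {
  sim <- simulateQuantExperiment(nProteins = 2000, spikeFraction = 0.1,
                                 spikeLog2fc = 3, noiseSd = 0.2,
                                 missingRate = 0, seed = 11)
  d <- pairedLogFoldChange(sim$quant)
  obs <- mean(d[sim$truth$spiked, "log2fc"])
  expect_lt(abs(obs - 3), 0.1)
  expect_lt(abs(mean(d[setdiff(rownames(d), sim$truth$spiked), "log2fc"])),
            0.1)
})

test_that("a sub-unity expected spike count warns and produces zero spikes", {
  expect_warning(
    sim <- simulateQuantExperiment(nProteins = 10, spikeFraction = 0.05,
                                   seed = 1),
    "no proteins spiked")
  expect_length(sim$truth$spiked, 0)
})

test_that("catalog generator produces the reference disease structure", {
  ann <- simulateAnnotationCatalog(50, nDiseasesArd = 38, nDiseasesNard = 12,
                                   nCategories = 5, seed = 4)
  expect_length(ardIds(ann$catalog), 38)
  expect_length(nardIds(ann$catalog), 12)
  info <- diseaseInfo(ann$catalog)
  expect_setequal(unique(info$category[info$age_related]), CARD_CATEGORIES)
  expect_true(all(lengths(ann$orthology) %in% 1:3))
})

test_that("boosted sharing separates planted proteins by direct counting", {
  planted <- sprintf("prot%04d", 1:50)
  ann <- simulateAnnotationCatalog(300, plantedSet = planted,
                                   sharingBoost = 20, seed = 8)
  prof <- shareCounts(sprintf("prot%04d", 1:300), ann$catalog,
                      ann$annotations, ann$orthology)
  med_planted <- median(prof[planted, "shared_ard"])
  med_bg <- median(prof[sprintf("prot%04d", 51:300), "shared_ard"])
  expect_gt(med_planted, med_bg)
})

test_that("score table covers each set once and honours planted log10 shifts", {
  tab <- simulateScoreTable(list(a = "p1", b = "p2", c = "p3"), seed = 1)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$set, c("a", "b", "c"))

  ids <- sprintf("s%03d", 1:400)
  tab2 <- simulateScoreTable(
    list(planted = ids[1:200], background = ids[201:400]),
    shifts = c(planted = 1.97), noiseSd = 1e-4, seed = 2)
  fold <- supersaturationFold(tab2, ids[1:200], ids[201:400])
  expect_equal(fold$fold, 10^1.97, tolerance = 0.01)
  expect_error(simulateScoreTable(list(a = "p1"), shifts = c(zz = 1)),
               "unknown set")
})

test_that("expression generator plants recoverable monotone trends", {
  expect_error(simulateExpressionSeries(timepoints = c(2, 4)), "fewer than 3")
  expect_error(simulateExpressionSeries(timepoints = c(2, 2, 4)),
               "strictly increasing")
  es <- simulateExpressionSeries(nGenes = 40, trendFraction = 0.5,
                                 trendSlope = 1, noiseSd = 0, nDatasets = 1,
                                 seed = 6)
  up <- es$truth$gene_id[es$truth$trend == 1][1]
  d <- es$expr[es$expr$gene_id == up, ]
  expect_equal(spearmanRho(d$age_day, d$value)$rho, 1)
})
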