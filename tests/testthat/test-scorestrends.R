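test_that("score comparison detects a planted shift with positive direction", {
  ids <- sprintf("s%03d", 1:900)
  sets <- list(shifted = ids[1:300], bg1 = ids[301:600], bg2 = ids[601:900])
  tab <- simulateScoreTable(sets, shifts = c(shifted = 2), noiseSd = 1,
                            seed = 3)
  cmp <- compareScores(tab, sets, "camsol")
  expect_lt(cmp$p, 1e-6)
  pw <- cmp$pairwise
  hit <- pw[pw$group1 == "shifted" | pw$group2 == "shifted", ]
  expect_true(all(hit$p_adj < 0.01))
  dirs <- ifelse(hit$group1 == "shifted", hit$direction, -hit$direction)
  expect_true(all(dirs > 0))
  # the bg1-bg2 comparison is null
  nullrow <- pw[pw$group1 %in% c("bg1", "bg2") &
                  pw$group2 %in% c("bg1", "bg2"), ]
  expect_gt(nullrow$p_adj, 0.05)
})

test_that("score comparison H matches the rank-formula oracle on shared core", {
  tab <- data.frame(protein_id = paste0("p", 1:6),
                    camsol = c(1, 2, 3, 4, 5, 6))
  sets <- list(a = paste0("p", 1:3), b = paste0("p", 4:6))
  cmp <- compareScores(tab, sets, "camsol")
  expect_equal(cmp$H, kw_H_oracle(1:6, rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)
  expect_error(compareScores(tab, list(a = "p1", b = paste0("p", 2:6)),
                             "camsol"), "fewer than 2")
})

test_that("supersaturation fold is a ratio of linear-scale means", {
  tab <- data.frame(protein_id = paste0("p", 1:8),
                    sigma_f = c(rep(94 * 3, 4), rep(3, 4)))
  f <- supersaturationFold(tab, paste0("p", 1:4), paste0("p", 5:8))
  expect_equal(f$fold, 94)
  expect_equal(f$foldGeometric, 94, tolerance = 1e-10)

  ident <- supersaturationFold(tab, paste0("p", 1:8), paste0("p", 1:8))
  expect_equal(ident$fold, 1)

  set.seed(10)
  tab2 <- data.frame(protein_id = paste0("q", 1:50),
                     sigma_f = 10^rnorm(50))
  a <- paste0("q", 1:20); b <- paste0("q", 21:50)
  f2 <- supersaturationFold(tab2, a, b)
  expect_equal(f2$fold, mean(tab2$sigma_f[1:20]) / mean(tab2$sigma_f[21:50]),
               tolerance = 1e-12)  # naive mean-ratio oracle
  # scale equivariance: multiplying all sigma_f by c leaves the ratio fixed
  tab3 <- tab2; tab3$sigma_f <- tab3$sigma_f * 7.3
  expect_equal(supersaturationFold(tab3, a, b)$fold, f2$fold,
               tolerance = 1e-12)
})

test_that("aging trend classifies noiseless monotone genes correctly", {
  es <- simulateExpressionSeries(nGenes = 40, trendFraction = 0.5,
                                 trendSlope = 1, noiseSd = 0.01,
                                 nDatasets = 2, seed = 5)
  tr <- agingTrend(es$expr)
  res <- tr$results
  truth <- setNames(es$truth$trend, es$truth$gene_id)
  planted_up <- names(truth)[truth == 1]
  planted_down <- names(truth)[truth == -1]
  expect_true(all(res$class[match(planted_up, res$gene_id)] == "up"))
  expect_true(all(res$class[match(planted_down, res$gene_id)] == "down"))
  # equal planted up/down -> ratio near 1
  expect_equal(tr$summary$up_down_ratio, 1, tolerance = 0.3)
})

test_that("trend recovery and sign agreement with planted ground truth", {
  es <- simulateExpressionSeries(nGenes = 300, trendFraction = 0.1,
                                 trendSlope = 0.5, noiseSd = 0.2,
                                 nDatasets = 2, seed = 7)
  tr <- agingTrend(es$expr)
  res <- tr$results
  truth <- setNames(es$truth$trend, es$truth$gene_id)
  planted <- names(truth)[truth != 0]
  called <- res$gene_id[res$class %in% c("up", "down")]
  expect_gte(mean(planted %in% called), 0.9)
  sgn <- ifelse(res$class == "up", 1, ifelse(res$class == "down", -1, 0))
  names(sgn) <- res$gene_id
  calledPlanted <- intersect(called, planted)
  expect_true(all(sgn[calledPlanted] == truth[calledPlanted]))
  # null genes rarely called
  expect_lte(mean(setdiff(names(truth), planted) %in% called), 0.05 + 0.04)
})

test_that("trend analysis windows days and flags short series untested", {
  expr <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 6),
    age_day = rep(c(1, 2, 4, 6, 10, 14), 2),
    value = c(1, 2, 3, 4, 5, 6, 9, 1, 1, 1, 1, 9),
    dataset_id = "ds")
  tr <- agingTrend(expr, dayWindow = c(2, 10))
  expect_equal(tr$results[tr$results$gene_id == "g1", "n"], 4)
  expect_equal(tr$results[tr$results$gene_id == "g1", "rho"], 1)

  short <- data.frame(gene_id = "g3", age_day = c(2, 4), value = c(1, 2),
                      dataset_id = "ds")
  tr2 <- agingTrend(short)
  expect_equal(tr2$results$class, "untested")
})
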