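test_that("paired fold-change handles exact and degenerate cases", {
  # per-pair ratios of exactly 4 -> log2fc = 2, zero-variance differences
  q <- quant_from_ratios(matrix(4, 1, 3))
  d <- pairedLogFoldChange(q)
  expect_equal(d$log2fc, 2)
  expect_equal(d$p, 1e-15)

  # identical case/control in every pair -> log2fc 0, p 1
  q0 <- quant_from_ratios(matrix(1, 2, 4))
  d0 <- pairedLogFoldChange(q0)
  expect_equal(d0$log2fc, c(0, 0))
  expect_equal(d0$p, c(1, 1))
})

test_that("paired t p-values match the textbook oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    ratios <- matrix(2^rnorm(4, sd = 1.5), 1, 4)
    q <- quant_from_ratios(ratios)
    d <- pairedLogFoldChange(q)
    dd <- log2(as.vector(ratios))
    tor <- mean(dd) / (sd(dd) / sqrt(4))
    por <- 2 * pt(-abs(tor), df = 3)
    expect_equal(d$t_stat, tor, tolerance = 1e-10)
    expect_equal(d$p, por, tolerance = 1e-10)
    # cross-check against stats::t.test as an independent implementation
    expect_equal(d$p, t.test(dd)$p.value, tolerance = 1e-10)
  }
})

test_that("proteins without two complete pairs are untested; zeros are missing", {
  m <- matrix(c(4, NA, NA, NA, 1, 1, 1, 1,
                8, 8, 0, 8, 2, 2, 2, 2), 2, 8, byrow = TRUE,
              dimnames = list(c("few", "zero"), NULL))
  q <- InsolubleQuant(m, condition = rep(c("case", "control"), each = 4),
                      pair = rep(1:4, 2), uniquePeptides = c(3, 3))
  d <- pairedLogFoldChange(q)
  expect_false(d["few", "tested"])
  expect_true(is.na(d["few", "p"]))
  expect_equal(d["zero", "n_pairs_used"], 3)  # the zero intensity dropped
  expect_equal(d["zero", "log2fc"], 2)
})

test_that("Storey q-values reduce to BH with pi0 = 1 and are rank-monotone", {
  set.seed(7)
  for (i in 1:10) {
    p <- runif(200)^(1 + i / 5)
    q1 <- storeyQValues(p, pi0 = 1)$q
    expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(q1, bh_stepup(p), tolerance = 1e-12)
    qs <- storeyQValues(p)
    expect_true(all(diff(qs$q[order(p)]) >= -1e-12))
    expect_true(qs$pi0 > 0 && qs$pi0 <= 1)
  }
  expect_error(storeyQValues(numeric()), "empty")
})

test_that("all-unit p-values give pi0 = 1 and q = 1", {
  qm <- storeyQValues(rep(1, 50))
  expect_equal(qm$pi0, 1)
  expect_equal(qm$q, rep(1, 50))
})

test_that("pi0 estimate is calibrated under the uniform null", {
  # frozen seeds; oracle = the Monte-Carlo distribution of the estimator
  for (s in 1:5) {
    set.seed(100 + s)
    qm <- storeyQValues(runif(1000))
    expect_gte(qm$pi0, 0.85)
    expect_lte(qm$pi0, 1)
  }
})

test_that("bootstrap pi0 method runs and stays in (0, 1]", {
  set.seed(1)
  qm <- storeyQValues(runif(300), method = "bootstrap", nBoot = 25)
  expect_true(qm$pi0 > 0 && qm$pi0 <= 1)
})

test_that("significance filters implement the printed thresholds exactly", {
  d <- S4Vectors::DataFrame(
    log2fc = c(0.50, 1.2, 1.2, 1.2, -1.2),
    q = c(0.001, 0.005, 0.02, 0.005, 0.001),
    unique_peptides = c(5L, 1L, 5L, 5L, 5L),
    tested = TRUE,
    row.names = c("lowfc", "onepep", "highq", "good", "down"))
  s <- callSignificant(d)
  expect_identical(members(s), "good")  # 0.50 < 0.58; 1 peptide; q >= 0.01
  expect_identical(members(callSignificant(d, direction = "down")), "down")
  expect_setequal(members(callSignificant(d, direction = "both")),
                  c("good", "down"))
})

test_that("total insoluble comparison normalizes to control means", {
  # case totals uniformly x2 the control
  m <- rbind(rep(c(200, 100), each = 4))
  q <- InsolubleQuant(m, condition = rep(c("case", "control"), each = 4),
                      pair = rep(1:4, 2), uniquePeptides = 1)
  tc <- totalInsolubleCompare(q)
  expect_equal(tc$totals$normalized[tc$totals$condition == "case"],
               rep(2, 4))
  expect_equal(tc$totals$normalized[tc$totals$condition == "control"],
               rep(1, 4))

  # identical arms: full ties -> midrank p of 1
  m2 <- rbind(rep(100, 8))
  q2 <- InsolubleQuant(m2, condition = rep(c("case", "control"), each = 4),
                       pair = rep(1:4, 2), uniquePeptides = 1)
  expect_equal(totalInsolubleCompare(q2)$p, 1)
})

test_that("Mann-Whitney p is exact: all-greater case and random enumeration", {
  # n = 4 vs 4, every case larger -> two-sided p = 2/70
  m <- rbind(c(110, 120, 130, 140, 10, 20, 30, 40))
  q <- InsolubleQuant(m, condition = rep(c("case", "control"), each = 4),
                      pair = rep(1:4, 2), uniquePeptides = 1)
  tc <- totalInsolubleCompare(q)
  expect_equal(tc$p, 2 / 70, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    x <- sample(1000, n); y <- sample(1000, n) + 0.5  # distinct values
    m3 <- rbind(c(x, y))
    q3 <- InsolubleQuant(m3, condition = rep(c("case", "control"), each = n),
                         pair = rep(seq_len(n), 2), uniquePeptides = 1)
    tc3 <- totalInsolubleCompare(q3)
    norm <- tc3$totals$normalized
    isCase <- tc3$totals$condition == "case"
    expect_equal(tc3$p, mw_enum_p(norm[isCase], norm[!isCase]),
                 tolerance = 1e-12)
  }
})

test_that("q-value call rate under the complete null stays below nominal", {
  nSeeds <- 50
  rates <- vapply(seq_len(nSeeds), function(s) {
    sim <- simulateQuantExperiment(nProteins = 300, spikeFraction = 0,
                                   noiseSd = 0.25, seed = 1000 + s)
    d <- differentialInsolubility(sim$quant)
    mean(d$q[d$tested] < 0.01)
  }, 0)
  mcse <- sqrt(0.01 * 0.99 / (nSeeds * 300))
  expect_lte(mean(rates), 0.01 + 3 * mcse)
})
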