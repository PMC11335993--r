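toy_catalog <- function(termSets, categories = NULL) {
  n <- length(termSets)
  ard <- grepl("^ARD", names(termSets))
  if (is.null(categories))
    categories <- ifelse(ard, rep_len(CARD_CATEGORIES, n), "non_ARD")
  DiseaseBPCatalog(
    data.frame(disease_id = names(termSets), name = names(termSets),
               category = ifelse(ard, categories, "non_ARD"),
               age_related = ard, stringsAsFactors = FALSE),
    termSets)
}

test_that("BP profiles are unions over orthologues", {
  ann <- list(H1 = c("T1", "T2"), H2 = c("T2", "T3"))
  ortho <- list(w1 = c("H1", "H2"), w2 = "H9")
  expect_setequal(proteinBpProfile("w1", ann, ortho), c("T1", "T2", "T3"))
  expect_length(proteinBpProfile("w2", ann, ortho), 0)  # unannotated
  expect_length(proteinBpProfile("w9", ann, ortho), 0)  # unmapped

  set.seed(6)
  genes <- paste0("H", 1:20)
  rann <- lapply(setNames(genes, genes),
                 function(g) sample(paste0("T", 1:30), 5))
  rortho <- lapply(setNames(paste0("w", 1:10), paste0("w", 1:10)),
                   function(w) sample(genes, sample(1:3, 1)))
  for (w in names(rortho))
    expect_setequal(proteinBpProfile(w, rann, rortho),
                    unique(unlist(rann[rortho[[w]]])))  # brute-force union
})

test_that("share counts follow the at-least-one-term rule", {
  cat3 <- toy_catalog(list(ARD1 = "T1", ARD2 = "T2", ARD3 = "T9"))
  ann <- list(w1 = c("T1", "T2"), w2 = "T8")
  prof <- shareCounts(c("w1", "w2"), cat3, ann)
  expect_equal(prof["w1", "shared_diseases"], 2)
  expect_equal(prof["w2", "shared_diseases"], 0)
  expect_equal(prof["w2", "categories_hit"], 0)
  expect_equal(prof$shared_diseases, prof$shared_ard + prof$shared_nard)
})

test_that("share counts equal an exhaustive double-loop oracle", {
  set.seed(14)
  for (rep in 1:3) {
    nd <- sample(4:10, 1)
    ard <- c(TRUE, FALSE, sample(c(TRUE, FALSE), nd - 2, replace = TRUE))
    tsets <- lapply(seq_len(nd), function(i)
      sample(paste0("T", 1:25), sample(2:6, 1)))
    names(tsets) <- ifelse(ard, paste0("ARD", seq_len(nd)),
                           paste0("NARD", seq_len(nd)))
    catal <- toy_catalog(tsets)
    prots <- paste0("w", 1:40)
    ann <- lapply(setNames(prots, prots),
                  function(w) sample(paste0("T", 1:25), sample(0:8, 1)))
    prof <- shareCounts(prots, catal, ann)
    info <- diseaseInfo(catal)
    for (w in sample(prots, 10)) {
      shared <- 0; cats <- character()
      for (d in seq_len(nd)) {
        if (length(intersect(tsets[[d]], ann[[w]]))) {
          shared <- shared + 1
          if (info$age_related[d]) cats <- c(cats, info$category[d])
        }
      }
      expect_equal(prof[w, "shared_diseases"], shared)
      expect_equal(prof[w, "categories_hit"], length(unique(cats)))
    }
  }
})

test_that("profile monotonicity: more terms never decrease counts", {
  cat3 <- toy_catalog(list(ARD1 = c("T1", "T5"), ARD2 = "T2", NARD1 = "T3"))
  base <- shareCounts("w1", cat3, list(w1 = "T1"))
  more <- shareCounts("w1", cat3, list(w1 = c("T1", "T3")))
  expect_true(all(as.matrix(more) >= as.matrix(base)))
  # removing a disease never increases counts
  cat2 <- toy_catalog(list(ARD1 = c("T1", "T5"), NARD1 = "T3"))
  fewer <- shareCounts("w1", cat2, list(w1 = c("T1", "T3")))
  expect_lte(fewer["w1", "shared_diseases"], more["w1", "shared_diseases"])
})

test_that("category breadth distribution computes cumulative fractions", {
  prof <- S4Vectors::DataFrame(categories_hit = c(5, 4, 3, 0, 0))
  out <- categoryBreadthDistribution(list(toy = prof))
  expect_equal(out$fraction[out$min_categories == 0], 1)
  expect_equal(out$fraction[out$min_categories == 4], 0.4)
  allfive <- categoryBreadthDistribution(
    list(s = S4Vectors::DataFrame(categories_hit = rep(5, 3))))
  expect_equal(allfive$fraction[allfive$min_categories == 4], 1)
  zero <- categoryBreadthDistribution(
    list(s = S4Vectors::DataFrame(categories_hit = rep(0, 3))))
  expect_equal(zero$fraction[zero$min_categories == 1], 0)
})

test_that("disease-proportion enrichment normalizes by diseases tested", {
  tsets <- c(lapply(setNames(1:38, paste0("ARD", 1:38)), function(i)
    paste0("T", i)), lapply(setNames(1:12, paste0("NARD", 1:12)),
                            function(i) paste0("U", i)))
  catal <- toy_catalog(tsets)
  # 19 of 38 ARDs and 3 of 12 non-ARDs share -> 0.5 vs 0.25, ratio 2
  bp <- c(paste0("T", 1:19), paste0("U", 1:3))
  pe <- diseaseProportionEnrichment(bp, catal)
  expect_equal(pe$prop_ard, 0.5)
  expect_equal(pe$prop_nard, 0.25)
  expect_equal(pe$ratio, 2)

  all_bp <- unique(unlist(tsets))
  pa <- diseaseProportionEnrichment(all_bp, catal)
  expect_equal(c(pa$prop_ard, pa$prop_nard, pa$ratio), c(1, 1, 1))
  none <- diseaseProportionEnrichment(character(), catal)
  expect_equal(c(none$prop_ard, none$prop_nard), c(0, 0))
  expect_true(is.na(none$ratio))
})

test_that("planted sharing separates sets under the omnibus comparison", {
  planted <- sprintf("prot%04d", 1:60)
  ann <- simulateAnnotationCatalog(400, plantedSet = planted,
                                   sharingBoost = 20, seed = 12)
  ids <- sprintf("prot%04d", 1:400)
  profs <- list(
    planted = shareCounts(planted, ann$catalog, ann$annotations,
                          ann$orthology),
    background = shareCounts(setdiff(ids, planted), ann$catalog,
                             ann$annotations, ann$orthology))
  kd <- compareShareDistributions(profs)
  expect_lt(kd$p, 0.01)
  expect_gt(kd$medians["planted"], kd$medians["background"])
})

test_that("random proteome background is seed-repeatable", {
  u <- sprintf("prot%04d", 1:2000)
  r1 <- randomProteomeSet(u, n = 100, seed = 17)
  r2 <- randomProteomeSet(u, n = 100, seed = 17)
  expect_identical(members(r1), members(r2))
  expect_length(r1, 100)
})
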