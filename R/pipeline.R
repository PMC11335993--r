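#' Run the full insolubility analysis pipeline from a config
#'
#' Orchestrates every stage of the analysis from a single configuration:
#' (1) read the paired quantification matrix; (2) differential
#' insolubility calling (paired t, Storey q, filters); (3) core insoluble
#' proteome construction from the aging lists with exact overlap tests;
#' (4) gene-set over-representation of the CIP; (5) disease-sharing
#' profiles of the CIP vs the background insoluble proteome vs a seeded
#' random proteome sample; (6) biophysical score comparisons and the
#' supersaturation fold-ratio; (7) aging expression-trend classification.
#' Stages whose inputs are not configured are skipped. Every stage output
#' is written as TSV under the output directory, together with a JSON run
#' manifest (input checksums, thresholds, seed, package version, stage
#' list), so a rerun with the same config and seed reproduces the outputs.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Recognised keys: \code{quant}, \code{aging_set_1}, \code{aging_set_2},
#'   \code{gmt}, \code{orthology}, \code{disease_catalog},
#'   \code{annotations_gmt}, \code{scores}, \code{expression} (paths);
#'   \code{thresholds} (sub-keys \code{q}, \code{lfc}, \code{min_peptides},
#'   \code{fdr}, \code{p_adj}); \code{universe_size}; \code{random_n};
#'   \code{seed}; \code{out_dir}.
#' @param outDir overrides the configured output directory.
#' @return (invisibly) a list of stage results: \code{differential},
#'   \code{significant}, \code{cip} (the [buildCip()] list),
#'   \code{enrichment}, \code{share}, \code{scores}, \code{trends},
#'   \code{manifest}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  if (is.null(outDir)) outDir <- cfg$out_dir
  if (is.null(outDir)) stop("no output directory configured")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- utils::modifyList(list(q = 0.01, lfc = 0.58, min_peptides = 2,
                               fdr = 0.05, p_adj = 0.05),
                          if (is.null(cfg$thresholds)) list()
                          else cfg$thresholds)
  seed <- if (is.null(cfg$seed)) 17L else as.integer(cfg$seed)
  paths <- cfg[vapply(cfg, is.character, NA)]
  paths <- paths[vapply(paths, function(p)
    length(p) == 1 && file.exists(p) && !dir.exists(p), NA)]
  stages <- character()
  out <- list()

  die <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  if (is.null(cfg$quant)) stop("config must point at a quant matrix")
  quant <- tryCatch(readQuantMatrix(cfg$quant),
                    error = function(e) die("read_quant", e))
  stages <- c(stages, "read_quant")

  diffTab <- tryCatch(
    differentialInsolubility(quant, qMax = th$q, lfcMin = th$lfc,
                             minPeptides = th$min_peptides),
    error = function(e) die("differential", e))
  .write_tsv(cbind(protein_id = rownames(diffTab),
                   as.data.frame(diffTab)),
             file.path(outDir, "differential.tsv"))
  out$differential <- diffTab
  stages <- c(stages, "differential")

  sig <- callSignificant(diffTab, qMax = th$q, lfcMin = th$lfc,
                         minPeptides = th$min_peptides, name = "abeta_up")
  writeProteinSet(sig, file.path(outDir, "significant_up.txt"))
  out$significant <- sig
  stages <- c(stages, "call_significant")

  universe <- if (is.null(cfg$universe_size)) 19985L
              else as.integer(cfg$universe_size)
  if (!is.null(cfg$aging_set_1) && !is.null(cfg$aging_set_2)) {
    a1 <- readProteinSet(cfg$aging_set_1, "aging_1")
    a2 <- readProteinSet(cfg$aging_set_2, "aging_2")
    cip <- tryCatch(buildCip(a1, a2, sig, universe),
                    error = function(e) die("build_cip", e))
    writeProteinSet(cip$agingCore, file.path(outDir, "aging_core.txt"))
    writeProteinSet(cip$cip, file.path(outDir, "cip.txt"))
    .write_tsv(data.frame(
      comparison = c("aging1_vs_aging2", "aging_core_vs_abeta"),
      a = c(cip$testAging@a, cip$testAbeta@a),
      b = c(cip$testAging@b, cip$testAbeta@b),
      k = c(cip$testAging@k, cip$testAbeta@k),
      N = c(cip$testAging@N, cip$testAbeta@N),
      p = c(pValue(cip$testAging), pValue(cip$testAbeta)),
      fold = c(foldEnrichment(cip$testAging),
               foldEnrichment(cip$testAbeta))),
      file.path(outDir, "overlap_tests.tsv"))
    out$cip <- cip
    stages <- c(stages, "build_cip")
    querySet <- cip$cip
  } else querySet <- sig

  if (!is.null(cfg$gmt)) {
    gmt <- readGmt(cfg$gmt, namespace = "GO-BP")
    bg <- rownames(quant)
    q <- intersect(members(querySet), bg)
    enr <- tryCatch(
      hypergeomEnrich(q, gmt, bg, fdrMax = th$fdr),
      error = function(e) die("enrichment", e))
    .write_tsv(as.data.frame(enr), file.path(outDir, "enrichment.tsv"))
    out$enrichment <- enr
    stages <- c(stages, "enrichment")
  }

  if (!is.null(cfg$disease_catalog) && !is.null(cfg$annotations_gmt) &&
      !is.null(cfg$orthology)) {
    catalog <- tryCatch(readDiseaseCatalog(cfg$disease_catalog, quiet = TRUE),
                        error = function(e) die("card_share", e))
    annot <- .gmt_to_gene_annotations(readGmt(cfg$annotations_gmt))
    ortho <- readOrthology(cfg$orthology)
    bgSet <- proteinSet("background_insoluble", rownames(quant),
                        "all proteins detected in the insoluble fraction")
    rnd <- randomProteomeSet(names(ortho),
                             n = if (is.null(cfg$random_n)) 1600
                                 else cfg$random_n,
                             seed = seed)
    writeProteinSet(rnd, file.path(outDir, "random_proteome.txt"))
    profs <- list(
      cip = shareCounts(querySet, catalog, annot, ortho),
      background_insoluble = shareCounts(bgSet, catalog, annot, ortho),
      random_proteome = shareCounts(rnd, catalog, annot, ortho))
    for (nm in names(profs))
      .write_tsv(cbind(protein_id = rownames(profs[[nm]]),
                       as.data.frame(profs[[nm]])),
                 file.path(outDir, paste0("share_", nm, ".tsv")))
    kd <- compareShareDistributions(profs)
    breadth <- categoryBreadthDistribution(profs)
    .write_tsv(breadth, file.path(outDir, "category_breadth.tsv"))
    prop <- diseaseProportionEnrichment(
      setBpUnion(querySet, annot, ortho), catalog)
    out$share <- list(profiles = profs, test = kd, breadth = breadth,
                      proportion = prop)
    stages <- c(stages, "card_share")
  }

  if (!is.null(cfg$scores)) {
    scoreTab <- tryCatch(readScoreTable(cfg$scores),
                         error = function(e) die("score_compare", e))
    ssets <- list(cip = members(querySet),
                  background_insoluble = rownames(quant),
                  whole_proteome = scoreTab$protein_id)
    cmp <- tryCatch(compareScores(scoreTab, ssets, "sigma_f"),
                    error = function(e) die("score_compare", e))
    fold <- supersaturationFold(scoreTab, querySet, scoreTab$protein_id)
    out$scores <- list(comparison = cmp, supersaturationFold = fold)
    .write_tsv(cmp$pairwise, file.path(outDir, "score_pairwise.tsv"))
    stages <- c(stages, "score_compare")
  }

  if (!is.null(cfg$expression)) {
    expr <- readExpressionSeries(cfg$expression)
    tr <- tryCatch(
      agingTrend(expr, genes = members(querySet), pAdjMax = th$p_adj),
      error = function(e) die("aging_trend", e))
    .write_tsv(as.data.frame(tr$results),
               file.path(outDir, "trend_results.tsv"))
    out$trends <- tr
    stages <- c(stages, "aging_trend")
  }

  manifest <- list(
    package = "insolubilome",
    version = as.character(utils::packageVersion("insolubilome")),
    seed = seed, thresholds = th, universe_size = universe,
    stages = as.list(stages),
    inputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}

# GMT stores term -> members; the sharing analysis needs gene -> terms
.gmt_to_gene_annotations <- function(gmt) {
  sets <- geneSets(gmt)
  lapply(split(rep(names(sets), lengths(sets)),
               unlist(sets, use.names = FALSE)), unique)
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Generates a complete, internally consistent set of pipeline input files
#' (quantification matrix, aging protein lists, annotation GMT, orthology
#' map, disease catalog, score table, expression series, plus ground-truth
#' sidecars) under \code{dir}, and returns a config list that
#' [runPipeline()] accepts. The aging lists are built to contain the
#' spiked proteins plus background so that the constructed CIP recovers
#' the spiked set.
#'
#' @param dir output directory.
#' @param nProteins,nPairs,spikeFraction,spikeLog2fc,noiseSd passed to
#'   [simulateQuantExperiment()].
#' @param sharingBoost passed to [simulateAnnotationCatalog()].
#' @param sigmaFShift log10 supersaturation shift of the spiked set.
#' @param seed master seed for all generators.
#' @return named list: a ready [runPipeline()] config (with
#'   \code{$truth} holding the ground-truth objects, ignored by the
#'   pipeline).
#' @export
writeSyntheticInputs <- function(dir, nProteins = 800, nPairs = 4,
                                 spikeFraction = 0.15, spikeLog2fc = 3,
                                 noiseSd = 0.25, sharingBoost = 8,
                                 sigmaFShift = log10(94), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateQuantExperiment(nProteins = nProteins, nPairs = nPairs,
                                 spikeFraction = spikeFraction,
                                 spikeLog2fc = spikeLog2fc,
                                 noiseSd = noiseSd, seed = seed)
  writeQuantMatrix(sim$quant, file.path(dir, "quant.tsv"))
  ids <- rownames(sim$quant)
  spiked <- sim$truth$spiked
  old <- .Random.seed.exists()
  set.seed(as.integer(seed) + 1L)
  on.exit(old(), add = TRUE)
  bg <- setdiff(ids, spiked)
  aging1 <- union(spiked, sample(bg, ceiling(length(bg) * 0.3)))
  aging2 <- union(spiked, sample(bg, ceiling(length(bg) * 0.3)))
  writeLines(aging1, file.path(dir, "aging1.txt"))
  writeLines(aging2, file.path(dir, "aging2.txt"))

  ann <- simulateAnnotationCatalog(ids, plantedSet = spiked,
                                   sharingBoost = sharingBoost,
                                   seed = seed + 2L)
  writeOrthology(ann$orthology, file.path(dir, "orthology.tsv"))
  writeDiseaseCatalog(ann$catalog, file.path(dir, "diseases.tsv"))
  genes <- names(ann$annotations)
  terms <- sort(unique(unlist(ann$annotations, use.names = FALSE)))
  byTerm <- lapply(stats::setNames(terms, terms), function(tt)
    genes[vapply(ann$annotations, function(a) tt %in% a, NA)])
  writeGmt(GeneSets(byTerm, namespace = "GO-BP"),
           file.path(dir, "annotations.gmt"))

  scores <- simulateScoreTable(
    list(cip = spiked, background = bg),
    shifts = c(cip = sigmaFShift, background = 0),
    seed = seed + 3L)
  writeScoreTable(scores, file.path(dir, "scores.tsv"))

  es <- simulateExpressionSeries(nGenes = length(ids), seed = seed + 4L)
  es$expr$gene_id <- ids[match(es$expr$gene_id,
                               sprintf("gene%04d", seq_along(ids)))]
  es$truth$gene_id <- ids
  writeExpressionSeries(es$expr, file.path(dir, "expression.tsv"))
  .write_tsv(es$truth, file.path(dir, "truth_trends.tsv"))
  writeLines(spiked, file.path(dir, "truth_spiked.txt"))

  list(quant = file.path(dir, "quant.tsv"),
       aging_set_1 = file.path(dir, "aging1.txt"),
       aging_set_2 = file.path(dir, "aging2.txt"),
       orthology = file.path(dir, "orthology.tsv"),
       disease_catalog = file.path(dir, "diseases.tsv"),
       annotations_gmt = file.path(dir, "annotations.gmt"),
       scores = file.path(dir, "scores.tsv"),
       expression = file.path(dir, "expression.tsv"),
       universe_size = nProteins,
       random_n = min(400, nProteins),
       seed = seed,
       out_dir = file.path(dir, "run"),
       truth = list(spiked = spiked, trends = es$truth))
}
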