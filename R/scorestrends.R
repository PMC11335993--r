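#' Compare a biophysical score distribution across protein sets
#'
#' Tie-corrected Kruskal-Wallis omnibus with Dunn's pairwise post hoc
#' comparisons (via the shared [kruskalDunn()] core) on one score column
#' of a score table, across named protein sets (e.g. CIP, background
#' insoluble proteome, whole reference proteome, disease amyloids).
#' Missing scores are dropped per group; supersaturation (\code{sigma_f})
#' is compared on the log10 scale.
#'
#' @param table score data.frame as from [readScoreTable()] /
#'   [simulateScoreTable()].
#' @param sets named list of protein id vectors (or [ProteinSet-class]s).
#' @param score one of \code{"camsol"}, \code{"zyggregator"},
#'   \code{"catgranule"}, \code{"sigma_f"}.
#' @param pAdjustMethod passed to [kruskalDunn()].
#' @return list with \code{score}, the [kruskalDunn()] fields, and
#'   \code{directions}: per significant pair, the sign of the median
#'   difference (group1 minus group2).
#' @export
compareScores <- function(table, sets, score = c("camsol", "zyggregator",
                                                 "catgranule", "sigma_f"),
                          pAdjustMethod = "bonferroni") {
  score <- match.arg(score)
  if (!score %in% colnames(table)) stop("score column not in table: ", score)
  vals <- table[[score]]
  if (score == "sigma_f") vals <- log10(vals)
  names(vals) <- table$protein_id
  grp <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    ids <- if (is(ids, "ProteinSet")) members(ids) else unique(ids)
    v <- vals[ids[ids %in% names(vals)]]
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("group with fewer than 2 scored proteins: ", nm)
    v
  })
  kd <- kruskalDunn(unlist(grp, use.names = FALSE),
                    rep(names(sets), lengths(grp)), pAdjustMethod)
  kd$pairwise$direction <- sign(kd$medians[kd$pairwise$group1] -
                                kd$medians[kd$pairwise$group2])
  c(list(score = score), kd)
}

#' Supersaturation fold-ratio between two protein sets
#'
#' Ratio of the average supersaturation score (sigma_f) of one set over a
#' reference set. The primary value is the ratio of arithmetic means on
#' the linear sigma_f scale; a geometric-mean variant (ratio of
#' 10^mean(log10 sigma_f)) is reported alongside.
#'
#' @param table score data.frame with \code{protein_id} and
#'   \code{sigma_f}.
#' @param set,reference protein id vectors or [ProteinSet-class]s.
#' @return list with \code{fold} (linear-scale mean ratio),
#'   \code{foldGeometric}, \code{meanSet}, \code{meanReference} and the
#'   per-set sizes used.
#' @export
supersaturationFold <- function(table, set, reference) {
  if (!"sigma_f" %in% colnames(table)) stop("table lacks sigma_f")
  sf <- stats::setNames(table$sigma_f, table$protein_id)
  pick <- function(s) {
    ids <- if (is(s, "ProteinSet")) members(s) else unique(s)
    v <- sf[ids[ids %in% names(sf)]]
    v[!is.na(v)]
  }
  a <- pick(set); b <- pick(reference)
  if (!length(a) || !length(b))
    stop("sigma_f present for no protein in one of the sets")
  if (mean(b) == 0) stop("reference mean sigma_f is zero")
  list(fold = mean(a) / mean(b),
       foldGeometric = 10^(mean(log10(a)) - mean(log10(b))),
       meanSet = mean(a), meanReference = mean(b),
       nSet = length(a), nReference = length(b))
}

#' Aging expression-trend classification
#'
#' For each gene, Spearman-correlates expression with adult age over a day
#' window (default days 2 to 10), pooling datasets, and classifies the
#' gene as increasing, decreasing or unchanged with age at an adjusted
#' significance threshold (BH across all tested genes, p.adj < 0.05 by
#' default). Genes with fewer than 3 (age, value) points after windowing
#' are reported untested.
#'
#' @param expr long-format expression data.frame (\code{gene_id},
#'   \code{age_day}, \code{value}, \code{dataset_id}).
#' @param genes optional id vector restricting the analysis (e.g. CIP
#'   genes).
#' @param dayWindow numeric length-2, inclusive age window (default
#'   \code{c(2, 10)}).
#' @param pAdjMax adjusted-p threshold for the up/down call.
#' @return list with \code{results} (DataFrame: \code{gene_id}, \code{n},
#'   \code{rho}, \code{p}, \code{p_adj}, \code{class} in
#'   up/down/unchanged/untested) and \code{summary} (fractions of tested
#'   genes up, down, unchanged, plus the up:down ratio).
#' @export
agingTrend <- function(expr, genes = NULL, dayWindow = c(2, 10),
                       pAdjMax = 0.05) {
  need <- c("gene_id", "age_day", "value")
  stopifnot(all(need %in% colnames(expr)))
  e <- expr[expr$age_day >= dayWindow[1] & expr$age_day <= dayWindow[2], ]
  if (!is.null(genes)) {
    ids <- if (is(genes, "ProteinSet")) members(genes) else unique(genes)
    e <- e[e$gene_id %in% ids, ]
  }
  byGene <- split(e[, c("age_day", "value")], e$gene_id)
  fit <- lapply(byGene, function(d) spearmanRho(d$age_day, d$value))
  res <- DataFrame(gene_id = names(byGene),
                   n = unname(vapply(fit, `[[`, 0, "n")),
                   rho = unname(vapply(fit, `[[`, 0, "rho")),
                   p = unname(vapply(fit, `[[`, 0, "p")))
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  if (any(tested)) res$p_adj[tested] <- bhAdjust(res$p[tested])
  res$class <- ifelse(!tested, "untested",
                 ifelse(res$p_adj < pAdjMax & res$rho > 0, "up",
                   ifelse(res$p_adj < pAdjMax & res$rho < 0, "down",
                          "unchanged")))
  nT <- sum(tested)
  nUp <- sum(res$class == "up"); nDown <- sum(res$class == "down")
  list(results = res,
       summary = list(
         n_tested = nT,
         frac_up = if (nT) nUp / nT else NA_real_,
         frac_down = if (nT) nDown / nT else NA_real_,
         frac_unchanged = if (nT) sum(res$class == "unchanged") / nT
                          else NA_real_,
         up_down_ratio = if (nDown > 0) nUp / nDown else NA_real_))
}
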