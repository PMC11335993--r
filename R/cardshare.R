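#' GO-BP profile of a protein via orthologue expansion
#'
#' The biological-process annotation profile of a (worm) protein is the
#' union of the GO-BP term sets of all of its human orthologues
#' (expand-all policy). Annotations keyed directly by the protein id are
#' used when no orthology map is supplied. Unannotated proteins get an
#' empty profile.
#'
#' @param protein single protein identifier.
#' @param annotations named list, (human) gene id -> GO-BP term ids.
#' @param orthology optional named list, worm id -> human ids.
#' @return character vector of GO-BP term ids (possibly empty).
#' @export
proteinBpProfile <- function(protein, annotations, orthology = NULL) {
  keys <- if (is.null(orthology)) protein
          else orthology[[protein]]
  if (is.null(keys)) return(character())
  unique(unlist(annotations[keys[keys %in% names(annotations)]],
                use.names = FALSE))
}

#' Per-protein disease-sharing counts
#'
#' For every protein in a set, counts the diseases of the catalog whose
#' GO-BP term set shares at least one term with the protein's BP profile
#' (term-id equality after orthologue expansion; no ontology-graph
#' closure). Reports, per protein, the total number of sharing diseases,
#' the age-related (ARD) and non-age-related (non-ARD) sub-counts, and the
#' number of the five broad CARD categories containing at least one
#' sharing ARD.
#'
#' @param s a [ProteinSet-class] or character vector of protein ids.
#' @param catalog a [DiseaseBPCatalog-class].
#' @param annotations named list, gene id -> GO-BP term ids.
#' @param orthology optional named list, worm id -> human ids.
#' @return A [S4Vectors::DataFrame], one row per protein:
#'   \code{shared_diseases}, \code{shared_ard}, \code{shared_nard},
#'   \code{categories_hit}.
#' @export
shareCounts <- function(s, catalog, annotations, orthology = NULL) {
  stopifnot(is(catalog, "DiseaseBPCatalog"))
  if (length(catalog) == 0) stop("empty disease catalog")
  ids <- if (is(s, "ProteinSet")) members(s) else unique(as.character(s))
  info <- diseaseInfo(catalog)
  tsets <- diseaseTerms(catalog)
  res <- lapply(ids, function(pid) {
    prof <- proteinBpProfile(pid, annotations, orthology)
    hit <- vapply(tsets, function(ts) any(ts %in% prof), NA)
    ard <- hit & info$age_related
    c(shared_diseases = sum(hit),
      shared_ard = sum(ard),
      shared_nard = sum(hit & !info$age_related),
      categories_hit = length(unique(info$category[ard])))
  })
  m <- do.call(rbind, res)
  DataFrame(m, row.names = ids)
}

#' Distribution of CARD category breadth across a protein set
#'
#' Summarises, per protein set, how broadly its proteins' shared diseases
#' span the five broad CARD categories: the fraction of proteins whose
#' sharing ARDs cover at least c categories, for c = 0..5.
#'
#' @param profiles named list of [shareCounts()] outputs, one per protein
#'   set.
#' @return data.frame with columns \code{set}, \code{min_categories} (c),
#'   \code{fraction} (fraction of proteins with \code{categories_hit >=
#'   c}). The c = 4 row is the headline "four or more of five" summary.
#' @export
categoryBreadthDistribution <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  out <- lapply(names(profiles), function(nm) {
    ch <- profiles[[nm]]$categories_hit
    data.frame(set = nm, min_categories = 0:5,
               fraction = vapply(0:5, function(c) mean(ch >= c), 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Set-level GO-BP union of a protein set
#'
#' @inheritParams shareCounts
#' @return character vector: union of the BP profiles of all proteins.
#' @export
setBpUnion <- function(s, annotations, orthology = NULL) {
  ids <- if (is(s, "ProteinSet")) members(s) else unique(as.character(s))
  unique(unlist(lapply(ids, proteinBpProfile, annotations = annotations,
                       orthology = orthology), use.names = FALSE))
}

#' Disease-proportion enrichment, normalized by diseases tested
#'
#' Given the set-level union of BP terms of a protein set, computes for the
#' age-related and the non-age-related disease classes the proportion of
#' diseases sharing at least one BP term with the set, normalized to the
#' number of diseases tested in that class, and their ratio.
#'
#' @param bpUnion character vector of GO-BP term ids (from
#'   [setBpUnion()]).
#' @param catalog a [DiseaseBPCatalog-class].
#' @return list with \code{n_ard}, \code{n_nard} (sharing disease counts),
#'   \code{prop_ard}, \code{prop_nard} (normalized proportions) and
#'   \code{ratio} (ARD over non-ARD; \code{NA} when undefined).
#' @export
diseaseProportionEnrichment <- function(bpUnion, catalog) {
  stopifnot(is(catalog, "DiseaseBPCatalog"))
  info <- diseaseInfo(catalog)
  if (!any(info$age_related) || all(info$age_related))
    stop("catalog must contain both ARD and non-ARD diseases")
  tsets <- diseaseTerms(catalog)
  hit <- vapply(tsets, function(ts) any(ts %in% bpUnion), NA)
  nArd <- sum(hit & info$age_related)
  nNard <- sum(hit & !info$age_related)
  pArd <- nArd / sum(info$age_related)
  pNard <- nNard / sum(!info$age_related)
  list(n_ard = nArd, n_nard = nNard, prop_ard = pArd, prop_nard = pNard,
       ratio = if (pNard > 0) pArd / pNard else NA_real_)
}

#' Compare disease-sharing distributions across protein sets
#'
#' Kruskal-Wallis omnibus plus Dunn's pairwise comparisons (shared core
#' [kruskalDunn()]) on a per-protein sharing count across sets, typically
#' the CIP vs the background insoluble proteome vs a random reference
#' proteome sample.
#'
#' @param profiles named list of [shareCounts()] outputs.
#' @param value which count to compare: \code{"shared_ard"} (default),
#'   \code{"shared_diseases"}, \code{"shared_nard"} or
#'   \code{"categories_hit"}.
#' @param pAdjustMethod passed to [kruskalDunn()].
#' @return the [kruskalDunn()] result list.
#' @export
compareShareDistributions <- function(profiles, value = "shared_ard",
                                      pAdjustMethod = "bonferroni") {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  vals <- unlist(lapply(profiles, function(p) p[[value]]), use.names = FALSE)
  grp <- rep(names(profiles), vapply(profiles, nrow, 0L))
  kruskalDunn(vals, grp, pAdjustMethod)
}

#' Draw a random reference-proteome protein set
#'
#' Samples n proteins uniformly without replacement from the reference
#' proteome, with an explicit seed so the background is exactly
#' repeatable.
#'
#' @param proteome character vector of reference proteome ids.
#' @param n sample size (default 1600).
#' @param seed integer seed.
#' @return A [ProteinSet-class] named \code{"random_proteome"}.
#' @export
randomProteomeSet <- function(proteome, n = 1600, seed = 17) {
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  on.exit(old(), add = TRUE)
  proteinSet("random_proteome",
             sample(unique(proteome), min(n, length(unique(proteome)))),
             sprintf("uniform sample of %d proteome ids, seed %d", n, seed))
}
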