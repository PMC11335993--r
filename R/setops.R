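#' Exact overlap (Fisher) test between two protein sets
#'
#' Tests whether two identifier sets overlap more than expected by chance
#' within a stated universe, using the exact hypergeometric tail
#' \eqn{P(X \ge k)} (one-sided enrichment, the default) computed in
#' log-gamma arithmetic via [stats::phyper()]. The fold enrichment is
#' \eqn{k N / (a b)}.
#'
#' The universe must be stated explicitly: either the full identifier
#' vector (membership of A and B is then checked) or its size. Every
#' returned [OverlapTest-class] records the N used.
#'
#' @param setA,setB [ProteinSet-class] objects or character vectors.
#' @param universe character vector of universe identifiers, or a single
#'   number giving the universe size.
#' @param alternative \code{"greater"} (enrichment, default),
#'   \code{"less"} or \code{"two.sided"} (via [stats::fisher.test()]).
#' @return An [OverlapTest-class].
#' @examples
#' fisherOverlap(letters[1:5], letters[3:10], universe = letters)
#' @export
fisherOverlap <- function(setA, setB, universe,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  nameA <- if (is(setA, "ProteinSet")) setA@name else "A"
  nameB <- if (is(setB, "ProteinSet")) setB@name else "B"
  A <- unique(if (is(setA, "ProteinSet")) members(setA) else setA)
  B <- unique(if (is(setB, "ProteinSet")) members(setB) else setB)
  if (is.character(universe)) {
    universe <- unique(universe)
    N <- length(universe)
    offA <- setdiff(A, universe)
    offB <- setdiff(B, universe)
    if (length(offA) || length(offB))
      stop("sets not contained in universe: ",
           paste(head(c(offA, offB), 10), collapse = ", "))
  } else {
    N <- as.integer(universe)
    if (length(A) > N || length(B) > N)
      stop("set larger than the stated universe size")
  }
  a <- length(A); b <- length(B); k <- length(intersect(A, B))
  p <- switch(alternative,
    greater = stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE),
    less = stats::phyper(k, a, N - a, b, lower.tail = TRUE),
    two.sided = stats::fisher.test(
      matrix(c(k, a - k, b - k, N - a - b + k), 2))$p.value)
  fold <- if (a > 0 && b > 0) k * N / (a * b) else NA_real_
  new("OverlapTest", nameA = nameA, nameB = nameB,
      a = as.integer(a), b = as.integer(b), k = as.integer(k),
      N = as.integer(N), pValue = p, foldEnrichment = fold,
      alternative = alternative)
}

#' Build the core insoluble proteome (CIP)
#'
#' Intersects two independently published aging insoluble proteomes to get
#' the proteins that robustly insolubilise during normal aging (the "aging
#' core"), then intersects that core with the amyloid-driven insoluble set
#' to get the core insoluble proteome: proteins that become insoluble both
#' during normal aging and upon amyloid expression. Both overlaps are
#' tested with [fisherOverlap()] against the stated universe.
#'
#' @param agingSet1,agingSet2 [ProteinSet-class]s (or character vectors) of
#'   aging insoluble proteins from two independent datasets.
#' @param abetaSet amyloid-driven insoluble [ProteinSet-class] (or
#'   character vector).
#' @param universe universe identifiers or size (see [fisherOverlap()]).
#' @return list with \code{agingCore} and \code{cip}
#'   ([ProteinSet-class]s), \code{cipFraction} = |cip| / |aging core|,
#'   \code{testAging} (overlap test of the two aging sets) and
#'   \code{testAbeta} (aging core vs amyloid set).
#' @export
buildCip <- function(agingSet1, agingSet2, abetaSet, universe) {
  m1 <- if (is(agingSet1, "ProteinSet")) members(agingSet1) else unique(agingSet1)
  m2 <- if (is(agingSet2, "ProteinSet")) members(agingSet2) else unique(agingSet2)
  mA <- if (is(abetaSet, "ProteinSet")) members(abetaSet) else unique(abetaSet)
  core <- intersect(m1, m2)
  cip <- intersect(core, mA)
  if (length(core) == 0 || length(cip) == 0)
    warning("empty intersection while building the CIP")
  list(
    agingCore = proteinSet("aging_core", core,
                           "intersection of the two aging insoluble sets"),
    cip = proteinSet("cip", cip,
                     "aging core intersected with amyloid-driven set"),
    cipFraction = if (length(core)) length(cip) / length(core) else NA_real_,
    testAging = fisherOverlap(agingSet1, agingSet2, universe),
    testAbeta = fisherOverlap(proteinSet("aging_core", core), abetaSet,
                              universe))
}

#' Project a protein set through an orthology map
#'
#' Maps worm identifiers to human orthologues. The default policy
#' \code{"expand_all"} maps each source id to all of its targets and
#' de-duplicates; \code{"first_only"} keeps one target per source.
#' Unmapped ids are not an error; they are recorded in the
#' \code{"unmapped"} attribute of the result.
#'
#' @param s a [ProteinSet-class] or character vector of source ids.
#' @param map named list, source id -> character vector of target ids
#'   (as from [readOrthology()]).
#' @param policy \code{"expand_all"} (default) or \code{"first_only"}.
#' @return A [ProteinSet-class] of target identifiers with attribute
#'   \code{"unmapped"}.
#' @export
mapOrthologs <- function(s, map, policy = c("expand_all", "first_only")) {
  policy <- match.arg(policy)
  ids <- if (is(s, "ProteinSet")) members(s) else unique(as.character(s))
  nm <- if (is(s, "ProteinSet")) s@name else "set"
  hit <- ids[ids %in% names(map)]
  unmapped <- setdiff(ids, hit)
  targets <- map[hit]
  if (policy == "first_only") targets <- lapply(targets, `[`, 1)
  out <- proteinSet(paste0(nm, "_human"),
                    unlist(targets, use.names = FALSE),
                    sprintf("orthology projection (%s) of '%s'", policy, nm))
  attr(out, "unmapped") <- unmapped
  out
}
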