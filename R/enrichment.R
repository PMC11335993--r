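#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values, monotone and capped at 1
#' (a thin wrapper over [stats::p.adjust()] that rejects empty input, for
#' symmetry with [storeyQValues()]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment score: gene count times FDR
#'
#' The reporting score for over-representation results: the product of the
#' overlap gene count and the FDR-corrected p-value. A display variant
#' multiplies the count by \eqn{-\log_{10}} FDR instead, which ranks
#' stronger terms higher (useful for barplots).
#'
#' @param k overlap gene count.
#' @param fdr FDR-corrected p-value in [0, 1].
#' @param display \code{"product"} (default, k * fdr) or \code{"neglog"}
#'   (k * -log10(fdr)).
#' @return numeric score vector.
#' @examples
#' enrichmentScore(10, 0.001)   # 0.01
#' @export
enrichmentScore <- function(k, fdr, display = c("product", "neglog")) {
  display <- match.arg(display)
  stopifnot(all(k >= 0), all(fdr >= 0 & fdr <= 1))
  if (display == "product") k * fdr else k * -log10(fdr)
}

#' Hypergeometric gene-set over-representation analysis
#'
#' Tests each term of a collection for over-representation in a query set
#' relative to a background universe. Term member sets are intersected with
#' the background before testing; terms whose intersected size falls
#' outside \code{[minTermSize, maxTermSize]} are skipped. The one-sided
#' hypergeometric p is identical to [fisherOverlap()] on the corresponding
#' 2x2; BH adjustment is applied across all tested terms of the collection
#' (one namespace = one adjustment family).
#'
#' @param query a [ProteinSet-class] or character vector; must be contained
#'   in the background.
#' @param collection a [GeneSets-class].
#' @param background character vector or [ProteinSet-class]: the universe.
#' @param minTermSize,maxTermSize term-size bounds after background
#'   intersection (defaults 3 and 2000).
#' @param fdrMax optional FDR cut applied to the returned table (default
#'   NULL: return all tested terms).
#' @return A [S4Vectors::DataFrame] sorted by \code{fdr} then \code{score}:
#'   \code{term_id}, \code{term_name}, \code{k} (overlap), \code{K} (term
#'   size in background), \code{n} (query size), \code{N} (background
#'   size), \code{p}, \code{fdr}, \code{score} (k * fdr) and
#'   \code{score_neglog} (k * -log10 fdr).
#' @export
hypergeomEnrich <- function(query, collection, background,
                            minTermSize = 3, maxTermSize = 2000,
                            fdrMax = NULL) {
  stopifnot(is(collection, "GeneSets"))
  q <- unique(if (is(query, "ProteinSet")) members(query) else query)
  bg <- unique(if (is(background, "ProteinSet")) members(background)
               else background)
  off <- setdiff(q, bg)
  if (length(off))
    stop("query not contained in background: ",
         paste(head(off, 10), collapse = ", "))
  N <- length(bg); n <- length(q)
  sets <- lapply(geneSets(collection), intersect, bg)
  K <- lengths(sets)
  keep <- K >= minTermSize & K <= maxTermSize
  sets <- sets[keep]; K <- K[keep]
  if (!length(sets)) {
    return(DataFrame(term_id = character(), term_name = character(),
                     k = integer(), K = integer(), n = integer(),
                     N = integer(), p = numeric(), fdr = numeric(),
                     score = numeric(), score_neglog = numeric()))
  }
  k <- unname(vapply(sets, function(s) length(intersect(s, q)), 0L))
  K <- unname(K)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- bhAdjust(p)
  res <- DataFrame(term_id = names(sets),
                   term_name = unname(collection@descriptions[names(sets)]),
                   k = k, K = as.integer(K), n = n, N = N,
                   p = p, fdr = fdr,
                   score = enrichmentScore(k, fdr),
                   score_neglog = enrichmentScore(k, fdr, "neglog"))
  res <- res[order(res$fdr, -res$score_neglog), ]
  if (!is.null(fdrMax)) res <- res[res$fdr < fdrMax, ]
  res
}
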