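#' Paired differential insolubility analysis
#'
#' For every protein group, computes the case/control log2 fold-change and a
#' two-sided paired t-test over the complete replicate pairs. Intensities
#' are analysed on the log2 scale; zeros are treated as missing (log
#' undefined). A pair is complete for a protein when both its case and
#' control measurements are present. Proteins with fewer than
#' \code{minPairs} complete pairs are reported but flagged untested.
#'
#' The per-pair difference is \eqn{d_i = \log_2(\mathrm{case}_i) -
#' \log_2(\mathrm{control}_i)}; the fold-change is \eqn{\bar d} and the
#' statistic \eqn{t = \bar d / (s_d/\sqrt{n})} on \eqn{n - 1} degrees of
#' freedom. Degenerate cases: identical nonzero differences across pairs
#' (zero variance) get a floored p of \code{1e-15}; identically-zero
#' differences get p = 1.
#'
#' @param x an [InsolubleQuant-class].
#' @param minPairs minimum complete pairs for a protein to be tested
#'   (default 2).
#'
#' @return A [S4Vectors::DataFrame] with one row per protein: \code{log2fc},
#'   \code{t_stat}, \code{p}, \code{n_pairs_used}, \code{unique_peptides},
#'   \code{tested}. Untested proteins carry \code{NA} statistics.
#' @seealso [storeyQValues()], [callSignificant()]
#' @export
pairedLogFoldChange <- function(x, minPairs = 2) {
  stopifnot(is(x, "InsolubleQuant"))
  m <- assay(x, "intensity")
  m[m == 0] <- NA_real_
  cd <- colData(x)
  pairs <- sort(unique(cd$pair))
  caseIdx <- vapply(pairs, function(p)
    which(cd$condition == "case" & cd$pair == p), 1L)
  ctrlIdx <- vapply(pairs, function(p)
    which(cd$condition == "control" & cd$pair == p), 1L)
  d <- log2(m[, caseIdx, drop = FALSE]) - log2(m[, ctrlIdx, drop = FALSE])
  n <- rowSums(!is.na(d))
  dbar <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
  tested <- n >= max(2, minPairs)
  tstat <- dbar / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zeroVar <- tested & !is.na(sd_d) & sd_d == 0
  p[zeroVar & dbar != 0] <- 1e-15
  tstat[zeroVar & dbar != 0] <- sign(dbar[zeroVar & dbar != 0]) * Inf
  p[zeroVar & dbar == 0] <- 1
  tstat[zeroVar & dbar == 0] <- 0
  res <- DataFrame(log2fc = unname(ifelse(n >= 1, dbar, NA_real_)),
                   t_stat = unname(tstat), p = unname(p),
                   n_pairs_used = unname(n),
                   unique_peptides = unname(uniquePeptides(x)),
                   tested = unname(tested),
                   row.names = rownames(x))
  res$log2fc[!tested & n == 0] <- NA_real_
  res$t_stat[!tested] <- NA_real_
  res$p[!tested] <- NA_real_
  res
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Converts p-values to q-values using Storey's estimate of the null
#' proportion \eqn{\pi_0}. For each \eqn{\lambda} on the grid,
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))}; the
#' estimates are smoothed with a cubic smoothing spline (3 df) and the
#' smoother is evaluated at the largest \eqn{\lambda}, then clipped to
#' (0, 1]. q-values are the step-up quantity \eqn{\hat\pi_0 \min_{k \ge i}
#' (m\, p_{(k)} / k)}, monotone non-decreasing in p-rank. With
#' \code{pi0 = 1} the result is exactly the Benjamini-Hochberg adjustment.
#'
#' A bootstrap alternative picks the \eqn{\lambda} minimising the estimated
#' MSE of \eqn{\hat\pi_0(\lambda)} over bootstrap resamples.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid of lambda values in [0, 1) (default
#'   \code{seq(0, 0.90, 0.05)}).
#' @param method \code{"smoother"} (default) or \code{"bootstrap"}.
#' @param pi0 optionally force the null-proportion estimate (e.g. 1 for
#'   plain BH).
#' @param nBoot bootstrap resamples for \code{method = "bootstrap"}.
#'
#' @return list with \code{q} (q-values, same order as \code{p}),
#'   \code{pi0}, \code{lambda}, \code{pi0Lambda} (the raw
#'   \eqn{\hat\pi_0(\lambda)} curve) and \code{method}.
#' @references Storey & Tibshirani (2003) PNAS 100:9440-9445.
#' @export
storeyQValues <- function(p, lambda = seq(0, 0.90, by = 0.05),
                          method = c("smoother", "bootstrap"),
                          pi0 = NULL, nBoot = 100) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  method <- match.arg(method)
  m <- length(p)
  lambda <- sort(unique(lambda))
  pi0Lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  if (is.null(pi0)) {
    if (m < 2 || length(lambda) < 4) {
      pi0 <- min(1, max(pi0Lambda[length(pi0Lambda)], .Machine$double.eps))
    } else if (method == "smoother") {
      fit <- stats::smooth.spline(lambda, pi0Lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    } else {
      minPi0 <- min(pi0Lambda)
      mse <- vapply(seq_along(lambda), function(i) {
        pb <- vapply(seq_len(nBoot), function(b) {
          pp <- sample(p, m, replace = TRUE)
          mean(pp > lambda[i]) / (1 - lambda[i])
        }, 0)
        mean((pb - minPi0)^2)
      }, 0)
      pi0 <- pi0Lambda[which.min(mse)]
    }
    pi0 <- min(1, max(pi0, .Machine$double.eps))
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p)
  ro <- order(o)
  qSorted <- pi0 * m * p[o] / seq_len(m)
  qSorted <- rev(cummin(rev(qSorted)))
  qSorted <- pmin(qSorted, 1)
  list(q = qSorted[ro], pi0 = pi0, lambda = lambda,
       pi0Lambda = pi0Lambda, method = method)
}

#' Run the full differential pipeline on a quantification matrix
#'
#' Convenience wrapper: [pairedLogFoldChange()] then [storeyQValues()] on
#' the tested proteins, returning the combined table with a \code{q} column
#' and \code{significant_up} flag at the default thresholds.
#'
#' @inheritParams pairedLogFoldChange
#' @inheritParams callSignificant
#' @param ... passed to [storeyQValues()].
#' @return DataFrame as [pairedLogFoldChange()] plus \code{q} and
#'   \code{significant_up}; the [storeyQValues()] model is attached as
#'   \code{metadata(x)$qvalueModel}.
#' @export
differentialInsolubility <- function(x, qMax = 0.01, lfcMin = 0.58,
                                     minPeptides = 2, ...) {
  res <- pairedLogFoldChange(x)
  res$q <- NA_real_
  if (any(res$tested)) {
    qm <- storeyQValues(res$p[res$tested], ...)
    res$q[res$tested] <- qm$q
    metadata(res)$qvalueModel <- qm[c("pi0", "lambda", "pi0Lambda", "method")]
  }
  res$significant_up <- res$tested & !is.na(res$q) &
    res$unique_peptides >= minPeptides & res$q < qMax & res$log2fc > lfcMin
  res
}

#' Call significantly insolubilised proteins
#'
#' Applies the significance filters to a differential table: at least
#' \code{minPeptides} unique peptides, q-value below \code{qMax} and log2
#' fold-change beyond \code{lfcMin} (defaults 2, 0.01 and 0.58). The
#' default direction \code{"up"} returns proteins increased in the
#' insoluble fraction; \code{"both"} applies the filter to
#' \code{|log2fc|}.
#'
#' @param d DataFrame from [differentialInsolubility()] (or
#'   [pairedLogFoldChange()] plus a \code{q} column).
#' @param qMax q-value threshold.
#' @param lfcMin log2 fold-change threshold (exclusive).
#' @param minPeptides minimum unique peptides (inclusive).
#' @param direction \code{"up"}, \code{"down"} or \code{"both"}.
#' @param name name for the returned set.
#' @return A [ProteinSet-class] of the significant proteins.
#' @export
callSignificant <- function(d, qMax = 0.01, lfcMin = 0.58, minPeptides = 2,
                            direction = c("up", "down", "both"),
                            name = NULL) {
  direction <- match.arg(direction)
  stopifnot(!is.null(d$q))
  lfc <- switch(direction, up = d$log2fc, down = -d$log2fc,
                both = abs(d$log2fc))
  keep <- !is.na(d$q) & d$tested & d$unique_peptides >= minPeptides &
    d$q < qMax & lfc > lfcMin
  if (is.null(name)) name <- paste0("significant_", direction)
  proteinSet(name, rownames(d)[keep],
             sprintf("q<%g, log2fc>%g (%s), peptides>=%d",
                     qMax, lfcMin, direction, minPeptides))
}

#' Compare total insoluble protein between arms
#'
#' Sums the present intensities per sample, normalizes every total to the
#' mean of the control totals within its experiment, and compares the
#' normalized case and control values with an exact two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. With full ties the normal approximation with
#' midranks is used instead of the exact distribution.
#'
#' @param x an [InsolubleQuant-class].
#' @param experiment optional factor over samples grouping them into
#'   experiments; default: all samples belong to one experiment.
#' @return list with \code{totals} (data.frame: sample, condition, pair,
#'   total, normalized), \code{p} (Mann-Whitney p) and \code{statistic}.
#' @export
totalInsolubleCompare <- function(x, experiment = NULL) {
  m <- assay(x, "intensity")
  cd <- colData(x)
  if (is.null(experiment)) experiment <- rep(1L, ncol(m))
  total <- colSums(m, na.rm = TRUE)
  norm <- total
  for (e in unique(experiment)) {
    i <- experiment == e
    ctrl <- i & cd$condition == "control"
    if (!any(ctrl)) stop("experiment without control samples")
    norm[i] <- total[i] / mean(total[ctrl])
  }
  isCase <- cd$condition == "case"
  if (!any(isCase) || all(isCase)) stop("empty arm")
  if (length(unique(norm)) == 1) {
    # complete ties carry no rank information
    wt <- list(p.value = 1,
               statistic = sum(isCase) * sum(!isCase) / 2)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(norm[isCase], norm[!isCase], exact = TRUE,
                         correct = FALSE))
  }
  list(totals = data.frame(sample = colnames(m),
                           condition = cd$condition, pair = cd$pair,
                           total = total, normalized = norm,
                           stringsAsFactors = FALSE, row.names = NULL),
       p = wt$p.value, statistic = unname(wt$statistic))
}
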