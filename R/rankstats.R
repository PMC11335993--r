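#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' The shared rank-statistics core used by both the disease-sharing and
#' biophysical-score comparisons. The omnibus H (tie-corrected) and its
#' chi-squared p come from [stats::kruskal.test()]. Dunn's pairwise z
#' statistics are computed on the pooled midranks:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values adjusted over all unordered pairs
#' (Bonferroni by default, Holm available).
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group labels, same length.
#' @param pAdjustMethod \code{"bonferroni"} (default) or \code{"holm"}.
#' @return list with \code{H}, \code{df}, \code{p} (omnibus),
#'   \code{pairwise} (data.frame: group1, group2, z, p, p_adj),
#'   \code{medians} and \code{n} (named per group). Degenerate input (all
#'   values identical) returns H = 0, p = 1.
#' @export
kruskalDunn <- function(values, groups,
                        pAdjustMethod = c("bonferroni", "holm")) {
  pAdjustMethod <- match.arg(pAdjustMethod)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  glev <- unique(groups)
  if (length(glev) < 2) stop("need at least 2 groups")
  nPer <- table(groups)[glev]
  if (any(nPer < 2)) stop("each group needs at least 2 observations")
  medians <- vapply(glev, function(g) stats::median(values[groups == g]), 0)
  if (length(unique(values)) == 1) {
    pw <- .dunn_pairs(glev)
    pw$z <- 0; pw$p <- 1; pw$p_adj <- 1
    return(list(H = 0, df = length(glev) - 1, p = 1, pairwise = pw,
                medians = medians, n = as.vector(nPer)))
  }
  kt <- stats::kruskal.test(values, factor(groups, levels = glev))
  N <- length(values)
  r <- rank(values)
  rbar <- vapply(glev, function(g) mean(r[groups == g]), 0)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tieTerm
  pw <- .dunn_pairs(glev)
  pw$z <- mapply(function(g1, g2) {
    (rbar[g1] - rbar[g2]) /
      sqrt(sigma2 * (1 / nPer[[g1]] + 1 / nPer[[g2]]))
  }, pw$group1, pw$group2)
  pw$p <- 2 * stats::pnorm(-abs(pw$z))
  pw$p_adj <- stats::p.adjust(pw$p, method = pAdjustMethod)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, pairwise = pw, medians = medians,
       n = as.vector(nPer))
}

.dunn_pairs <- function(glev) {
  cmb <- utils::combn(glev, 2)
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with small-sample exact p
#'
#' Computes Spearman's rho on midranks with a two-sided p-value: the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} for \eqn{n \ge
#' 10}, and an exact permutation p (enumeration of all \eqn{n!} orderings)
#' for \eqn{n < 10}, which remains valid under ties.
#'
#' @param x,y numeric vectors (pairs with missing values dropped).
#' @return list with \code{rho}, \code{p}, \code{n}. Fewer than 3 complete
#'   pairs (or constant \code{x}) gives \code{rho = NA}, \code{p = NA};
#'   constant \code{y} gives \code{rho = 0}, \code{p = 1} (all ranks tied:
#'   no trend).
#' @export
spearmanRho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  # constant response: no trend by definition (all-tied ranks)
  if (length(unique(y)) < 2)
    return(list(rho = 0, p = 1, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    # vectorised Pearson-on-ranks over all n! permutations:
    # rho_perm is affine in sum(rx[perm] * ry)
    perms <- .permutations(n)
    cross <- matrix(rx[perms], nrow(perms)) %*% ry
    mx <- mean(rx); my <- mean(ry)
    sx <- sqrt(sum((rx - mx)^2)); sy <- sqrt(sum((ry - my)^2))
    rhoPerm <- (cross - n * mx * my) / (sx * sy)
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 2e-16
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = min(p, 1), n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
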