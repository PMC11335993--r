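# Independent brute-force oracles used across the suite.

# hypergeometric upper tail P(X >= k) by direct combinatorial enumeration
hyper_enum_p <- function(k, a, b, N) {
  i <- k:min(a, b)
  sum(choose(a, i) * choose(N - a, b - i)) / choose(N, b)
}

# Benjamini-Hochberg by the direct step-up formula min_{j >= i} m p_(j) / j
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(m * ps[i:m] / (i:m), 1), 0)
  adj[order(o)]
}

# tie-corrected Kruskal-Wallis H by the direct rank formula
kw_H_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact two-sided Mann-Whitney p for distinct values by full enumeration
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Uall <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  if (Uobs >= mu) p <- 2 * mean(Uall >= Uobs) else p <- 2 * mean(Uall <= Uobs)
  min(p, 1)
}

# tiny paired quant matrix from a per-pair case/control ratio matrix
quant_from_ratios <- function(ratios, control = 100, peptides = 3) {
  nPairs <- ncol(ratios)
  ctrl <- matrix(control, nrow(ratios), nPairs)
  m <- cbind(ctrl * ratios, ctrl)
  rn <- rownames(ratios)
  if (is.null(rn)) rn <- paste0("P", seq_len(nrow(ratios)))
  rownames(m) <- rn
  InsolubleQuant(m,
                 condition = rep(c("case", "control"), each = nPairs),
                 pair = rep(seq_len(nPairs), 2),
                 uniquePeptides = peptides)
}
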