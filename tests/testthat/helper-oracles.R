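# Independent brute-force oracles. Each recomputes a quantity from its
# definition by a different route than the package implementation.

# Conditional NB exact test by direct enumeration of gamma-function ratios.
# P(split k | total t) is proportional to
#   Gamma(k + r1)/[Gamma(r1) k!] * Gamma(t - k + r2)/[Gamma(r2) (t - k)!]
# with r = n/phi (binomial coefficients in the Poisson limit).
oracle_nb_exact_p <- function(y1, y2, phi) {
  y1 <- round(y1); y2 <- round(y2)
  s1 <- sum(y1); t <- s1 + sum(y2)
  if (t == 0) return(1)
  n1 <- length(y1); n2 <- length(y2)
  k <- 0:t
  if (phi == 0) {
    lw <- lchoose(t, k) + k * log(n1 / (n1 + n2)) +
      (t - k) * log(n2 / (n1 + n2))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    lw <- (lgamma(k + r1) - lgamma(r1) - lfactorial(k)) +
      (lgamma(t - k + r2) - lgamma(r2) - lfactorial(t - k))
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  min(1, sum(w[w <= w[s1 + 1] * (1 + 1e-12)]))
}

# BH step-up by the direct min-over-suffix formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o][rank_i:n] * n / (rank_i:n)))
  }
  q
}

# Upper hypergeometric tail by summing choose() terms.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Two-sided Fisher p for a 2x2 table: sum over all tables with the observed
# margins whose hypergeometric probability is <= the observed one.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  K <- sum(tab[1, ]); N <- sum(tab); n <- sum(tab[, 1])
  aa <- max(0, n - (N - K)):min(K, n)
  pr <- stats::dhyper(aa, K, N - K, n)
  sum(pr[pr <= stats::dhyper(a, K, N - K, n) * (1 + 1e-7)])
}

# Spearman correlation as Pearson on average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Complete-linkage agglomeration from the definition: at every step the
# cross-cluster distance is recomputed as the max over all member pairs of
# the original distance matrix, searching every pair. Returns the
# cophenetic distance matrix.
oracle_complete_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dc <- max(d[clusters[[i]], clusters[[j]]])
      if (dc < best[1]) best <- c(dc, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# PCA via eigendecomposition of the covariance matrix.
oracle_pca <- function(x) {
  e <- eigen(stats::cov(x), symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors)
}
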