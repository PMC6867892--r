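#' Scale count columns to a common library depth
#'
#' Scales each sample's counts to the geometric mean of the library sizes
#' and rounds to the nearest integer, the pre-processing required by the
#' conditional (exact) negative-binomial test, which assumes equal depths.
#'
#' @param counts A [count_matrix()].
#' @return A [count_matrix()] with equalized (geometric-mean) library sizes.
#' @export
equalize_depth <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  ls <- counts$lib_sizes
  if (any(ls <= 0)) stop("library sizes must be positive", call. = FALSE)
  target <- exp(mean(log(ls)))
  scaled <- round(sweep(counts$counts, 2, target / ls, `*`))
  storage.mode(scaled) <- "integer"
  count_matrix(scaled,
               stats::setNames(counts$gene_lengths, rownames(counts$counts)),
               lib_sizes = rep(target, ncol(scaled)))
}

#' Common-dispersion estimate by conditional maximum likelihood
#'
#' Maximizes, over the negative-binomial dispersion phi (variance =
#' mu + phi * mu^2), the log-likelihood of the within-group counts
#' conditional on each gene's group total, summed over all genes and all
#' replicated groups. Conditioning removes the per-gene mean, so a single
#' phi is estimated for the whole matrix. Counts must be (and are) scaled to
#' a common depth first. The estimate is clipped at 0; data with no
#' overdispersion evidence (e.g. identical replicates) return exactly 0.
#'
#' @param counts A [count_matrix()] of raw counts (depth-equalized
#'   internally).
#' @param groups Factor/vector of group labels, one per sample column.
#' @param interval Search interval for phi.
#' @return List of class `dispersion_estimate`: `phi`, `method`, `n_genes`,
#'   `n_groups`.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       interval = c(1e-6, 20)) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- as.character(groups)
  if (length(groups) != ncol(counts$counts))
    stop("one group label per sample required", call. = FALSE)
  keep <- names(which(table(groups) >= 2L))
  if (!length(keep))
    stop("no group has >= 2 replicates; cannot estimate dispersion",
         call. = FALSE)
  y <- equalize_depth(counts)$counts

  cond_loglik <- function(phi) {
    r <- 1 / phi
    ll <- 0
    for (g in keep) {
      yg <- y[, groups == g, drop = FALSE]
      n <- ncol(yg)
      z <- rowSums(yg)
      ll <- ll + sum(lgamma(yg + r)) - length(yg) * lgamma(r) -
        sum(lgamma(yg + 1)) -
        sum(lgamma(z + n * r)) + length(z) * lgamma(n * r) +
        sum(lgamma(z + 1))
    }
    ll
  }
  opt <- stats::optimize(function(lp) cond_loglik(exp(lp)),
                         log(interval), maximum = TRUE, tol = 1e-6)
  phi <- exp(opt$maximum)
  # boundary => no evidence of overdispersion
  if (opt$maximum < log(interval[1]) + 0.05 ||
      cond_loglik(interval[1]) >= opt$objective)
    phi <- 0
  structure(list(phi = phi, method = "conditional maximum likelihood",
                 n_genes = nrow(y), n_groups = length(keep)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Common NB dispersion: phi = %.4g (%s; %d genes, %d groups)\n",
              x$phi, x$method, x$n_genes, x$n_groups))
  invisible(x)
}

#' Exact negative-binomial test for a two-group comparison
#'
#' Conditional on the total count across both groups, the group-1 sum
#' follows a distribution free of the (common, null) mean: with per-group
#' sizes n1, n2 and dispersion phi, the conditional probability of a split
#' is proportional to the product of two negative-binomial weights with
#' sizes n1/phi and n2/phi (binomial when phi = 0). The two-sided p-value
#' sums the probabilities of every split at most as probable as the
#' observed one. Counts must be scaled to a common depth beforehand;
#' non-integer values are rounded.
#'
#' @param y1,y2 Non-negative count vectors for the two groups (replicates).
#' @param dispersion NB dispersion phi >= 0.
#' @param pseudocount Added to each group mean for the fold change.
#' @return List with `pvalue` (in (0, 1]) and `log2fc`, oriented
#'   `log2((mean(y2) + pc) / (mean(y1) + pc))` so that swapping the groups
#'   negates the fold change but leaves the p-value unchanged.
#' @export
#' @examples
#' nb_exact_test(c(5, 5, 5), c(5, 5, 5), dispersion = 0.1)$pvalue  # 1
#' nb_exact_test(4, 0, dispersion = 0)$pvalue                      # 0.125
nb_exact_test <- function(y1, y2, dispersion, pseudocount = 0.5) {
  if (any(y1 < 0) || any(y2 < 0) || anyNA(c(y1, y2)))
    stop("counts must be non-negative", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  log2fc <- log2((mean(y2) + pseudocount) / (mean(y1) + pseudocount))
  y1 <- round(y1); y2 <- round(y2)
  s1 <- sum(y1); total <- s1 + sum(y2)
  if (total == 0) return(list(pvalue = 1, log2fc = 0))
  n1 <- length(y1); n2 <- length(y2)
  k <- 0:total
  if (dispersion == 0) {
    lw <- stats::dbinom(k, total, n1 / (n1 + n2), log = TRUE)
  } else {
    lw <- stats::dnbinom(k, size = n1 / dispersion, prob = 0.5, log = TRUE) +
      stats::dnbinom(total - k, size = n2 / dispersion, prob = 0.5,
                     log = TRUE)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  p <- sum(w[w <= w[s1 + 1L] * (1 + 1e-12)])
  list(pvalue = min(1, p), log2fc = log2fc)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]); q-values stay attached to their
#' input positions.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and names as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
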