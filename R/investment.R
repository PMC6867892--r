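#' Early/late DEG counts per CAZY family and functional class
#'
#' Counts, for every species, how many early- and late-upregulated DEGs
#' fall in each CAZY family, and pools the counts per functional class
#' (LOX / GH / other). DEGs missing from the annotation are counted as
#' class "other" with a warning. The early-minus-late difference `delta`
#' is positive when a family's DEGs skew toward the hyphal front.
#'
#' @param stage_sets Named list (per species) of `early` / `late` gene-id
#'   vectors, as from [pool_stage_sets()].
#' @param annotation Data frame `gene_id`, `family`, `class` (and
#'   optionally `species`).
#' @param rot_type Optional named map species -> rot type, carried through
#'   to the output.
#' @return List with data frames `families` (species, family, class,
#'   n_early, n_late, delta) and `classes` (species, class, n_early,
#'   n_late, delta).
#' @export
family_deg_counts <- function(stage_sets, annotation, rot_type = NULL) {
  rows <- list()
  for (sp in names(stage_sets)) {
    for (stage in c("early", "late")) {
      genes <- stage_sets[[sp]][[stage]]
      if (!length(genes)) next
      idx <- match(genes, annotation$gene_id)
      if (anyNA(idx)) {
        warning(sum(is.na(idx)), " DEG(s) missing annotation in ", sp,
                "; counted as class 'other'", call. = FALSE)
      }
      cls <- ifelse(is.na(idx), "other", annotation$class[idx])
      fam <- ifelse(is.na(idx), NA_character_, annotation$family[idx])
      fam[is.na(fam)] <- "unassigned"
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, stage = stage, family = fam, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    fam <- data.frame(species = character(0), family = character(0),
                      class = character(0), n_early = integer(0),
                      n_late = integer(0), delta = integer(0))
    cls <- fam[, c("species", "class", "n_early", "n_late", "delta")]
    return(list(families = fam, classes = cls))
  }
  long <- do.call(rbind, rows)

  count_by <- function(keys) {
    tab <- stats::aggregate(list(n = rep(1L, nrow(long))),
                            long[, c(keys, "stage")], sum)
    wide <- merge(
      stats::setNames(tab[tab$stage == "early", c(keys, "n")],
                      c(keys, "n_early")),
      stats::setNames(tab[tab$stage == "late", c(keys, "n")],
                      c(keys, "n_late")),
      by = keys, all = TRUE)
    wide$n_early[is.na(wide$n_early)] <- 0L
    wide$n_late[is.na(wide$n_late)] <- 0L
    wide$delta <- wide$n_early - wide$n_late
    if (!is.null(rot_type)) wide$rot_type <- rot_type[wide$species]
    wide[do.call(order, wide[keys]), , drop = FALSE]
  }
  list(families = count_by(c("species", "family", "class")),
       classes = count_by(c("species", "class")))
}

#' Tests for the early-decay shift of LOX regulation
#'
#' Two complementary tests of whether lignocellulose-oxidizing (LOX)
#' differential expression is shifted toward early decay in brown-rot
#' relative to white-rot fungi:
#'
#' * `fisher`: two-sided Fisher's exact test on the 2x2 table of pooled
#'   LOX DEG counts, rot type x (early, late). A degenerate table (zero
#'   margin) returns p = 1 with `degenerate = TRUE`.
#' * `paired_t`: two-tailed paired t-test on the per-family
#'   early-minus-late DEG difference, pairing each CAZY family's value in
#'   brown rot against the same family in white rot (species summed within
#'   rot type). Identical paired vectors give t = 0, p = 1.
#'
#' @param counts Output of [family_deg_counts()] (needs `rot_type`).
#' @param class Functional class tested (default `"LOX"`).
#' @return List with elements `fisher` (table, p, degenerate flag) and
#'   `paired_t` (n families, t, p).
#' @export
lox_shift_tests <- function(counts, class = "LOX") {
  cls <- counts$classes
  if (is.null(cls$rot_type))
    stop("family_deg_counts() must be run with rot_type", call. = FALSE)
  cl <- cls[cls$class == class, , drop = FALSE]
  tab <- rbind(
    brown = c(early = sum(cl$n_early[cl$rot_type == "brown"]),
              late = sum(cl$n_late[cl$rot_type == "brown"])),
    white = c(early = sum(cl$n_early[cl$rot_type == "white"]),
              late = sum(cl$n_late[cl$rot_type == "white"])))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  fisher <- list(
    table = tab,
    p = if (degenerate) 1 else stats::fisher.test(tab)$p.value,
    degenerate = degenerate)

  fam <- counts$families[counts$families$class == class, , drop = FALSE]
  agg <- stats::aggregate(fam[, c("n_early", "n_late")],
                          list(family = fam$family, rot_type = fam$rot_type),
                          sum)
  agg$delta <- agg$n_early - agg$n_late
  b <- agg[agg$rot_type == "brown", ]
  w <- agg[agg$rot_type == "white", ]
  shared <- intersect(b$family, w$family)
  paired_t <- list(n = length(shared), t = NA_real_, p = NA_real_)
  if (length(shared) >= 2L) {
    d <- b$delta[match(shared, b$family)] - w$delta[match(shared, w$family)]
    if (stats::sd(d) == 0) {
      paired_t$t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      paired_t$p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      paired_t$t <- unname(tt$statistic)
      paired_t$p <- tt$p.value
    }
  }
  list(fisher = fisher, paired_t = paired_t)
}

#' Hypergeometric (one-sided Fisher) term over-representation
#'
#' For each term, tests over-representation of the term's genes in the
#' target set against the universe with the one-sided hypergeometric tail
#' (the upper tail of the 2x2 Fisher table), then adjusts across terms by
#' Benjamini-Hochberg. Terms with no gene in the universe are skipped with
#' a warning.
#'
#' @param target Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector of all gene ids considered.
#' @param term_map Data frame `gene_id`, `term` (one row per
#'   gene-term link), or a named list term -> gene ids.
#' @return Data frame `term`, `n_term`, `n_overlap`, `expected`, `p`, `q`,
#'   ordered by p.
#' @export
fisher_enrichment <- function(target, universe, term_map) {
  target <- unique(target)
  universe <- unique(universe)
  if (length(setdiff(target, universe)))
    stop("target must be a subset of the universe", call. = FALSE)
  if (is.data.frame(term_map))
    term_map <- split(term_map$gene_id, term_map$term)
  term_map <- lapply(term_map, intersect, universe)
  empty <- lengths(term_map) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " term(s) absent from the universe",
            call. = FALSE)
    term_map <- term_map[!empty]
  }
  N <- length(universe)
  n <- length(target)
  res <- do.call(rbind, lapply(names(term_map), function(tm) {
    K <- length(term_map[[tm]])
    k <- length(intersect(term_map[[tm]], target))
    data.frame(term = tm, n_term = K, n_overlap = k,
               expected = n * K / N,
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(term = character(0), n_term = integer(0),
                      n_overlap = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GH:LOX transcriptional-investment ratio
#'
#' Per species and wafer section, sums section-mean RPKM over glycoside
#' hydrolase (GH) genes and over lignocellulose-oxidizing (LOX) genes and
#' reports their ratio - the transcriptional energy-allocation statistic.
#' When the LOX sum is zero the ratio is undefined (NA), not infinite.
#'
#' @param section_rpkm_list Named list (per species) of genes x sections
#'   RPKM matrices (see [section_means()]).
#' @param annotation Data frame `gene_id`, `class`.
#' @return Data frame `species`, `section`, `gh_rpkm`, `lox_rpkm`,
#'   `gh_lox_ratio`.
#' @export
investment_ratio <- function(section_rpkm_list, annotation) {
  rows <- lapply(names(section_rpkm_list), function(sp) {
    rp <- section_rpkm_list[[sp]]
    cls <- annotation$class[match(rownames(rp), annotation$gene_id)]
    gh <- colSums(rp[cls %in% "GH", , drop = FALSE])
    lox <- colSums(rp[cls %in% "LOX", , drop = FALSE])
    data.frame(species = sp, section = colnames(rp),
               gh_rpkm = unname(gh), lox_rpkm = unname(lox),
               gh_lox_ratio = ifelse(lox > 0, gh / lox, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal-component analysis of expression profiles
#'
#' Centers features internally and decomposes the observations x features
#' matrix (wrapper around [stats::prcomp()]). Loadings are orthonormal,
#' explained-variance fractions are non-increasing and component variances
#' sum to the total variance of the centered data. A constant matrix has
#' zero variance and yields no components.
#'
#' @param x Numeric matrix, observations x features.
#' @param n_components Number of components to keep (default all).
#' @return List with `scores`, `loadings`, `explained` (fractions) and
#'   `sdev`.
#' @export
pca_expression <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs >= 2 observations", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total == 0)
    return(list(scores = x[, 0, drop = FALSE],
                loadings = matrix(0, ncol(x), 0), explained = numeric(0),
                sdev = numeric(0)))
  k <- min(n_components %||% length(pc$sdev), length(pc$sdev))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / total)[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Family-summed, log-transformed expression matrix for PCA
#'
#' Sums section-mean RPKM per CAZY family within each species and returns
#' a (species x section) x family matrix, log2(x + 1)-transformed since
#' RPKM spans orders of magnitude.
#'
#' @inheritParams investment_ratio
#' @return Numeric matrix, rows named `<species>_<section>`.
#' @export
family_expression_matrix <- function(section_rpkm_list, annotation) {
  fams <- sort(unique(annotation$family[!is.na(annotation$family)]))
  rows <- list()
  for (sp in names(section_rpkm_list)) {
    rp <- section_rpkm_list[[sp]]
    fam <- annotation$family[match(rownames(rp), annotation$gene_id)]
    keep <- !is.na(fam)
    summed <- rowsum(rp[keep, , drop = FALSE], fam[keep])
    m <- matrix(0, ncol(rp), length(fams),
                dimnames = list(paste(sp, colnames(rp), sep = "_"), fams))
    m[, rownames(summed)] <- t(summed)
    rows[[sp]] <- m
  }
  log2(do.call(rbind, rows) + 1)
}

#' Z-score scaling of a matrix
#'
#' Per row (default) or column: `(x - mean) / sd` with the sample (n - 1)
#' standard deviation; constant slices map to all-zeros.
#'
#' @param x Numeric matrix.
#' @param margin 1 to scale rows, 2 to scale columns.
#' @return Matrix of the same shape; non-constant slices have mean 0 and
#'   sd 1.
#' @export
zscore_scale <- function(x, margin = 1L) {
  x <- as.matrix(x)
  if (margin == 1L) return(t(zscore_scale(t(x), margin = 2L)))
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  out <- sweep(x, 2L, mu)
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sd[nz], `/`)
  out[, !nz] <- 0
  out
}
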