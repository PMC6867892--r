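#' Early-to-late expression ratio
#'
#' The per-gene (or per-group) temporal statistic:
#' `r = log2[(RPKM_0-5mm + eps) / (mean(RPKM_15-20mm, RPKM_30-35mm) + eps)]`.
#' The pseudocount `eps` (default 0.1 RPKM, well below the RPKM > 5
#' expression-evidence threshold) keeps the ratio finite; an all-zero
#' profile maps to exactly 0.
#'
#' @param section_rpkm Matrix (rows = genes/groups) with the three section
#'   columns of [decay_sections()], or a length-3 vector.
#' @param eps Pseudocount added to numerator and denominator.
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' early_late_ratio(c(`0-5mm` = 8, `15-20mm` = 2, `30-35mm` = 2))  # 2
early_late_ratio <- function(section_rpkm, eps = 0.1) {
  if (is.null(dim(section_rpkm)))
    section_rpkm <- matrix(section_rpkm, 1L,
                           dimnames = list(NULL, names(section_rpkm)))
  secs <- decay_sections()
  if (!all(secs %in% colnames(section_rpkm)))
    stop("need the three section columns", call. = FALSE)
  early <- section_rpkm[, secs[1]]
  late <- (section_rpkm[, secs[2]] + section_rpkm[, secs[3]]) / 2
  r <- as.numeric(log2((early + eps) / (late + eps)))
  names(r) <- rownames(section_rpkm)
  r
}

#' Per-sample ortholog-group early-to-late ratio profiles
#'
#' For every species and replicate, sums member-gene RPKM per ortholog
#' group (paralogs pool their expression) and computes the early-to-late
#' ratio from that replicate's three sections. Profiles from all species
#' are aligned on group ids; a species without member genes contributes NA
#' (absent), not zero.
#'
#' @param rpkm_list Named list (per species) of RPKM matrices,
#'   genes x samples.
#' @param design Sample sheet covering all samples (`sample_id`, `species`,
#'   `section`, `replicate`).
#' @param orthogroups Table `group_id`, `species`, `gene_id`.
#' @param ids Optional character vector restricting rows (e.g. to
#'   ortho-DEG group ids).
#' @param eps Pseudocount, see [early_late_ratio()].
#' @return Matrix groups x (species_replicate) of ratios.
#' @export
ortho_ratio_profiles <- function(rpkm_list, design, orthogroups,
                                 ids = NULL, eps = 0.1) {
  groups <- sort(unique(orthogroups$group_id))
  if (!is.null(ids)) groups <- intersect(groups, ids)
  cols <- character(0)
  mats <- list()
  for (sp in names(rpkm_list)) {
    rp <- rpkm_list[[sp]]
    og <- orthogroups[orthogroups$species == sp &
                        orthogroups$gene_id %in% rownames(rp), , drop = FALSE]
    d <- design[design$species == sp, , drop = FALSE]
    reps <- sort(unique(d$replicate))
    sp_mat <- matrix(NA_real_, length(groups), length(reps),
                     dimnames = list(groups, paste(sp, reps, sep = "_")))
    if (nrow(og)) {
      summed <- rowsum(rp[og$gene_id, , drop = FALSE], og$group_id)
      summed <- summed[intersect(rownames(summed), groups), , drop = FALSE]
      for (k in seq_along(reps)) {
        dk <- d[d$replicate == reps[k], , drop = FALSE]
        sec <- sapply(decay_sections(), function(s)
          summed[, dk$sample_id[dk$section == s], drop = TRUE])
        if (is.null(dim(sec)))
          sec <- matrix(sec, 1L, dimnames = list(rownames(summed),
                                                 decay_sections()))
        r <- early_late_ratio(sec, eps)
        sp_mat[rownames(summed), k] <- r
      }
    }
    mats[[sp]] <- sp_mat
    cols <- c(cols, colnames(sp_mat))
  }
  out <- do.call(cbind, mats)
  colnames(out) <- cols
  out
}

#' Pairwise sample correlation matrix
#'
#' Spearman (default; average ranks for ties) or Pearson correlation of the
#' columns of a profile matrix, dropping missing rows pairwise. Pairs
#' sharing fewer than `min_obs` complete observations are flagged missing
#' (NA).
#'
#' @param profiles Matrix, observations x samples (NA = absent).
#' @param method `"spearman"` or `"pearson"`.
#' @param min_obs Minimum shared observations per pair.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(profiles, method = c("spearman", "pearson"),
                               min_obs = 3L) {
  method <- match.arg(method)
  cc <- stats::cor(profiles, use = "pairwise.complete.obs", method = method)
  ok <- !is.na(profiles)
  shared <- crossprod(ok)            # pairwise complete counts
  cc[shared < min_obs] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Hierarchical clustering of sample profiles
#'
#' Agglomerative clustering (default: euclidean distance, complete
#' linkage) of the rows of a matrix - typically the rows of a sample
#' correlation matrix used as feature vectors, so samples with similar
#' correlation structure cluster together.
#'
#' @param x Numeric matrix with row names; all entries must be finite.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] object.
#' @export
hierarchical_cluster <- function(x, distance = "euclidean",
                                 linkage = "complete") {
  if (any(!is.finite(x)))
    stop("non-finite entries in clustering input", call. = FALSE)
  stats::hclust(stats::dist(x, method = distance), method = linkage)
}

#' Export a dendrogram as a Newick string
#' @param hc An [stats::hclust] object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
cluster_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  nwk <- ape::write.tree(tr)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Species composition of the two top-level clusters
#'
#' Cuts a sample dendrogram into two clusters and reports, per cluster, the
#' species of its members - used to check whether the two brown-rot species
#' separate from the two white-rot species.
#'
#' @param hc An [stats::hclust] of samples named `<species>_<replicate>`.
#' @param rot_type Named map species -> rot type.
#' @return `TRUE` when one cluster holds exactly the brown-rot samples.
#' @export
clusters_by_rot_type <- function(hc, rot_type) {
  k2 <- stats::cutree(hc, k = 2L)
  sp <- sub("_[^_]*$", "", names(k2))
  rt <- rot_type[sp]
  all(vapply(split(rt, k2), function(v) length(unique(v)) == 1L,
             logical(1))) &&
    length(unique(rt)) == 2L
}
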