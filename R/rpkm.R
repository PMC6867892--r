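#' Construct a count matrix with gene lengths
#'
#' Light container for gene-level read counts: a non-negative integer matrix
#' (genes x samples) together with transcript lengths in bp. Library sizes
#' default to column sums but may be supplied externally (e.g. total mapped
#' reads).
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param gene_lengths Named numeric vector of transcript lengths (bp > 0)
#'   covering every row of `counts`.
#' @param lib_sizes Optional named numeric vector of library sizes; defaults
#'   to `colSums(counts)`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample names", call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative and complete", call. = FALSE)
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl) || any(gl <= 0))
    stop("gene lengths must be positive for every gene", call. = FALSE)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- stats::setNames(as.numeric(lib_sizes), colnames(counts))
  structure(list(counts = counts, gene_lengths = as.numeric(gl),
                 lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median depth %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM[g, s] = counts[g, s] * 1e9 / (length[g] * lib_size[s])`. RPKM is 0
#' exactly where the count is 0 and is invariant to scaling counts and
#' library sizes by a common factor.
#'
#' @param counts A [count_matrix()], or a plain matrix if `gene_lengths`
#'   (and optionally `lib_sizes`) are given.
#' @param gene_lengths,lib_sizes Used only when `counts` is a plain matrix.
#' @return Numeric matrix of RPKM values, genes x samples.
#' @export
#' @examples
#' m <- matrix(10L, 1, 1, dimnames = list("g1", "s1"))
#' compute_rpkm(m, gene_lengths = c(g1 = 1000), lib_sizes = c(s1 = 1e6))
compute_rpkm <- function(counts, gene_lengths = NULL, lib_sizes = NULL) {
  if (!inherits(counts, "count_matrix"))
    counts <- count_matrix(counts, gene_lengths, lib_sizes)
  if (any(counts$lib_sizes <= 0)) {
    bad <- names(counts$lib_sizes)[counts$lib_sizes <= 0][1]
    stop(sprintf("library size is zero for sample '%s'", bad), call. = FALSE)
  }
  counts$counts * 1e9 /
    outer(counts$gene_lengths, counts$lib_sizes)
}

#' Mean expression per wafer section
#'
#' Averages an expression matrix over replicates within each section of a
#' (single-species) design.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param design Sample sheet with `sample_id` and `section` columns covering
#'   the columns of `expr`.
#' @return Matrix genes x sections, columns ordered as [decay_sections()].
#' @export
section_means <- function(expr, design) {
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("design does not cover all expression columns", call. = FALSE)
  secs <- decay_sections()
  missing <- setdiff(secs, design$section)
  if (length(missing))
    stop("missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- sapply(secs, function(s)
    rowMeans(expr[, design$section == s, drop = FALSE]))
  colnames(out) <- secs
  out
}

#' Expression-evidence classification of genes
#'
#' A gene has `full` expression evidence when its section-mean RPKM exceeds
#' the threshold in all three wafer sections, `partial` when in one or two,
#' and `none` otherwise.
#'
#' @param section_rpkm Matrix genes x 3 sections of section-mean RPKM.
#' @param threshold RPKM threshold (default 5, strict inequality).
#' @return Named factor with levels `full`, `partial`, `none`.
#' @export
expression_evidence <- function(section_rpkm, threshold = 5) {
  secs <- decay_sections()
  if (!all(secs %in% colnames(section_rpkm)))
    stop("section_rpkm must have all three section columns", call. = FALSE)
  n <- rowSums(section_rpkm[, secs, drop = FALSE] > threshold)
  lab <- ifelse(n == 3L, "full", ifelse(n >= 1L, "partial", "none"))
  factor(stats::setNames(lab, rownames(section_rpkm)),
         levels = c("full", "partial", "none"))
}
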