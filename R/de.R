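#' Call differentially expressed genes from a DE table
#'
#' A gene is a DEG for a contrast iff its BH-adjusted FDR is below
#' `fdr_threshold` and its absolute fold change exceeds `fc_threshold`
#' (both strict), the FC > 4 / FDR < 0.05 rule by default. `direction` is
#' the sign of the log2 fold change for DEGs and 0 otherwise.
#'
#' @param de Data frame with at least `log2fc` and `fdr` columns.
#' @param fc_threshold Fold-change threshold on the natural scale.
#' @param fdr_threshold FDR threshold.
#' @return `de` with a `direction` column (integer -1, 0, +1).
#' @export
call_degs <- function(de, fc_threshold = 4, fdr_threshold = 0.05) {
  sig <- de$fdr < fdr_threshold & abs(de$log2fc) > log2(fc_threshold)
  de$direction <- ifelse(sig, sign(de$log2fc), 0)
  de$direction <- as.integer(de$direction)
  de
}

#' Section-pairwise differential expression for one species
#'
#' Runs the full two-group exact-test workflow on a species' count matrix:
#' scales samples to a common depth, estimates the common NB dispersion by
#' conditional maximum likelihood across the three section groups (unless
#' supplied), tests every gene for each of the three section contrasts
#' (later vs earlier), adjusts p-values per contrast by Benjamini-Hochberg
#' and applies the FC/FDR DEG rule.
#'
#' @param counts A [count_matrix()] for one species (9 samples at the
#'   default design).
#' @param design Sample sheet rows for this species (`sample_id`,
#'   `section`).
#' @param dispersion Optional fixed NB dispersion; estimated when `NULL`.
#' @param fc_threshold,fdr_threshold DEG thresholds, see [call_degs()].
#' @return List of class `de_result`: `table` (gene_id, contrast, log2fc,
#'   pvalue, fdr, direction), `dispersion` (the
#'   [estimate][estimate_common_dispersion] or supplied value).
#' @export
run_species_de <- function(counts, design, dispersion = NULL,
                           fc_threshold = 4, fdr_threshold = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  design <- design[match(colnames(counts$counts), design$sample_id), ,
                   drop = FALSE]
  if (anyNA(design$sample_id))
    stop("design does not cover all count columns", call. = FALSE)
  eq <- equalize_depth(counts)
  if (is.null(dispersion)) {
    est <- estimate_common_dispersion(counts, design$section)
    phi <- est$phi
  } else {
    est <- dispersion
    phi <- if (inherits(dispersion, "dispersion_estimate"))
      dispersion$phi else dispersion
  }

  contrasts <- decay_contrasts()
  genes <- rownames(eq$counts)
  tabs <- vector("list", nrow(contrasts))
  for (i in seq_len(nrow(contrasts))) {
    e_cols <- design$section == contrasts$earlier[i]
    l_cols <- design$section == contrasts$later[i]
    if (!any(e_cols) || !any(l_cols))
      stop("missing section samples for contrast ", contrasts$contrast[i],
           call. = FALSE)
    y_e <- eq$counts[, e_cols, drop = FALSE]
    y_l <- eq$counts[, l_cols, drop = FALSE]
    res <- vapply(seq_along(genes), function(g) {
      r <- nb_exact_test(y_e[g, ], y_l[g, ], phi)
      c(r$pvalue, r$log2fc)
    }, numeric(2))
    tabs[[i]] <- data.frame(
      gene_id = genes,
      contrast = contrasts$contrast[i],
      log2fc = res[2, ],
      pvalue = res[1, ],
      fdr = bh_fdr(res[1, ]),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  tab <- call_degs(tab, fc_threshold, fdr_threshold)
  structure(list(table = tab, dispersion = est), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  n_deg <- sum(x$table$direction != 0)
  cat(sprintf("DE result: %d genes x %d contrasts, %d DEG calls\n",
              length(unique(x$table$gene_id)),
              length(unique(x$table$contrast)), n_deg))
  invisible(x)
}

#' Write a per-contrast DE table to TSV
#' @param de A `de_result` or its `table` component.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  tab <- if (inherits(de, "de_result")) de$table else de
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
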