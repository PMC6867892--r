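#' Eight decay-stage trend subgroups
#'
#' The per-gene DEG directions of the three section contrasts form a triple
#' `(d_BA, d_CA, d_CB)` with A = 0-5 mm, B = 15-20 mm, C = 30-35 mm and
#' "-" meaning significantly lower in the later section. Trend-consistent
#' triples map to eight subgroups: I-IV peak at the hyphal front and pool
#' as early-upregulated, V-VIII peak in later sections and pool as
#' late-upregulated. Any other triple (including contradictory directions)
#' is `none`.
#'
#' @return Data frame of the eight subgroup patterns with their stage.
#' @export
trend_subgroups <- function() {
  data.frame(
    subgroup = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    d_BA = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
    d_CA = c(-1L, -1L, 0L, -1L, 1L, 1L, 0L, 1L),
    d_CB = c(-1L, 0L, 1L, -1L, 1L, 0L, -1L, 1L),
    stage = rep(c("early", "late"), each = 4L),
    stringsAsFactors = FALSE
  )
}

#' Classify per-gene temporal trends across wafer sections
#'
#' Takes the DE table of the three section contrasts (from
#' [run_species_de()]) and assigns each gene its trend subgroup and pooled
#' decay stage.
#'
#' @param de A `de_result` or its `table` component with `gene_id`,
#'   `contrast` and `direction` columns covering all three contrasts.
#' @return Data frame `gene_id`, `d_BA`, `d_CA`, `d_CB`, `subgroup`
#'   (I-VIII or `none`) and `stage` (`early`, `late` or `none`).
#' @export
classify_trend <- function(de) {
  tab <- if (inherits(de, "de_result")) de$table else de
  cons <- decay_contrasts()$contrast
  missing <- setdiff(cons, tab$contrast)
  if (length(missing))
    stop("missing contrast(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  genes <- unique(tab$gene_id)
  dirs <- vapply(cons, function(cn) {
    sub <- tab[tab$contrast == cn, ]
    d <- sub$direction[match(genes, sub$gene_id)]
    if (anyNA(d))
      stop("contrast ", cn, " does not cover every gene", call. = FALSE)
    as.integer(d)
  }, integer(length(genes)))
  dirs <- matrix(dirs, nrow = length(genes),
                 dimnames = list(NULL, c("d_BA", "d_CA", "d_CB")))

  pat <- trend_subgroups()
  key <- paste(dirs[, 1], dirs[, 2], dirs[, 3])
  pkey <- paste(pat$d_BA, pat$d_CA, pat$d_CB)
  idx <- match(key, pkey)
  out <- data.frame(gene_id = genes, dirs,
                    subgroup = ifelse(is.na(idx), "none", pat$subgroup[idx]),
                    stage = ifelse(is.na(idx), "none", pat$stage[idx]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pool trend subgroups into early and late DEG sets
#'
#' Early = union of subgroups I-IV, late = union of V-VIII; the sets are
#' disjoint by construction.
#'
#' @param assignments Output of [classify_trend()].
#' @return List with character vectors `early` and `late`.
#' @export
pool_stage_sets <- function(assignments) {
  list(early = assignments$gene_id[assignments$stage == "early"],
       late = assignments$gene_id[assignments$stage == "late"])
}
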